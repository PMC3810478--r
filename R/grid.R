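#' Define a multi-parametric detection grid
#'
#' A detection grid is the channel partition of a photon-counting instrument:
#' ordered bin edges along photon arrival time (within one laser period),
#' emission wavelength, and a set of polarization analyzer states. The total
#' channel count is the product of the per-dimension channel numbers.
#'
#' Time gates and wavelength bins are half-open `[lo, hi)`. Channel ordering
#' (for flattened vectors and CSV/TIFF export) is polarization-major, then
#' wavelength, then time (time index varies fastest).
#'
#' @param time_edges Strictly increasing gate edges in ns, within
#'   `[0, laser_period_ns]`.
#' @param laser_period_ns Laser repetition period T in ns.
#' @param wavelength_edges Strictly increasing spectral bin edges in nm.
#' @param polarizations Character vector of analyzer states, a subset of
#'   `"parallel"`, `"perpendicular"`, `"unpolarized"`.
#' @return An object of class `detection_grid`.
#' @examples
#' default_grid()            # 2 pol x 16 spectral x 64 time = 2048 channels
#' @export
detection_grid <- function(time_edges, laser_period_ns,
                           wavelength_edges = c(440, 630),
                           polarizations = c("parallel", "perpendicular")) {
  check_scalar(laser_period_ns, "laser_period_ns")
  check_edges(time_edges, "time_edges", lower = 0, upper = laser_period_ns)
  check_edges(wavelength_edges, "wavelength_edges")
  valid <- c("parallel", "perpendicular", "unpolarized")
  if (length(polarizations) < 1L || !all(polarizations %in% valid) ||
      anyDuplicated(polarizations)) {
    abort("`polarizations` must be distinct labels from parallel/perpendicular/unpolarized.",
          class = "hdim_error_domain")
  }
  structure(
    list(time_edges = as.numeric(time_edges),
         laser_period_ns = laser_period_ns,
         wavelength_edges = as.numeric(wavelength_edges),
         polarizations = polarizations),
    class = "detection_grid"
  )
}

#' The reference hyper-dimensional detection grid
#'
#' 64 equal time gates spanning 12.5 ns, 16 equal spectral bins over
#' 440–630 nm and both polarization states: 2048 channels, matching the
#' configuration of commercially available spectrally/polarization-resolved
#' TCSPC systems.
#'
#' @param n_time Number of equal-width time gates (default 64).
#' @param n_spectral Number of equal-width spectral bins (default 16).
#' @param laser_period_ns Laser period in ns (default 12.5).
#' @param wavelength_range_nm Detection band in nm (default `c(440, 630)`).
#' @param polarizations Analyzer states (default both linear states).
#' @return A [detection_grid()].
#' @export
default_grid <- function(n_time = 64, n_spectral = 16, laser_period_ns = 12.5,
                         wavelength_range_nm = c(440, 630),
                         polarizations = c("parallel", "perpendicular")) {
  detection_grid(
    time_edges = seq(0, laser_period_ns, length.out = n_time + 1L),
    laser_period_ns = laser_period_ns,
    wavelength_edges = seq(wavelength_range_nm[1], wavelength_range_nm[2],
                           length.out = n_spectral + 1L),
    polarizations = polarizations
  )
}

grid_dims <- function(grid) {
  c(pol = length(grid$polarizations),
    wavelength = length(grid$wavelength_edges) - 1L,
    time = length(grid$time_edges) - 1L)
}

#' Number of detection channels in a grid
#' @param grid A [detection_grid()].
#' @return Integer channel count.
#' @export
n_channels <- function(grid) as.integer(prod(grid_dims(grid)))

#' @export
print.detection_grid <- function(x, ...) {
  d <- grid_dims(x)
  cat(sprintf("<detection_grid: %d channels = %d pol x %d spectral x %d time>\n",
              prod(d), d[1], d[2], d[3]))
  cat(sprintf("  time: [0, %g] ns, %d gates; wavelength: [%g, %g] nm, %d bins\n",
              x$laser_period_ns, d[3],
              min(x$wavelength_edges), max(x$wavelength_edges), d[2]))
  cat("  polarizations:", paste(x$polarizations, collapse = ", "), "\n")
  invisible(x)
}

#' Per-channel table of a detection grid
#'
#' One row per channel in flattened (polarization-major, time-fastest) order,
#' with the channel boundaries along each dimension.
#'
#' @param grid A [detection_grid()].
#' @return A tibble with columns `channel`, `polarization`, `lambda_lo`,
#'   `lambda_hi`, `t_lo`, `t_hi`.
#' @export
channel_table <- function(grid) {
  d <- grid_dims(grid)
  tl <- utils::head(grid$time_edges, -1L)
  th <- utils::tail(grid$time_edges, -1L)
  wl <- utils::head(grid$wavelength_edges, -1L)
  wh <- utils::tail(grid$wavelength_edges, -1L)
  out <- expand_grid(
    polarization = grid$polarizations,
    lambda_idx = seq_len(d[["wavelength"]]),
    time_idx = seq_len(d[["time"]])
  )
  out <- mutate(out,
                channel = dplyr::row_number(),
                lambda_lo = wl[.data$lambda_idx],
                lambda_hi = wh[.data$lambda_idx],
                t_lo = tl[.data$time_idx],
                t_hi = th[.data$time_idx])
  select(out, "channel", "polarization", "lambda_lo", "lambda_hi",
         "t_lo", "t_hi")
}

grids_compatible <- function(a, b) {
  isTRUE(all.equal(a$time_edges, b$time_edges)) &&
    isTRUE(all.equal(a$wavelength_edges, b$wavelength_edges)) &&
    identical(a$polarizations, b$polarizations) &&
    isTRUE(all.equal(a$laser_period_ns, b$laser_period_ns))
}
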