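# Technique comparison: F-values of every marginalization of the full grid.

technique_dims <- function() {
  list(
    FLIM   = "time",
    SPEC   = "wavelength",
    ANISO  = "polarization",
    SLIM   = c("wavelength", "time"),
    TR_ANISO = c("polarization", "time"),
    SR_ANISO = c("polarization", "wavelength"),
    HDIM   = c("polarization", "wavelength", "time")
  )
}

#' F-value of unmixing for every detection modality
#'
#' Marginalizes the hyper-dimensional signatures of two fluorophores onto
#' each of the seven non-empty combinations of the time / wavelength /
#' polarization dimensions — FLIM, spectral imaging (SPEC), anisotropy
#' imaging (ANISO), spectrally resolved FLIM (SLIM), time-resolved
#' anisotropy, spectrally resolved anisotropy, and the full grid (HDIM) —
#' and computes the combined abundance F-value ([fisher_matrix()]) across a
#' grid of relative abundances. By the photon partitioning theorem, HDIM
#' dominates every marginalization at every abundance.
#'
#' @param fluoroA,fluoroB Two [fluorophore()] objects.
#' @param grid A [detection_grid()]; default [default_grid()].
#' @param abundance_grid Relative abundances of fluorophore A to scan,
#'   strictly inside (0, 1).
#' @param shape,shape_k Spectral model options, see [spectrum_fractions()].
#' @return A tibble of class `hdim_scan` with columns `technique`,
#'   `abundance`, `F` (combined F-value) and `p` (photon efficiency).
#'   Summarise with [glance()]; plot with [autoplot()].
#' @examples
#' fl <- example_fluorophores(spectral_shift_nm = 10)
#' scan <- technique_fvalue_scan(fl$A, fl$B)
#' glance(scan)
#' @export
technique_fvalue_scan <- function(fluoroA, fluoroB, grid = default_grid(),
                                  abundance_grid = seq(0.05, 0.95, by = 0.01),
                                  shape = c("gamma", "gaussian"),
                                  shape_k = 16) {
  shape <- match.arg(shape)
  if (any(abundance_grid <= 0 | abundance_grid >= 1)) {
    abort("`abundance_grid` must lie strictly inside (0, 1).",
          class = "hdim_error_domain")
  }
  hA <- build_hdss(fluoroA, grid, shape, shape_k)
  hB <- build_hdss(fluoroB, grid, shape, shape_k)
  rows <- imap(technique_dims(), function(keep, tech) {
    gA <- as.vector(marginalize(hA, keep)$fractions)
    gB <- as.vector(marginalize(hB, keep)$fractions)
    Fv <- map_dbl(abundance_grid, function(a) {
      fisher_matrix(cbind(gA, gB), c(a, 1 - a))$combined_F
    })
    tibble(technique = tech, abundance = abundance_grid, F = Fv)
  })
  out <- mutate(bind_rows(rows), p = photon_efficiency(F))
  class(out) <- c("hdim_scan", class(out))
  out
}

#' Summarise a technique F-value scan
#'
#' One row per technique: the minimum combined F over the abundance grid, the
#' abundance where it occurs, the F-value at 50% abundance (when scanned) and
#' the photon count needed for 5% relative error (`round(F_min^2 * 400)`).
#'
#' @param x An `hdim_scan` from [technique_fvalue_scan()].
#' @param ... Unused.
#' @return A tibble with columns `technique`, `F_min`, `abundance_at_min`,
#'   `F_at_half`, `photons_5pct`, sorted by decreasing `F_min`.
#' @method glance hdim_scan
#' @export
glance.hdim_scan <- function(x, ...) {
  halves <- x |>
    group_by(.data$technique) |>
    summarise(F_at_half = {
      i <- which.min(abs(.data$abundance - 0.5))
      if (abs(.data$abundance[i] - 0.5) < 1e-9) .data$F[i] else NA_real_
    }, .groups = "drop")
  x |>
    group_by(.data$technique) |>
    summarise(F_min = min(.data$F),
              abundance_at_min = .data$abundance[which.min(.data$F)],
              .groups = "drop") |>
    left_join(halves, by = "technique") |>
    mutate(photons_5pct = round(photons_required(.data$F_min))) |>
    arrange(dplyr::desc(.data$F_min))
}

#' @method autoplot hdim_scan
#' @export
autoplot.hdim_scan <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$abundance, y = .data$F,
                               colour = .data$technique)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "relative abundance of fluorophore A",
                  y = "combined F-value",
                  colour = "technique") +
    ggplot2::theme_minimal()
}
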