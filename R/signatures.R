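# Forward photophysical models: per-channel expected photon fractions.

# definite integral of exp(-rate * t) over [a, b], elementwise
exp_integral <- function(a, b, rate) (exp(-rate * a) - exp(-rate * b)) / rate

#' Fraction of decay photons per time gate
#'
#' For a mono-exponential decay with lifetime `tau` under pulsed excitation
#' with period `T`, arrival times within one period follow the truncated
#' exponential density `exp(-t/tau) / (tau * (1 - exp(-T/tau)))`. The
#' fraction of photons in gate `[t_a, t_b)` is
#' `(exp(-t_a/tau) - exp(-t_b/tau)) / (1 - exp(-T/tau))`, so a full cover of
#' `[0, T]` sums to one.
#'
#' @param time_edges Strictly increasing gate edges (ns) within `[0, T]`.
#' @param tau Fluorescence lifetime (ns), > 0.
#' @param T Laser period (ns).
#' @return Numeric vector of per-gate fractions, one per gate.
#' @examples
#' decay_fractions(c(0, 1.3863, 12.5), tau = 2, T = 12.5)
#' @export
decay_fractions <- function(time_edges, tau, T) {
  check_scalar(tau, "tau")
  check_scalar(T, "T")
  check_edges(time_edges, "time_edges", lower = 0, upper = T)
  a <- utils::head(time_edges, -1L)
  b <- utils::tail(time_edges, -1L)
  (exp(-a / tau) - exp(-b / tau)) / (1 - exp(-T / tau))
}

#' Polarization-resolved time-gate fractions
#'
#' Photons observed through parallel and perpendicular analyzers follow
#' `I_par(t)  ~ exp(-t/tau) * (1 + 2 r(t)) / 3` and
#' `I_perp(t) ~ exp(-t/tau) * (1 -   r(t)) / 3`
#' with anisotropy decay `r(t) = r0 * exp(-t/theta)`. Each gate integral is a
#' sum of two exponential integrals (rates `1/tau` and `1/tau + 1/theta`), so
#' everything is evaluated in closed form. Fractions are normalized so that
#' both rows over a full cover of `[0, T]` sum to one.
#'
#' @inheritParams decay_fractions
#' @param r0 Limiting anisotropy in `[0, 0.4]`.
#' @param theta Rotational correlation time (ns), > 0.
#' @return A 2 x n_gates matrix with rows `parallel`, `perpendicular`.
#' @export
polarized_time_fractions <- function(time_edges, tau, r0, theta, T) {
  check_scalar(tau, "tau")
  check_scalar(theta, "theta")
  check_scalar(T, "T")
  if (!is.numeric(r0) || length(r0) != 1L || r0 < 0 || r0 > 0.4) {
    abort("`r0` must lie in [0, 0.4].", class = "hdim_error_domain")
  }
  check_edges(time_edges, "time_edges", lower = 0, upper = T)
  a <- utils::head(time_edges, -1L)
  b <- utils::tail(time_edges, -1L)
  rate2 <- 1 / tau + 1 / theta
  E1 <- exp_integral(a, b, 1 / tau)
  E2 <- exp_integral(a, b, rate2)
  par_ <- (E1 + 2 * r0 * E2) / 3
  perp <- (E1 - r0 * E2) / 3
  total <- (2 * exp_integral(0, T, 1 / tau) + r0 * exp_integral(0, T, rate2)) / 3
  out <- rbind(parallel = par_, perpendicular = perp) / total
  out
}

# FWHM of the standard gamma density (shape k, scale 1), used to rescale
gamma_unit_fwhm <- function(k) {
  mode0 <- k - 1
  half <- dgamma(mode0, shape = k) / 2
  lo <- uniroot(function(x) dgamma(x, shape = k) - half,
                c(.Machine$double.eps, mode0), tol = 1e-12)$root
  hi <- uniroot(function(x) dgamma(x, shape = k) - half,
                c(mode0, mode0 + 30 * sqrt(k) + 10), tol = 1e-12)$root
  hi - lo
}

#' Fraction of emission per spectral bin
#'
#' Integrates a unimodal spectral density over each wavelength bin and
#' renormalizes so the fractions over the covered detection range sum to one.
#' `shape = "gamma"` uses a gamma density (right-skewed, the typical shape of
#' an emission spectrum) reparameterized so that its mode equals `peak` and
#' its FWHM equals `fwhm`; the dimensionless shape parameter `shape_k`
#' controls the skewness (`2/sqrt(shape_k)`). `shape = "gaussian"` is
#' provided for sensitivity analysis.
#'
#' @param wavelength_edges Strictly increasing bin edges (nm).
#' @param peak Spectral peak (mode) in nm.
#' @param fwhm Full width at half maximum in nm, > 0.
#' @param shape `"gamma"` (default) or `"gaussian"`.
#' @param shape_k Gamma shape parameter (> 1); default 16, i.e. skewness 0.5.
#' @return Numeric vector of per-bin fractions summing to 1.
#' @export
spectrum_fractions <- function(wavelength_edges, peak, fwhm,
                               shape = c("gamma", "gaussian"), shape_k = 16) {
  shape <- match.arg(shape)
  check_scalar(fwhm, "fwhm")
  check_scalar(peak, "peak")
  check_edges(wavelength_edges, "wavelength_edges")
  if (shape == "gamma") {
    if (shape_k <= 1) {
      abort("`shape_k` must be > 1 so the gamma density has a mode.",
            class = "hdim_error_domain")
    }
    scale <- fwhm / gamma_unit_fwhm(shape_k)
    offset <- peak - (shape_k - 1) * scale
    cdf <- pgamma((wavelength_edges - offset) / scale, shape = shape_k)
  } else {
    sdev <- fwhm / (2 * sqrt(2 * log(2)))
    cdf <- pnorm(wavelength_edges, mean = peak, sd = sdev)
  }
  raw <- diff(cdf)
  total <- sum(raw)
  if (total < 1e-6) {
    abort("Spectrum mass inside the detection range is < 1e-6; the peak lies far outside the covered wavelengths.",
          class = "hdim_error_degenerate_spectrum")
  }
  raw / total
}

#' Build a hyper-dimensional spectral signature (HDSS)
#'
#' The HDSS of a fluorophore on a detection grid is its expected per-channel
#' photon-detection probability: the outer product of the spectral bin
#' fractions with the polarization-resolved time-gate fractions
#' (`fractions[pol, lambda, t] = spectrum[lambda] * pol_time[pol, t]`). If the
#' grid's only polarization state is `"unpolarized"` the time factor is the
#' analyzer-free [decay_fractions()] (the sum of both polarization rows).
#'
#' @param fluorophore A [fluorophore()].
#' @param grid A [detection_grid()].
#' @param shape,shape_k Spectral density options passed to
#'   [spectrum_fractions()].
#' @return An object of class `hdss`: a list with the `grid` and a
#'   `pol x wavelength x time` array `fractions` summing to 1.
#' @examples
#' h <- build_hdss(example_fluorophores()$A, default_grid())
#' sum(h$fractions)
#' @export
build_hdss <- function(fluorophore, grid, shape = c("gamma", "gaussian"),
                       shape_k = 16) {
  shape <- match.arg(shape)
  stopifnot(inherits(fluorophore, "fluorophore"),
            inherits(grid, "detection_grid"))
  d <- grid_dims(grid)
  sp <- spectrum_fractions(grid$wavelength_edges, fluorophore$peak_nm,
                           fluorophore$fwhm_nm, shape, shape_k)
  pt2 <- polarized_time_fractions(grid$time_edges, fluorophore$tau_ns,
                                  fluorophore$r0, fluorophore$theta_ns,
                                  grid$laser_period_ns)
  rows <- lapply(grid$polarizations, function(p) {
    switch(p,
           parallel = pt2["parallel", ],
           perpendicular = pt2["perpendicular", ],
           unpolarized = colSums(pt2))
  })
  pt <- do.call(rbind, rows)
  pt <- pt / sum(pt)   # renormalize over the analyzer states actually detected
  arr <- array(0, dim = unname(d))
  for (p in seq_len(d[["pol"]])) {
    arr[p, , ] <- outer(sp, pt[p, ])
  }
  structure(list(grid = grid, fractions = arr,
                 fluorophore = fluorophore$name,
                 dims = c("polarization", "wavelength", "time")),
            class = "hdss")
}

#' @export
print.hdss <- function(x, ...) {
  d <- dim(x$fractions)
  cat(sprintf("<hdss: %s, %s channels (%s)>\n", x$fluorophore,
              prod(d), paste(d, collapse = " x ")))
  invisible(x)
}

# flatten an hdss array (pol, wl, time) to channel order: polarization-major,
# then wavelength, with time fastest
as_channel_vector <- function(x) {
  arr <- if (inherits(x, "hdss")) x$fractions else x
  as.vector(aperm(arr, c(3L, 2L, 1L)))
}

#' Expected per-channel counts of a fluorophore mixture
#'
#' For endmember signatures `g_j` and abundances `a_j` (conventionally summing
#' to 1), the expected count in channel i is `G_i = N * sum_j a_j * g_ij`.
#'
#' @param endmembers A list of [build_hdss()] signatures sharing one grid.
#' @param abundances Non-negative abundance vector, one entry per endmember.
#' @param N Total expected photon count.
#' @return Array of expected counts with the same `pol x wavelength x time`
#'   shape as the signatures.
#' @export
expected_counts <- function(endmembers, abundances, N) {
  stopifnot(length(endmembers) >= 1L, is.numeric(abundances),
            length(abundances) == length(endmembers))
  if (any(abundances < 0)) {
    abort("`abundances` must be non-negative.", class = "hdim_error_domain")
  }
  check_scalar(N, "N", positive = FALSE)
  g0 <- endmembers[[1L]]
  for (e in endmembers[-1L]) {
    if (!grids_compatible(g0$grid, e$grid)) {
      abort("All endmembers must share the same detection grid.",
            class = "hdim_error_incompatible_endmembers")
    }
  }
  out <- array(0, dim = dim(g0$fractions))
  for (j in seq_along(endmembers)) {
    out <- out + abundances[j] * endmembers[[j]]$fractions
  }
  N * out
}

#' Sum a signature or count tensor over detection dimensions
#'
#' Marginalization emulates a simpler instrument: binning all photons along
#' the dropped dimensions (e.g. keeping only `"time"` turns a
#' hyper-dimensional signature into a FLIM signature). Totals are preserved
#' exactly.
#'
#' @param x An `hdss`, or a numeric array whose last three dimensions are
#'   polarization, wavelength, time.
#' @param keep_dims Non-empty subset of `c("polarization", "wavelength",
#'   "time")` to retain.
#' @return Same type as the input, reduced over the dropped dimensions.
#' @export
marginalize <- function(x, keep_dims) {
  dims <- c("polarization", "wavelength", "time")
  if (length(keep_dims) == 0L || !all(keep_dims %in% dims)) {
    abort("`keep_dims` must be a non-empty subset of polarization/wavelength/time.",
          class = "hdim_error_domain")
  }
  keep <- which(dims %in% keep_dims)
  if (inherits(x, "hdss")) {
    red <- apply(x$fractions, keep, sum)
    out <- x
    out$fractions <- array(red, dim = dim(x$fractions)[keep])
    out$dims <- dims[keep]
    return(out)
  }
  nd <- length(dim(x))
  if (nd == 3L) {
    res <- apply(x, keep, sum)
    return(array(res, dim = dim(x)[keep]))
  }
  # image tensors: leading pixel dimensions are always kept
  lead <- seq_len(nd - 3L)
  res <- apply(x, c(lead, nd - 3L + keep), sum)
  array(res, dim = dim(x)[c(lead, nd - 3L + keep)])
}
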