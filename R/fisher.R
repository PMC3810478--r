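# Poisson-channel Fisher information and photon-economy metrics.
#
# For independent Poisson channels with expected counts G_i(x) = N * f_i(x),
# the Fisher information about x is I = sum_i (dG_i/dx)^2 / G_i. All
# F-values derive from its inverse (the Cramer-Rao bound).

ZERO_FRACTION <- 1e-12  # channels below this are dropped from the Eq. sum

#' Fisher information about a scalar parameter
#'
#' Evaluates `I = N * sum_i (df_i/dx)^2 / f_i` for a signature function
#' `sig(x)` returning per-channel fractions, using central finite differences
#' with relative step `delta`. Channels with `f_i < 1e-12` are excluded: their
#' information contribution vanishes but the division is numerically unstable.
#'
#' @param sig Function mapping a scalar parameter to a vector of channel
#'   fractions summing to 1.
#' @param x0 Parameter value at which to evaluate the information.
#' @param N Total photon count (the information is proportional to N).
#' @param delta Relative finite-difference step (default 0.01).
#' @return Total Fisher information (a scalar, units `1/x^2`).
#' @examples
#' sig <- function(tau) decay_fractions(seq(0, 50, length.out = 257), tau, 50)
#' fisher_scalar(sig, x0 = 2, N = 1000)   # close to N / tau^2
#' @export
fisher_scalar <- function(sig, x0, N, delta = 0.01) {
  check_scalar(delta, "delta")
  check_scalar(x0, "x0")
  f0 <- sig(x0)
  if (any(f0 < -1e-12)) {
    abort("Signature returned negative fractions.",
          class = "hdim_error_invalid_signature")
  }
  h <- delta * abs(x0)
  df <- (sig(x0 + h) - sig(x0 - h)) / (2 * h)
  keep <- f0 > ZERO_FRACTION
  if (!any(keep) || all(abs(df[keep]) < 1e-300)) return(0)
  N * sum(df[keep]^2 / f0[keep])
}

#' Photon-economy F-value of a scalar estimate
#'
#' `F = (sigma_x / x) * sqrt(N)`: the relative error of the best unbiased
#' estimate of `x` compared with the Poisson (shot-noise) limit. `F = 1` means
#' the measurement uses every photon as efficiently as direct counting;
#' F is independent of `N`.
#'
#' @inheritParams fisher_scalar
#' @return The F-value; `Inf` with a warning when the partition carries no
#'   information.
#' @export
f_value_scalar <- function(sig, x0, N = 1, delta = 0.01) {
  info <- fisher_scalar(sig, x0, N, delta)
  if (info <= 0) {
    warn("Information-free partition: F-value is infinite.")
    return(Inf)
  }
  sqrt(N / info) / abs(x0)
}

#' Analytic F-value of a two-gate lifetime system
#'
#' For two adjacent time gates with boundary at `u = t/tau` (laser period much
#' longer than the lifetime), `F(u) = sqrt(exp(u) - 1) / u`. The function
#' diverges at both `u -> 0` (vanishing first gate information) and
#' `u -> Inf` (empty second gate).
#'
#' @param u Reduced gate boundary `t / tau`, > 0.
#' @return F-value(s), vectorized over `u`.
#' @export
two_gate_f_curve <- function(u) {
  if (any(u <= 0)) abort("`u` must be > 0.", class = "hdim_error_domain")
  sqrt(expm1(u)) / u
}

#' Optimal boundary of a two-gate lifetime system
#'
#' Minimizes [two_gate_f_curve()] over the reduced boundary; the optimum
#' solves `u * exp(u) = 2 * (exp(u) - 1)`.
#'
#' @return A list with `u_opt` (in units of the lifetime) and `f_opt`.
#' @examples
#' two_gate_optimum()   # u ~ 1.59, F ~ 1.24
#' @export
two_gate_optimum <- function() {
  opt <- optimize(two_gate_f_curve, interval = c(0.05, 10), tol = 1e-10)
  list(u_opt = opt$minimum, f_opt = opt$objective)
}

#' Fisher-information gain from splitting one channel
#'
#' Splitting a channel with expected count `G` by a partitioning function
#' `phi` (the fraction going to the first daughter channel) yields an
#' information gain `dI = G * (dphi/dx)^2 / (phi * (1 - phi))`. The gain is
#' zero iff the split is trivial (`dphi/dx = 0`).
#'
#' @param G Expected photon count of the channel being split, > 0.
#' @param phi Partition fraction in (0, 1).
#' @param dphi_dx Derivative of the partition fraction w.r.t. the parameter.
#' @return The (non-negative) information gain.
#' @export
split_gain <- function(G, phi, dphi_dx) {
  check_scalar(G, "G")
  if (!is.numeric(phi) || length(phi) != 1L || phi <= 0 || phi >= 1) {
    abort("`phi` must lie strictly inside (0, 1).",
          class = "hdim_error_degenerate_split")
  }
  G * dphi_dx^2 / (phi * (1 - phi))
}

#' Abundance Fisher matrix for a fluorophore mixture
#'
#' For the linear mixing model `G_i = N * sum_j a_j g_ij` the derivatives are
#' analytic (`dG_i/da_j = N * g_ij`) and the Fisher matrix is
#' `I_jk = N * sum_i g_ij g_ik / (sum_l a_l g_il)`. Its inverse is the
#' covariance bound on the abundance estimates. The per-parameter F-value
#' compares each abundance's uncertainty with the Poisson limit of counting
#' that fluorophore's own `a_j * N` photons:
#' `F_j = sigma_j * sqrt(N / a_j)`, so fully disjoint signatures give
#' `F_j = 1` (shot-limited unmixing). The combined F is the unweighted mean
#' of the per-parameter values.
#'
#' @param endmembers List of `hdss` objects on one grid, or a numeric matrix
#'   (channels x fluorophores) of signature fractions.
#' @param abundances Positive abundance vector; fractions `a_j / sum(a)` are
#'   used for normalization.
#' @param N Total photon count (default 1; F-values do not depend on it).
#' @return A `fisher_fit` object with elements `information` (total),
#'   `covariance`, `per_param_F`, `combined_F`, `abundances`, `N`,
#'   `n_channels`.
#' @examples
#' fl <- example_fluorophores()
#' g <- default_grid()
#' fisher_matrix(list(build_hdss(fl$A, g), build_hdss(fl$B, g)), c(0.5, 0.5))
#' @export
fisher_matrix <- function(endmembers, abundances, N = 1) {
  if (is.matrix(endmembers)) {
    g <- endmembers
  } else {
    g0 <- endmembers[[1L]]
    for (e in endmembers[-1L]) {
      if (!all(dim(e$fractions) == dim(g0$fractions))) {
        abort("All endmembers must share the same detection grid.",
              class = "hdim_error_incompatible_endmembers")
      }
    }
    g <- vapply(endmembers, as_channel_vector, numeric(length(as_channel_vector(g0))))
  }
  k <- ncol(g)
  if (k < 2L) abort("At least two endmembers are required.",
                    class = "hdim_error_domain")
  if (!is.numeric(abundances) || length(abundances) != k || any(abundances <= 0)) {
    abort("`abundances` must be positive, one entry per endmember.",
          class = "hdim_error_domain")
  }
  check_scalar(N, "N")
  frac <- abundances / sum(abundances)
  denom <- as.vector(g %*% frac)
  keep <- denom > ZERO_FRACTION
  info <- N * crossprod(g[keep, , drop = FALSE],
                        g[keep, , drop = FALSE] / denom[keep])
  covariance <- tryCatch(
    solve(info),
    error = function(e) {
      # constant columns make cor() warn; the NA result is simply not a match
      cors <- suppressWarnings(stats::cor(g))
      pair <- which(!is.na(cors) & abs(cors - 1) < 1e-10 & upper.tri(cors),
                    arr.ind = TRUE)
      msg <- if (nrow(pair) > 0) {
        sprintf("Fisher matrix is singular: endmembers %d and %d are identical (or proportional).",
                pair[1, 1], pair[1, 2])
      } else "Fisher matrix is singular."
      abort(msg, class = "hdim_error_singular")
    }
  )
  per_param_F <- sqrt(N * diag(covariance) / frac)
  structure(
    list(information = info, covariance = covariance,
         per_param_F = per_param_F, combined_F = mean(per_param_F),
         abundances = frac, N = N, n_channels = sum(keep)),
    class = "fisher_fit"
  )
}

#' @export
print.fisher_fit <- function(x, ...) {
  cat(sprintf("<fisher_fit: %d channels, N = %g>\n", x$n_channels, x$N))
  cat("  abundances:", paste(signif(x$abundances, 4), collapse = ", "), "\n")
  cat("  per-parameter F:", paste(signif(x$per_param_F, 4), collapse = ", "),
      "\n")
  cat(sprintf("  combined F = %.4g (photon efficiency %.3g)\n",
              x$combined_F, photon_efficiency(x$combined_F)))
  invisible(x)
}

#' Photon efficiency from an F-value
#'
#' `p = F^-2`: the fraction of detected photons effectively contributing to
#' the estimate, relative to a shot-limited measurement.
#'
#' @param F F-value, > 0.
#' @return Efficiency in (0, Inf); 1 at the shot limit.
#' @export
photon_efficiency <- function(F) {
  if (any(F <= 0)) abort("`F` must be > 0.", class = "hdim_error_domain")
  F^-2
}

#' Photons required for a target relative error
#'
#' At photon economy `F`, reaching relative error `rel_error` requires
#' `N = (F / rel_error)^2` photons; a shot-limited measurement (`F = 1`)
#' reaches 5% with 400 photons.
#'
#' @param F F-value.
#' @param rel_error Target relative error (default 0.05).
#' @return Required photon count (not rounded).
#' @export
photons_required <- function(F, rel_error = 0.05) {
  check_scalar(rel_error, "rel_error")
  if (any(F <= 0)) abort("`F` must be > 0.", class = "hdim_error_domain")
  (F / rel_error)^2
}

#' Separability of two biochemical signatures
#'
#' `S = |x1 - x2| / sqrt(sigma1^2 + sigma2^2)`: the distance between two
#' parameter values in units of their combined estimation uncertainty. `S = 2`
#' plays the role of the Rayleigh criterion for biochemical resolution.
#'
#' @param x1,x2 Parameter values characterizing the two environments.
#' @param sigma1,sigma2 Estimation uncertainties, > 0.
#' @return Separability S >= 0.
#' @export
separability <- function(x1, sigma1, x2, sigma2) {
  if (any(c(sigma1, sigma2) <= 0)) {
    abort("`sigma1` and `sigma2` must be > 0.", class = "hdim_error_domain")
  }
  abs(x1 - x2) / sqrt(sigma1^2 + sigma2^2)
}

#' Biochemical resolution and resolving power
#'
#' Applying the Rayleigh-equivalent criterion `S = 2` with equal
#' uncertainties `sigma = x0 * F / sqrt(N)` gives the smallest resolvable
#' difference `dx = 2 * sqrt(2) * x0 / sqrt(p * N)` and resolving power
#' `R = x0 / dx = sqrt(p * N) / (2 * sqrt(2))`, where `p` is the photon
#' efficiency.
#'
#' @param x0 Parameter value around which resolution is evaluated.
#' @param p Photon efficiency in (0, 1].
#' @param N Photon count, > 0.
#' @return A list with `delta_x` and `resolving_power` (their product is
#'   exactly `x0`).
#' @export
resolution_and_power <- function(x0, p, N) {
  check_scalar(x0, "x0")
  check_scalar(N, "N")
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p > 1) {
    abort("`p` must lie in (0, 1].", class = "hdim_error_domain")
  }
  delta_x <- 2 * sqrt(2) * x0 / sqrt(p * N)
  list(delta_x = delta_x, resolving_power = x0 / delta_x)
}

#' Channel cost from detector dark counts
#'
#' A single-photon detector with dark count rate `dcr` and maximum count rate
#' `mcr` contributes a relative cost `epsilon = (dcr / mcr) / N` when a
#' channel is added, usable as the split-acceptance threshold of the
#' partition optimizers.
#'
#' @param dcr Dark count rate (Hz), >= 0.
#' @param mcr Maximum count rate (Hz), > 0.
#' @param N Photons counted in the measurement, > 0.
#' @return The dimensionless cost epsilon.
#' @export
cost_from_dark_counts <- function(dcr, mcr, N) {
  check_scalar(mcr, "mcr")
  check_scalar(N, "N")
  if (!is.numeric(dcr) || length(dcr) != 1L || dcr < 0) {
    abort("`dcr` must be >= 0.", class = "hdim_error_domain")
  }
  (dcr / mcr) / N
}
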