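# broom-style tidiers for fitted Fisher objects.

#' Tidy an abundance Fisher fit
#'
#' One row per fluorophore: its relative abundance, the Cramer-Rao standard
#' error at the fit's photon count, and the per-parameter F-value.
#'
#' @param x A `fisher_fit` from [fisher_matrix()].
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`, `f_value`.
#' @method tidy fisher_fit
#' @export
tidy.fisher_fit <- function(x, ...) {
  k <- length(x$abundances)
  tibble(term = paste0("abundance_", seq_len(k)),
         estimate = unname(x$abundances),
         std.error = sqrt(diag(x$covariance)),
         f_value = unname(x$per_param_F))
}

#' Glance at an abundance Fisher fit
#'
#' @param x A `fisher_fit`.
#' @param ... Unused.
#' @return A one-row tibble with `combined_F`, `photon_efficiency`,
#'   `photons_5pct` (photons for 5% relative error, `round(F^2 * 400)`),
#'   `n_channels` and `N`.
#' @method glance fisher_fit
#' @export
glance.fisher_fit <- function(x, ...) {
  tibble(combined_F = x$combined_F,
         photon_efficiency = photon_efficiency(x$combined_F),
         photons_5pct = round(photons_required(x$combined_F)),
         n_channels = x$n_channels,
         N = x$N)
}

#' Analytic two-gate F-value curve as a plot
#'
#' The F-value of a two-gate lifetime system versus the reduced boundary
#' `u = t / tau`, with its minimum marked.
#'
#' @param u_max Upper end of the plotted range (default 6).
#' @return A ggplot object.
#' @export
plot_two_gate_curve <- function(u_max = 6) {
  opt <- two_gate_optimum()
  ggplot2::ggplot() +
    ggplot2::geom_function(fun = two_gate_f_curve,
                           xlim = c(0.05, u_max)) +
    ggplot2::annotate("point", x = opt$u_opt, y = opt$f_opt, colour = "red") +
    ggplot2::labs(x = "reduced gate boundary u = t / tau", y = "F-value") +
    ggplot2::coord_cartesian(ylim = c(1, 5)) +
    ggplot2::theme_minimal()
}
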