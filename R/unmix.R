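# Linear abundance unmixing and accuracy/precision figures of merit.

# coerce image / count tensor to a channels x pixels matrix plus pixel dims;
# channel order matches as_channel_vector (pol-major, time fastest)
counts_matrix <- function(x) {
  counts <- if (inherits(x, "hdim_image")) x$counts else x
  d <- dim(counts)
  nd <- length(d)
  if (is.null(d) || nd < 3L) {
    abort("Count tensor must have rows, cols and at least one channel dimension.",
          class = "hdim_error_shape")
  }
  # dims 3..nd are channel dimensions ordered (pol, wavelength, time); the
  # flattened channel index runs with the last dimension (time) fastest
  chdims <- seq(3L, nd)
  flat <- aperm(counts, c(rev(chdims), 1L, 2L))
  dim(flat) <- c(prod(d[chdims]), d[1L] * d[2L])
  list(mat = flat, rows = d[1L], cols = d[2L])
}

endmember_matrix <- function(endmembers) {
  if (is.matrix(endmembers)) return(endmembers)
  vapply(endmembers, as_channel_vector,
         numeric(length(as_channel_vector(endmembers[[1L]]))))
}

#' Least-squares abundance unmixing of a multi-channel image
#'
#' Solves, pixel by pixel, the linear mixing model
#' `counts = N * emHDSS %*% a` in the least-squares sense, and reports
#' fractional abundances `a_j / sum(a)`. The unconstrained solution (a single
#' QR solve for the whole image) is the default; `nonneg = TRUE` constrains
#' `a >= 0` (solved per pixel). Negative unconstrained estimates are kept,
#' not clipped, so downstream bias/precision metrics stay unbiased.
#'
#' @param image An `hdim_image`, or a numeric count tensor of dim
#'   `(rows, cols, channels)` or `(rows, cols, pol, wavelength, time)`.
#' @param endmembers List of `hdss` signatures, or a channels x fluorophores
#'   matrix (e.g. from [estimate_endmembers_from_rows()]).
#' @param nonneg Use non-negative least squares (default `FALSE`).
#' @return Numeric array `(rows, cols, n_fluorophores)` of fractional
#'   abundances.
#' @export
lstsq_unmix <- function(image, endmembers, nonneg = FALSE) {
  cm <- counts_matrix(image)
  E <- endmember_matrix(endmembers)
  if (nrow(E) != nrow(cm$mat)) {
    abort(sprintf("Endmembers have %d channels but the image has %d.",
                  nrow(E), nrow(cm$mat)),
          class = "hdim_error_incompatible_endmembers")
  }
  if (qr(E)$rank < ncol(E)) {
    abort("Endmember matrix is rank deficient.",
          class = "hdim_error_singular")
  }
  if (nonneg) {
    coefs <- apply(cm$mat, 2L, function(y) pracma::lsqnonneg(E, y)$x)
  } else {
    coefs <- qr.coef(qr(E), cm$mat)
  }
  totals <- colSums(coefs)
  fracs <- sweep(coefs, 2L, totals, "/")
  out <- array(t(fracs), dim = c(cm$rows, cm$cols, ncol(E)))
  out
}

#' Estimate endmember signatures from the pure ends of a gradient image
#'
#' In the synthetic gradient layout the pixels at the two ends of the
#' abundance ramp are pure fluorophore B (first column) and pure fluorophore A
#' (last column); each endmember signature is the mean over that column's
#' replicate pixels, renormalized to sum to 1.
#'
#' @param image An `hdim_image` (gradient along columns, replicates along
#'   rows).
#' @return A channels x 2 matrix with columns `(A, B)`, matching the
#'   fluorophore order of [simulate_gradient_image()].
#' @export
estimate_endmembers_from_rows <- function(image) {
  stopifnot(inherits(image, "hdim_image"))
  cm <- counts_matrix(image)
  idx <- matrix(seq_len(cm$rows * cm$cols), cm$rows, cm$cols)
  pureB <- rowMeans(cm$mat[, idx[, 1L], drop = FALSE])
  pureA <- rowMeans(cm$mat[, idx[, cm$cols], drop = FALSE])
  if (sum(pureA) <= 0 || sum(pureB) <= 0) {
    abort("A pure end of the gradient has zero total counts.",
          class = "hdim_error_degenerate_endmember")
  }
  cbind(A = pureA / sum(pureA), B = pureB / sum(pureB))
}

#' Unmixing accuracy (bias) figure of merit
#'
#' Mean over all pixels of `true - estimated` for the reference (first)
#' fluorophore's fractional abundance; 0 for a perfectly calibrated
#' estimator, negative when abundances are overestimated.
#'
#' @param true_fractions,estimated_fractions Matching arrays (rows x cols, or
#'   rows x cols x fluorophores, in which case the first fluorophore is used).
#' @return Scalar bias.
#' @export
accuracy_bias <- function(true_fractions, estimated_fractions) {
  tf <- ref_fraction(true_fractions)
  ef <- ref_fraction(estimated_fractions)
  if (!all(dim(tf) == dim(ef))) {
    abort("`true_fractions` and `estimated_fractions` must have the same shape.",
          class = "hdim_error_shape")
  }
  mean(tf - ef)
}

ref_fraction <- function(x) {
  if (length(dim(x)) == 3L) x[, , 1L] else x
}

#' Unmixing precision figure of merit
#'
#' Each image column holds replicate estimates of the same abundance; the
#' figure of merit is the mean over columns of the replicate standard
#' deviation, normalized by Poisson noise: `mean_cols(sd_rows) * sqrt(N)`.
#' Lower is better; it is bounded below by the Cramer-Rao combined F of the
#' same detection grid.
#'
#' @param estimated_fractions Estimated abundance array (rows x cols or
#'   rows x cols x fluorophores; the first fluorophore is scored).
#' @param N Expected photons per pixel.
#' @return Scalar dimensionless precision figure.
#' @export
precision_sigma <- function(estimated_fractions, N) {
  check_scalar(N, "N")
  ef <- ref_fraction(estimated_fractions)
  if (is.null(dim(ef)) || nrow(ef) < 2L) {
    abort("At least 2 replicate rows are required to estimate precision.",
          class = "hdim_error_undefined_variance")
  }
  mean(apply(ef, 2L, sd)) * sqrt(N)
}

#' Bias and precision of unmixing across detection modalities
#'
#' Convenience benchmark: marginalizes a gradient image (and endmembers
#' estimated from its pure ends) onto each requested technique, unmixes, and
#' reports the accuracy and precision figures of merit.
#'
#' @param image An `hdim_image` from [simulate_gradient_image()].
#' @param techniques Character vector of technique names (subset of
#'   `names(technique_dims())`, default SPEC/SLIM/HDIM).
#' @param nonneg Passed to [lstsq_unmix()].
#' @return A tibble with columns `technique`, `n_channels`, `bias`,
#'   `precision`.
#' @export
unmix_benchmark <- function(image, techniques = c("SPEC", "SLIM", "HDIM"),
                            nonneg = FALSE) {
  stopifnot(inherits(image, "hdim_image"))
  dims <- technique_dims()
  if (!all(techniques %in% names(dims))) {
    abort("Unknown technique name.", class = "hdim_error_domain")
  }
  E_full <- estimate_endmembers_from_rows(image)
  d <- grid_dims(image$grid)
  rows <- map(techniques, function(tech) {
    keep <- dims[[tech]]
    cnt <- marginalize(image$counts, keep)
    keep_idx <- which(c("polarization", "wavelength", "time") %in% keep)
    E <- marginalize_endmembers(E_full, d, keep_idx)
    fr <- lstsq_unmix(cnt, E, nonneg = nonneg)
    tibble(technique = tech,
           n_channels = nrow(E),
           bias = accuracy_bias(image$true_abundances, fr),
           precision = precision_sigma(fr, image$expected_N))
  })
  bind_rows(rows)
}

# marginalize flattened endmember columns (pol-major, time fastest) onto the
# kept dimensions, preserving flattening conventions
marginalize_endmembers <- function(E, d, keep_idx) {
  out <- apply(E, 2L, function(col) {
    arr <- array(col, dim = unname(d[c("time", "wavelength", "pol")]))
    arr <- aperm(arr, c(3L, 2L, 1L))        # back to (pol, wl, time)
    as.vector(aperm(array(apply(arr, keep_idx, sum),
                          dim = dim(arr)[keep_idx]),
                    rev(seq_along(keep_idx))))
  })
  out
}
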