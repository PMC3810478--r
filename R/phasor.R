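# Phasor transforms: first-harmonic cosine/sine projections of decays,
# spectra, and the joint time-spectrum plane; the 16-coefficient
# hyper-dimensional phasor (HDPH) reduction.
#
# The unnormalized (projection) convention is used throughout so every
# transform is exactly linear in the counts and linear unmixing carries over
# to phasor space unchanged. Normalized (divide-by-total) phasors are offered
# only for display.

phasor_basis <- function(n, harmonic = 1) {
  ang <- 2 * pi * harmonic * (seq_len(n) - 0.5) / n
  list(cos = cos(ang), sin = sin(ang))
}

#' First-harmonic time phasor of a gated decay
#'
#' `cos = sum_t c_t * cos(2 pi h (t + 1/2) / n)` and the matching sine sum
#' over the `n` time gates (0-based gate index `t`).
#'
#' @param band_counts Counts over the time gates (length >= 2).
#' @param harmonic Harmonic number (default 1).
#' @param normalize Divide by the total count (for phasor-plot display).
#' @return Named numeric vector `c(cos, sin)`.
#' @export
time_phasor <- function(band_counts, harmonic = 1, normalize = FALSE) {
  n <- length(band_counts)
  if (n < 2L) abort("At least 2 gates are required.", class = "hdim_error_shape")
  b <- phasor_basis(n, harmonic)
  out <- c(cos = sum(band_counts * b$cos), sin = sum(band_counts * b$sin))
  if (normalize) out <- out / sum(band_counts)
  out
}

#' First-harmonic spectral phasor
#'
#' The same cosine/sine projection as [time_phasor()], taken along the
#' spectral bins.
#'
#' @param spectral_counts Counts over the spectral bins (length >= 2).
#' @inheritParams time_phasor
#' @return Named numeric vector `c(cos, sin)`.
#' @export
spectral_phasor <- function(spectral_counts, harmonic = 1, normalize = FALSE) {
  time_phasor(spectral_counts, harmonic, normalize)
}

#' First-harmonic two-dimensional time-spectrum phasor
#'
#' Separable 2-D projection over the joint wavelength x time plane:
#' `cos = sum_{l,t} c_{l,t} cos(2 pi (l + 1/2) / n_l) * cos(2 pi (t + 1/2) / n_t)`
#' and the corresponding sine-product sum. For a separable input
#' `c_{l,t} = u_l * v_t` the 2-D coefficients factor into the 1-D ones.
#'
#' @param time_spectral_counts Matrix (wavelength bins x time gates) for one
#'   polarization state.
#' @param normalize Divide by the total count.
#' @return Named numeric vector `c(cos, sin)`.
#' @export
hd_phasor_2d <- function(time_spectral_counts, normalize = FALSE) {
  if (!is.matrix(time_spectral_counts)) {
    abort("`time_spectral_counts` must be a wavelength x time matrix.",
          class = "hdim_error_shape")
  }
  bl <- phasor_basis(nrow(time_spectral_counts))
  bt <- phasor_basis(ncol(time_spectral_counts))
  out <- c(cos = as.numeric(bl$cos %*% time_spectral_counts %*% bt$cos),
           sin = as.numeric(bl$sin %*% time_spectral_counts %*% bt$sin))
  if (normalize) out <- out / sum(time_spectral_counts)
  out
}

#' Hyper-dimensional phasor (HDPH) reduction of one pixel
#'
#' Reduces a full `2 x n_wavelength x n_time` channel tensor to 16 linear
#' coefficients: per polarization state, time-phasor cosine/sine over each of
#' two spectral halves (8 coefficients), spectral-phasor cosine/sine (4), and
#' 2-D time-spectrum phasor cosine/sine (4). The spectral halves split at the
#' bin edge closest to `split_nm` (default 540 nm, i.e. bands of roughly
#' 440-540 and 540-630 nm on the reference grid).
#'
#' @param pixel_counts Numeric array `2 x n_wavelength x n_time`
#'   (polarization, wavelength, time).
#' @param grid Optional [detection_grid()] used to locate the spectral split
#'   edge; without it the bins are halved at `n_wavelength / 2`.
#' @param split_nm Wavelength (nm) separating the two spectral bands.
#' @return Named numeric vector of 16 coefficients (class `hdph`).
#' @examples
#' x <- array(rpois(2 * 16 * 64, 5), c(2, 16, 64))
#' length(hdph_transform(x))
#' @export
hdph_transform <- function(pixel_counts, grid = NULL, split_nm = 540) {
  d <- dim(pixel_counts)
  if (length(d) != 3L || d[1L] != 2L || d[2L] < 2L || d[3L] < 2L) {
    abort("`pixel_counts` must be a 2 x n_wavelength x n_time array.",
          class = "hdim_error_shape")
  }
  nw <- d[2L]
  split_bin <- if (!is.null(grid)) {
    which.min(abs(grid$wavelength_edges - split_nm)) - 1L
  } else {
    nw %/% 2L
  }
  split_bin <- min(max(split_bin, 1L), nw - 1L)
  halves <- list(lo = seq_len(split_bin), hi = seq(split_bin + 1L, nw))
  pols <- c("par", "perp")
  out <- numeric(0)
  for (p in 1:2) {
    for (h in names(halves)) {
      tp <- time_phasor(colSums(pixel_counts[p, halves[[h]], , drop = FALSE],
                                dims = 2L))
      names(tp) <- paste("time", pols[p], h, names(tp), sep = "_")
      out <- c(out, tp)
    }
  }
  for (p in 1:2) {
    sp <- spectral_phasor(rowSums(pixel_counts[p, , ]))
    names(sp) <- paste("spectral", pols[p], names(sp), sep = "_")
    out <- c(out, sp)
  }
  for (p in 1:2) {
    jp <- hd_phasor_2d(pixel_counts[p, , ])
    names(jp) <- paste("joint2d", pols[p], names(jp), sep = "_")
    out <- c(out, jp)
  }
  structure(out, class = "hdph")
}

#' HDPH reduction of a whole image
#'
#' Applies [hdph_transform()] to every pixel, turning a
#' `(rows, cols, 2, n_wavelength, n_time)` count tensor into a
#' `(rows, cols, 16)` coefficient tensor that can be unmixed with
#' [lstsq_unmix()] against HDPH-transformed endmembers (the transform is
#' linear, so the mixing model is exact in phasor space).
#'
#' @param image An `hdim_image` or a 5-d count tensor.
#' @inheritParams hdph_transform
#' @return Numeric array `(rows, cols, 16)`; coefficient labels in
#'   `dimnames(...)[[3]]`.
#' @export
hdph_image <- function(image, grid = NULL, split_nm = 540) {
  counts <- if (inherits(image, "hdim_image")) {
    grid <- grid %||% image$grid
    image$counts
  } else image
  d <- dim(counts)
  if (length(d) != 5L) {
    abort("Expected a (rows, cols, pol, wavelength, time) tensor.",
          class = "hdim_error_shape")
  }
  first <- hdph_transform(array(counts[1, 1, , , ], d[3:5]), grid, split_nm)
  out <- array(0, dim = c(d[1L], d[2L], 16L),
               dimnames = list(NULL, NULL, names(first)))
  for (i in seq_len(d[1L])) {
    for (j in seq_len(d[2L])) {
      out[i, j, ] <- hdph_transform(array(counts[i, j, , , ], d[3:5]),
                                    grid, split_nm)
    }
  }
  out
}

#' HDPH signature of an endmember
#'
#' The HDPH coefficients of an endmember's expected counts; because the
#' transform is linear these are the columns of the phasor-space mixing
#' matrix.
#'
#' @param hdss An `hdss` signature (2 polarization states).
#' @inheritParams hdph_transform
#' @return Named numeric vector of 16 coefficients.
#' @export
hdph_endmember <- function(hdss, split_nm = 540) {
  as.numeric(hdph_transform(hdss$fractions, hdss$grid, split_nm))
}
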