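# Forward photophysical models: decays, anisotropy, spectra, signatures.

test_that("decay_fractions matches closed forms and quadrature", {
  # single all-covering gate
  expect_equal(decay_fractions(c(0, 12.5), tau = 2, T = 12.5), 1.0)

  # frozen example: boundary at tau * log(2) splits photons ~50/50
  expect_equal(round(decay_fractions(c(0, 1.3863, 12.5), 2, 12.5), 4),
               c(0.5010, 0.4990))

  # boundary at 1.59 * tau with a long period: closed-form exponentials
  fr <- decay_fractions(c(0, 1.59 * 2, 50), 2, 50)
  expect_equal(fr, c(0.7960, 0.2040), tolerance = 2e-4)

  # property: agreement with the quadrature oracle on random partitions
  set.seed(41)
  for (i in 1:20) {
    tau <- runif(1, 0.5, 5)
    T <- runif(1, 8, 40)
    edges <- sort(c(0, runif(sample(2:6, 1), 0, T), T))
    f <- decay_fractions(edges, tau, T)
    expect_equal(f, quad_decay_fractions(edges, tau, T), tolerance = 1e-8)
    expect_equal(sum(f), 1, tolerance = 1e-9)
  }
})

test_that("decay_fractions handles the periodic wrap and rejects bad input", {
  tau <- 2
  # with T = 25 tau the periodic normalization is indistinguishable from T -> Inf
  edges25 <- c(0, 2, 5, 25 * tau)
  f25 <- decay_fractions(edges25, tau, 25 * tau)
  finf <- (exp(-c(0, 2, 5) / tau) - exp(-c(2, 5, 50) / tau))
  expect_lt(max(abs(f25 - finf) / finf), 2e-11)

  expect_error(decay_fractions(c(0, 5, 3, 12.5), 2, 12.5),
               class = "hdim_error_invalid_partition")
  expect_error(decay_fractions(c(0, 12.5), -1, 12.5),
               class = "hdim_error_domain")
  expect_error(decay_fractions(c(0, 15), 2, 12.5),
               class = "hdim_error_invalid_partition")
})

test_that("polarized fractions reduce correctly and match quadrature", {
  edges <- seq(0, 12.5, length.out = 65)

  # isotropic emission: both analyzer rows are half the plain decay
  pt0 <- polarized_time_fractions(edges, 3, r0 = 0, theta = 12, T = 12.5)
  expect_equal(pt0["parallel", ], pt0["perpendicular", ])
  expect_equal(pt0["parallel", ], decay_fractions(edges, 3, 12.5) / 2)

  # limiting-anisotropy identity: instantaneous intensity ratio at t = 0
  # is (1 + 2 r0) / (1 - r0) = 3 for r0 = 0.4 (probed with a narrow gate)
  nr <- polarized_time_fractions(c(0, 1e-5, 12.5), 3, 0.4, 12, 12.5)
  expect_equal(unname(nr["parallel", 1] / nr["perpendicular", 1]), 3,
               tolerance = 1e-4)

  # conservation and quadrature oracle
  pt <- polarized_time_fractions(edges, 3, 0.4, 12, 12.5)
  expect_equal(sum(pt), 1, tolerance = 1e-12)
  expect_true(all(pt >= 0))
  expect_equal(pt, quad_pol_fractions(edges, 3, 0.4, 12, 12.5),
               tolerance = 1e-10)

  expect_error(polarized_time_fractions(edges, 3, 0.7, 12, 12.5),
               class = "hdim_error_domain")
})

test_that("spectrum_fractions integrates the stated densities", {
  # one bin covering essentially all support
  expect_equal(spectrum_fractions(c(200, 900), 500, 50), 1.0)

  # gaussian symmetry around the peak
  expect_equal(spectrum_fractions(c(400, 500, 600), 500, 50, "gaussian"),
               c(0.5, 0.5))

  # gamma density vs adaptive quadrature, 16 bins over the detection band
  edges <- seq(440, 630, length.out = 17)
  f <- spectrum_fractions(edges, 500, 50, "gamma")
  expect_equal(f, quad_gamma_fractions(edges, 500, 50), tolerance = 1e-8)
  expect_equal(sum(f), 1, tolerance = 1e-12)

  # requested peak/width are actually realized (sanity on the
  # mode/FWHM reparameterization, checked on a fine grid)
  fine <- seq(300, 800, by = 0.1)
  ff <- spectrum_fractions(fine, 500, 50, "gamma")
  expect_equal(fine[which.max(ff)], 500, tolerance = 0.2)

  expect_error(spectrum_fractions(c(1000, 1100), 500, 20),
               class = "hdim_error_degenerate_spectrum")
})

test_that("build_hdss is a normalized outer product of its factors", {
  fl <- example_fluorophores()

  # degenerate 1 x 1 x 1 grid
  g1 <- detection_grid(c(0, 12.5), 12.5, c(440, 630), "unpolarized")
  expect_equal(as.vector(build_hdss(fl$A, g1)$fractions), 1.0)

  # separability: the (pol, time) marginal reproduces the spectrum exactly
  g <- tiny_grid()
  h <- build_hdss(fl$A, g)
  expect_equal(as.vector(marginalize(h, "wavelength")$fractions),
               spectrum_fractions(g$wavelength_edges, fl$A$peak_nm,
                                  fl$A$fwhm_nm),
               tolerance = 1e-12)

  # reference grid: 2048 non-negative entries summing to one
  hfull <- build_hdss(fl$A, default_grid())
  expect_equal(length(hfull$fractions), 2048L)
  expect_true(all(hfull$fractions >= 0))
  expect_equal(sum(hfull$fractions), 1, tolerance = 1e-9)

  # analyzer-free detection sums the two polarization components, so the
  # time profile keeps its anisotropy weighting
  gu <- detection_grid(seq(0, 12.5, length.out = 17), 12.5, c(440, 630),
                       "unpolarized")
  hu <- build_hdss(fl$A, gu)
  pt <- polarized_time_fractions(gu$time_edges, fl$A$tau_ns, fl$A$r0,
                                 fl$A$theta_ns, 12.5)
  expect_equal(as.vector(marginalize(hu, "time")$fractions), colSums(pt),
               tolerance = 1e-12)
})

test_that("expected_counts mixes endmembers linearly and conserves photons", {
  fl <- example_fluorophores()
  g <- tiny_grid()
  hA <- build_hdss(fl$A, g)
  hB <- build_hdss(fl$B, g)

  expect_equal(expected_counts(list(hA), 1, 1000), 1000 * hA$fractions)

  # mixing identical endmembers is degenerate
  expect_equal(expected_counts(list(hA, hA), c(0.5, 0.5), 500),
               expected_counts(list(hA), 1, 500))

  ec <- expected_counts(list(hA, hB), c(0.3, 0.7), 250)
  expect_equal(sum(ec), 250, tolerance = 1e-9)

  g2 <- default_grid(n_time = 8, n_spectral = 8)
  expect_error(expected_counts(list(hA, build_hdss(fl$B, g2)), c(0.5, 0.5), 1),
               class = "hdim_error_incompatible_endmembers")
})
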