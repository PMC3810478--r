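# Poisson-channel Fisher information, F-values and derived metrics.

test_that("fisher_scalar recovers exponential-distribution closed forms", {
  # a single all-covering channel carries no information
  expect_equal(fisher_scalar(function(x) 1, x0 = 2, N = 100), 0)

  # fine partition, long period: I -> N / tau^2 (exponential distribution)
  edges <- seq(0, 50, length.out = 257)
  sig <- function(tau) decay_fractions(edges, tau, 50)
  info <- fisher_scalar(sig, x0 = 2, N = 1000)
  expect_equal(info, 1000 / 4, tolerance = 0.005)

  # two gates with boundary u * tau, T >> tau: algebraic two-channel sum
  u <- 1.59
  tau <- 2
  sig2 <- function(x) decay_fractions(c(0, u * tau, 60), x, 60)
  info2 <- fisher_scalar(sig2, x0 = tau, N = 500)
  expect_equal(info2, 500 * u^2 * exp(-u) / (tau^2 * (1 - exp(-u))),
               tolerance = 1e-4)

  expect_error(fisher_scalar(function(x) c(-0.1, 1.1), 1, 1),
               class = "hdim_error_invalid_signature")
})

test_that("finite-difference step choice does not move the information", {
  edges <- seq(0, 50, length.out = 65)
  sig <- function(tau) decay_fractions(edges, tau, 50)
  vals <- vapply(c(0.005, 0.01, 0.02),
                 function(d) fisher_scalar(sig, 2, 1, delta = d), numeric(1))
  expect_lt(diff(range(vals)) / mean(vals), 0.001)
})

test_that("F-values are N-invariant and reach 1 for fine partitions", {
  edges <- seq(0, 50, length.out = 257)
  sig <- function(tau) decay_fractions(edges, tau, 50)
  expect_identical(f_value_scalar(sig, 2, N = 250),
                   f_value_scalar(sig, 2, N = 10000))
  expect_equal(f_value_scalar(sig, 2), 1, tolerance = 0.01)
  expect_warning(Finf <- f_value_scalar(function(x) 1, 2), "Information-free")
  expect_identical(Finf, Inf)
})

test_that("the analytic two-gate curve has the known shape and optimum", {
  expect_equal(two_gate_f_curve(1), sqrt(exp(1) - 1), tolerance = 1e-12)
  # degenerate at both limits
  expect_gt(two_gate_f_curve(1e-4), 50)
  expect_gt(two_gate_f_curve(25), 100)
  expect_error(two_gate_f_curve(-1), class = "hdim_error_domain")

  opt <- two_gate_optimum()
  # oracle: the optimum solves u * exp(u) = 2 * (exp(u) - 1)
  u_star <- uniroot(function(u) u * exp(u) - 2 * (exp(u) - 1),
                    c(1, 2), tol = 1e-12)$root
  expect_equal(opt$u_opt, u_star, tolerance = 1e-5)
  expect_equal(opt$f_opt, two_gate_f_curve(u_star), tolerance = 1e-9)

  # agreement with the finite-difference information on the same partition
  tau <- 2
  sigu <- function(x) decay_fractions(c(0, tau, 60), x, 60)
  expect_equal(f_value_scalar(sigu, tau), two_gate_f_curve(1),
               tolerance = 1e-4)
})

test_that("split_gain equals the direct information difference", {
  expect_equal(split_gain(100, 0.5, 0), 0)
  # quadratic in the derivative at phi = 0.5
  expect_equal(split_gain(7, 0.5, 0.3), 4 * 7 * 0.3^2)
  expect_error(split_gain(10, 1.2, 0.1),
               class = "hdim_error_degenerate_split")

  # oracle: for random single-channel splits of an exponential partition the
  # gain formula must equal the direct difference of the analytic
  # information sums (exact derivatives on both sides)
  set.seed(97)
  T <- 80
  N <- 1
  for (i in 1:100) {
    tau <- runif(1, 1, 4)
    edges <- sort(c(0, runif(3, 0, T), T))
    ch <- sample(length(edges) - 1L, 1)
    t1 <- edges[ch]; t3 <- edges[ch + 1L]
    t2 <- runif(1, t1 + 0.05 * (t3 - t1), t3 - 0.05 * (t3 - t1))
    f <- exp_gate_fractions_exact(edges, tau, T)
    df <- exp_gate_dfractions_dtau(edges, tau, T)
    fsub <- exp_gate_fractions_exact(c(t1, t2, t3), tau, T)
    dfsub <- exp_gate_dfractions_dtau(c(t1, t2, t3), tau, T)
    phi <- fsub[1] / f[ch]
    dphi <- (dfsub[1] * f[ch] - fsub[1] * df[ch]) / f[ch]^2
    gain <- split_gain(N * f[ch], phi, dphi)
    direct <- analytic_exp_info(sort(c(edges, t2)), tau, T, N) -
      analytic_exp_info(edges, tau, T, N)
    expect_equal(gain, direct, tolerance = 1e-8)
  }
})

test_that("refining a partition never loses Fisher information", {
  set.seed(11)
  T <- 50
  for (i in 1:25) {
    tau <- runif(1, 0.8, 4)
    coarse <- sort(c(0, runif(sample(1:5, 1), 0, T), T))
    extra <- runif(sample(1:4, 1), 0, T)
    fine <- sort(unique(c(coarse, extra)))
    sig_c <- function(x) decay_fractions(coarse, x, T)
    sig_f <- function(x) decay_fractions(fine, x, T)
    Ic <- fisher_scalar(sig_c, tau, 1)
    If <- fisher_scalar(sig_f, tau, 1)
    expect_gte(If, Ic - 1e-9 * Ic)
  }
})

test_that("disjoint signatures reach the shot-noise limit in unmixing", {
  # oracle: with disjoint channel support, estimating a_j * N is plain
  # Poisson counting of that fluorophore's photons, so each per-parameter
  # F is exactly 1 (shot-limited) at any abundance
  g <- cbind(c(0.6, 0.4, 0, 0), c(0, 0, 0.3, 0.7))
  for (a in c(0.2, 0.5, 0.8)) {
    fit <- fisher_matrix(g, c(a, 1 - a), N = 1000)
    expect_equal(unname(fit$per_param_F), c(1, 1), tolerance = 1e-10)
    expect_equal(fit$combined_F, 1, tolerance = 1e-10)
  }
})

test_that("fisher_matrix detects rank deficiency and reports tidy output", {
  g <- cbind(c(0.5, 0.5), c(0.5, 0.5))
  expect_error(fisher_matrix(g, c(0.5, 0.5)), class = "hdim_error_singular")

  fl <- example_fluorophores()
  grid <- tiny_grid()
  fit <- fisher_matrix(list(build_hdss(fl$A, grid), build_hdss(fl$B, grid)),
                       c(0.4, 0.6), N = 1000)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "f_value"))
  expect_equal(td$estimate, c(0.4, 0.6))
  gl <- glance(fit)
  expect_equal(gl$combined_F, mean(fit$per_param_F))
  expect_equal(gl$photons_5pct, round(400 * gl$combined_F^2))
})

test_that("marginalization preserves totals and factors", {
  fl <- example_fluorophores()
  g <- tiny_grid()
  h <- build_hdss(fl$A, g)
  expect_equal(marginalize(h, c("polarization", "wavelength", "time")),
               h)
  for (keep in list("time", "wavelength", c("polarization", "time"))) {
    expect_equal(sum(marginalize(h, keep)$fractions), 1, tolerance = 1e-12)
  }
  expect_error(marginalize(h, character(0)), class = "hdim_error_domain")
})

test_that("full-grid unmixing dominates every marginalized technique", {
  set.seed(5)
  grid <- default_grid(n_time = 16, n_spectral = 8)
  for (i in 1:5) {
    fA <- random_fluorophore()
    fB <- random_fluorophore()
    scan <- technique_fvalue_scan(fA, fB, grid,
                                  abundance_grid = c(0.25, 0.5, 0.75))
    wide <- tidyr::pivot_wider(scan[, c("technique", "abundance", "F")],
                               names_from = "technique", values_from = "F")
    for (tech in c("FLIM", "SPEC", "ANISO", "SLIM", "TR_ANISO", "SR_ANISO")) {
      expect_true(all(wide$HDIM <= wide[[tech]] * (1 + 1e-9)))
    }
  }
})

test_that("efficiency, separability, resolution and cost identities hold", {
  expect_equal(photon_efficiency(1), 1)
  expect_equal(photon_efficiency(2), 0.25)
  Fs <- seq(0.5, 5, by = 0.25)
  expect_true(all(diff(photon_efficiency(Fs)) < 0))
  expect_error(photon_efficiency(0), class = "hdim_error_domain")

  expect_equal(separability(3, 1, 3, 2), 0)
  expect_equal(separability(1, 0.5, 2, 0.5), 1 / (0.5 * sqrt(2)))
  expect_error(separability(1, 0, 2, 1), class = "hdim_error_domain")

  rp <- resolution_and_power(1, p = 1, N = 400)
  expect_equal(rp$delta_x, 2 * sqrt(2) / 20)
  # internal consistency: R * delta_x = x0, and S = 2 at delta_x by Eq. 15
  expect_equal(rp$resolving_power * rp$delta_x, 1)
  sigma0 <- 1 / sqrt(400)   # x0 * F / sqrt(N) with F = 1
  expect_equal(separability(1 + rp$delta_x / 2, sigma0,
                            1 - rp$delta_x / 2, sigma0), 2)
  # quadrupling N doubles the resolving power
  expect_equal(resolution_and_power(1, 1, 1600)$resolving_power,
               2 * rp$resolving_power)
  # higher efficiency resolves smaller differences
  expect_lt(resolution_and_power(1, 0.9, 400)$delta_x * 0.999,
            resolution_and_power(1, 0.5, 400)$delta_x)

  expect_equal(cost_from_dark_counts(1e3, 1e6, 100), 1e-5)
  expect_equal(cost_from_dark_counts(0, 1e6, 100), 0)
  expect_equal(cost_from_dark_counts(1e3, 1e6, 200),
               cost_from_dark_counts(1e3, 1e6, 100) / 2)

  expect_equal(photons_required(1, 0.05), 400)
  expect_equal(photons_required(2), 1600)
})
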