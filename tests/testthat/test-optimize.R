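# Greedy split / merge / refinement of detection-channel partitions.

test_that("greedy splitting finds the optimal two-gate boundary", {
  obj <- lifetime_objective(tau_values = 2, T = 50)
  part <- optimize_split(obj, partition1d(c(0, 50)), epsilon = 1e-6,
                         max_channels = 2)
  expect_equal(n_partition_channels <- length(partition_edges(part)) - 1L, 2L)
  # candidate-grid resolution limits the precision of a single pass
  expect_equal(partition_edges(part)[2], 1.59 * 2, tolerance = 0.2)

  # a threshold larger than any achievable relative gain is the identity
  even4 <- even_partition(c(0, 50), 4)
  expect_identical(partition_edges(optimize_split(obj, even4, epsilon = 1e6,
                                                  max_channels = 8)),
                   partition_edges(even4))
})

test_that("optimized gates beat even gates of the same channel count", {
  obj <- lifetime_objective(seq(0.5, 3, length.out = 5), T = 12.5)
  for (m in c(4L, 8L)) {
    opt <- optimize_split(obj, partition1d(c(0, 12.5)), epsilon = 1e-6,
                          max_channels = m, n_candidates = 64L)
    even <- even_partition(c(0, 12.5), m)
    F_opt <- obj$f_values(partition_edges(opt))
    F_even <- obj$f_values(partition_edges(even))
    # the optimizer targets the mean over the lifetime range (individual
    # lifetimes may trade off against each other)
    expect_lt(mean(F_opt), mean(F_even))
    expect_true(all(F_opt < 1.3))
  }
})

test_that("merging prunes a fine partition back to the optimal boundary", {
  obj <- lifetime_objective(tau_values = 2, T = 50)
  fine <- even_partition(c(0, 50), 256)

  # epsilon = 0 keeps everything
  expect_identical(
    partition_edges(optimize_merge(fine, obj, epsilon = 0)),
    partition_edges(fine))

  # forced merge down to two channels: the surviving boundary must be within
  # one bin of the exhaustive-search optimum over all single boundaries
  merged <- optimize_merge(fine, obj, epsilon = Inf, min_channels = 2)
  cand <- partition_edges(fine)[-c(1, 257)]
  F_all <- vapply(cand, function(b) obj$f_values(c(0, b, 50)), numeric(1))
  best <- cand[which.min(F_all)]
  expect_equal(partition_edges(merged)[2], best,
               tolerance = 50 / 256 + 1e-9)

  # each accepted merge can only lose information
  F2 <- obj$f_values(partition_edges(merged))
  expect_gte(F2, obj$f_values(partition_edges(fine)) - 1e-12)
})

test_that("boundary refinement converges to the analytic optimum", {
  obj <- lifetime_objective(tau_values = 2, T = 50)
  start <- partition1d(c(0, 50), boundaries = 2.0)   # 1.0 * tau
  ref <- refine_boundaries(start, obj)
  expect_true(attr(ref, "converged"))
  expect_equal(partition_edges(ref)[2], 1.59 * 2, tolerance = 0.02)
  expect_equal(obj$f_values(partition_edges(ref)), 1.24, tolerance = 0.005)

  # an already-optimal partition is a fixed point
  again <- refine_boundaries(ref, obj)
  expect_equal(partition_edges(again), partition_edges(ref),
               tolerance = 1e-3)

  # refinement never increases the mean F
  obj5 <- lifetime_objective(seq(0.5, 3, length.out = 5), T = 12.5)
  p4 <- even_partition(c(0, 12.5), 4)
  r4 <- refine_boundaries(p4, obj5)
  expect_lte(mean(obj5$f_values(partition_edges(r4))),
             mean(obj5$f_values(partition_edges(p4))))
})

test_that("all three optimization routes agree on the two-gate problem", {
  obj <- lifetime_objective(tau_values = 2, T = 50)
  b_split <- partition_edges(refine_boundaries(
    optimize_split(obj, partition1d(c(0, 50)), max_channels = 2), obj))[2]
  b_merge <- partition_edges(refine_boundaries(
    optimize_merge(even_partition(c(0, 50), 256), obj, epsilon = Inf,
                   min_channels = 2), obj))[2]
  b_refine <- partition_edges(refine_boundaries(
    partition1d(c(0, 50), 7), obj))[2]
  expect_equal(b_split, b_refine, tolerance = 0.02 * 2)
  expect_equal(b_merge, b_refine, tolerance = 0.02 * 2)
})

test_that("relative efficiency behaves like a fraction of retained photons", {
  obj <- lifetime_objective(seq(0.5, 3, length.out = 5), T = 12.5)
  ref <- even_partition(c(0, 12.5), 256, resolution = 12.5 / 4096)
  expect_equal(relative_efficiency(ref, obj, reference = ref), 1.0)

  effs <- vapply(c(2L, 4L, 8L), function(m) {
    even <- even_partition(c(0, 12.5), m)
    opt <- refine_boundaries(
      optimize_split(obj, partition1d(c(0, 12.5)), max_channels = m,
                     n_candidates = 64L), obj)
    c(relative_efficiency(even, obj), relative_efficiency(opt, obj))
  }, numeric(2))
  # optimized gates retain at least as many effective photons as even gates
  expect_true(all(effs[2, ] >= effs[1, ] - 1e-9))
  # nested optimized partitions: efficiency non-decreasing in channel count
  expect_true(all(diff(effs[2, ]) > -1e-9))
})

test_that("spectral unmixing partitions can be optimized the same way", {
  fl <- example_fluorophores(spectral_shift_nm = 40)
  obj <- unmixing_objective(fl$A, fl$B, abundances = c(0.3, 0.5, 0.7))
  part <- optimize_split(obj, partition1d(c(440, 630)), max_channels = 2,
                         n_candidates = 64L)
  part <- refine_boundaries(part, obj)
  F2 <- mean(obj$f_values(partition_edges(part)))
  # two optimized spectral channels must beat the even split
  expect_lt(F2, mean(obj$f_values(c(440, 535, 630))))
})
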