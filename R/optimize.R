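# Greedy split (bottom-up), merge (top-down) and boundary-refinement
# optimization of 1-D channel partitions.
#
# All three optimizers work on a shared objective contract: a function from
# partition edges to the vector of F-values over the parameter values being
# optimized for. Split/merge decisions use the mean relative change in photon
# efficiency p = 1/F^2 (proportional to the relative Fisher-information
# gain), so a single cost threshold epsilon is dimensionless.

#' Optimization objective for lifetime detection
#'
#' Builds the objective used by the partition optimizers for time-gated
#' lifetime estimation: for a candidate gate partition it evaluates the
#' scalar F-value ([f_value_scalar()]) of the mono-exponential decay model at
#' each lifetime in `tau_values`. Optimizing over a range of lifetimes at
#' once yields gates that perform well across experimental conditions.
#'
#' @param tau_values Lifetimes (ns) to optimize over, e.g.
#'   `seq(0.5, 3, by = 0.5)`.
#' @param T Laser period (ns).
#' @param delta Finite-difference step for [fisher_scalar()].
#' @return An object of class `partition_objective`.
#' @export
lifetime_objective <- function(tau_values, T, delta = 0.01) {
  check_scalar(T, "T")
  stopifnot(is.numeric(tau_values), length(tau_values) >= 1L,
            all(tau_values > 0))
  f_values <- function(edges) {
    vapply(tau_values, function(tau) {
      f_value_scalar(function(x) decay_fractions(edges, x, T), tau)
    }, numeric(1))
  }
  structure(list(f_values = f_values, x_values = tau_values,
                 mode = "scalar_lifetime", domain = c(0, T)),
            class = "partition_objective")
}

#' Optimization objective for two-fluorophore spectral unmixing
#'
#' For a candidate spectral partition it computes the combined abundance
#' F-value ([fisher_matrix()]) of unmixing two fluorophores, at each relative
#' abundance in `abundances`.
#'
#' @param fluoroA,fluoroB Two [fluorophore()] objects.
#' @param abundances Relative abundances of A to optimize over, inside (0, 1).
#' @param wavelength_range_nm Detected band (default `c(440, 630)`).
#' @param shape,shape_k Spectral density options, see [spectrum_fractions()].
#' @return An object of class `partition_objective`.
#' @export
unmixing_objective <- function(fluoroA, fluoroB,
                               abundances = seq(0.2, 0.8, by = 0.1),
                               wavelength_range_nm = c(440, 630),
                               shape = c("gamma", "gaussian"), shape_k = 16) {
  shape <- match.arg(shape)
  if (any(abundances <= 0 | abundances >= 1)) {
    abort("`abundances` must lie strictly inside (0, 1).",
          class = "hdim_error_domain")
  }
  f_values <- function(edges) {
    gA <- spectrum_fractions(edges, fluoroA$peak_nm, fluoroA$fwhm_nm,
                             shape, shape_k)
    gB <- spectrum_fractions(edges, fluoroB$peak_nm, fluoroB$fwhm_nm,
                             shape, shape_k)
    vapply(abundances, function(a) {
      # a partition on which the endmembers are indistinguishable carries
      # no abundance information: F is infinite, not an error, so the
      # optimizers can evaluate (and reject) such candidates
      tryCatch(fisher_matrix(cbind(gA, gB), c(a, 1 - a))$combined_F,
               hdim_error_singular = function(e) Inf)
    }, numeric(1))
  }
  structure(list(f_values = f_values, x_values = abundances,
                 mode = "abundance_unmixing", domain = wavelength_range_nm),
            class = "partition_objective")
}

objective_mean_F <- function(obj, edges) mean(obj$f_values(edges))

# mean relative efficiency change of `new` edges vs reference values p0.
# Where the reference partition carries no information (p0 = 0, e.g. a single
# all-covering channel) the absolute gain is used: any finite information from
# such a channel is worth infinitely much in relative terms, and the absolute
# score still ranks candidate splits correctly.
mean_rel_gain <- function(obj, new_edges, p0) {
  p1 <- suppressWarnings(photon_efficiency(obj$f_values(new_edges)))
  mean((p1 - p0) / ifelse(p0 > 0, p0, 1))
}

#' Grow a partition by greedy channel splitting
#'
#' Bottom-up optimization: at each step every channel is scanned over a dense
#' grid of interior split points, and the split with the largest mean
#' relative information gain (averaged over the objective's parameter
#' values) is accepted if the gain is at least `epsilon` and the channel
#' budget allows it. Deterministic: ties are broken toward the
#' lowest-coordinate split.
#'
#' @param obj A `partition_objective`.
#' @param initial Starting [partition1d()].
#' @param epsilon Split-acceptance threshold on the relative gain (>= 0). A
#'   physically motivated value is the dark-count cost
#'   [cost_from_dark_counts()]; default `1e-4`.
#' @param max_channels Maximum channel count.
#' @param n_candidates Candidate split points scanned per channel
#'   (default 128).
#' @return The optimized [partition1d()].
#' @examples
#' obj <- lifetime_objective(tau_values = 2, T = 50)
#' p <- optimize_split(obj, partition1d(c(0, 50)), max_channels = 2)
#' partition_edges(p)   # interior boundary near 1.59 * tau = 3.19 ns
#' @export
optimize_split <- function(obj, initial, epsilon = 1e-4,
                           max_channels = 8L, n_candidates = 128L) {
  stopifnot(inherits(obj, "partition_objective"),
            inherits(initial, "partition1d"))
  if (epsilon < 0) abort("`epsilon` must be >= 0.", class = "hdim_error_domain")
  if (max_channels < n_partition_channels(initial)) {
    abort("`max_channels` must be >= the initial channel count.",
          class = "hdim_error_domain")
  }
  part <- initial
  res <- part$resolution
  repeat {
    if (n_partition_channels(part) >= max_channels) break
    edges <- partition_edges(part)
    p0 <- suppressWarnings(photon_efficiency(obj$f_values(edges)))
    best_gain <- -Inf
    best_split <- NA_real_
    for (ch in seq_len(length(edges) - 1L)) {
      lo <- edges[ch] + res
      hi <- edges[ch + 1L] - res
      if (hi <= lo) next
      cands <- seq(lo, hi, length.out = n_candidates)
      for (cand in cands) {
        gain <- mean_rel_gain(obj, sort(c(edges, cand)), p0)
        if (gain > best_gain + 1e-15) {
          best_gain <- gain
          best_split <- cand
        }
      }
    }
    if (is.na(best_gain) || best_gain < epsilon) break
    part <- partition1d(part$domain, sort(c(part$boundaries, best_split)), res)
  }
  part
}

#' Prune a partition by greedy channel merging
#'
#' Top-down optimization: repeatedly merges the adjacent channel pair whose
#' removal costs the smallest mean relative information loss, as long as that
#' loss is at most `epsilon`. Information is monotone non-increasing along
#' the merge sequence.
#'
#' @param fine Starting [partition1d()] with at least 2 channels.
#' @param obj A `partition_objective`.
#' @param epsilon Maximum acceptable mean relative loss per merge (>= 0).
#' @param min_channels Stop merging below this channel count (default 1).
#' @return The pruned [partition1d()].
#' @export
optimize_merge <- function(fine, obj, epsilon, min_channels = 1L) {
  stopifnot(inherits(obj, "partition_objective"),
            inherits(fine, "partition1d"))
  if (n_partition_channels(fine) < 2L) {
    abort("`fine` must have at least 2 channels.",
          class = "hdim_error_invalid_partition")
  }
  part <- fine
  while (n_partition_channels(part) > max(1L, min_channels)) {
    edges <- partition_edges(part)
    p0 <- suppressWarnings(photon_efficiency(obj$f_values(edges)))
    losses <- vapply(seq_along(part$boundaries), function(i) {
      -mean_rel_gain(obj, edges[-(i + 1L)], p0)
    }, numeric(1))
    i_min <- which.min(losses)
    if (losses[i_min] > epsilon) break
    part <- partition1d(part$domain, part$boundaries[-i_min], part$resolution)
  }
  part
}

#' Refine partition boundaries by coordinate descent
#'
#' Local minimization of the mean F-value over the objective's parameter
#' values: each interior boundary in turn is optimized by golden-section
#' search between its neighbours, and passes repeat until the mean F improves
#' by less than `tol` (default 1e-6). The returned partition never has a
#' larger mean F than the input.
#'
#' @param partition A [partition1d()] with >= 2 channels.
#' @param obj A `partition_objective`.
#' @param tol Convergence threshold on the mean-F improvement per pass.
#' @param max_iter Maximum number of passes; if reached, the best partition
#'   so far is returned with `attr(, "converged") = FALSE`.
#' @return The refined [partition1d()] (attribute `converged`).
#' @export
refine_boundaries <- function(partition, obj, tol = 1e-6, max_iter = 50L) {
  stopifnot(inherits(obj, "partition_objective"),
            inherits(partition, "partition1d"))
  if (n_partition_channels(partition) < 2L) {
    abort("`partition` must have at least 2 channels.",
          class = "hdim_error_invalid_partition")
  }
  part <- partition
  res <- part$resolution
  f_prev <- objective_mean_F(obj, partition_edges(part))
  converged <- FALSE
  for (pass in seq_len(max_iter)) {
    b <- part$boundaries
    for (i in seq_along(b)) {
      edges <- c(part$domain[1L], b, part$domain[2L])
      lo <- edges[i] + res
      hi <- edges[i + 2L] - res
      if (hi <= lo) next
      opt <- optimize(function(x) {
        bi <- b
        bi[i] <- x
        objective_mean_F(obj, c(part$domain[1L], bi, part$domain[2L]))
      }, interval = c(lo, hi), tol = min(res / 10, 1e-6 * diff(part$domain)))
      b[i] <- opt$minimum
    }
    part <- partition1d(part$domain, b, res)
    f_now <- objective_mean_F(obj, partition_edges(part))
    if (f_prev - f_now < tol) {
      converged <- TRUE
      f_prev <- f_now
      break
    }
    f_prev <- f_now
  }
  attr(part, "converged") <- converged
  part
}

#' Efficiency of a partition relative to a reference
#'
#' Mean (over the objective's parameter values) of `(F_ref / F)^2` — the
#' fraction of photons the candidate partition effectively retains compared
#' with the reference. The default reference, 256 equal-width channels,
#' stands in for full TCSPC / hyperspectral resolution. A relative efficiency
#' of 0.75 means the candidate behaves as if 25% of photons were lost.
#'
#' @param partition Candidate [partition1d()].
#' @param obj A `partition_objective`.
#' @param reference Reference [partition1d()] on the same domain (default:
#'   256 even channels).
#' @return Scalar efficiency in (0, 1] (up to numerical noise).
#' @export
relative_efficiency <- function(partition, obj, reference = NULL) {
  stopifnot(inherits(partition, "partition1d"))
  reference <- reference %||%
    even_partition(partition$domain, 256L,
                   resolution = diff(partition$domain) / 4096)
  if (!isTRUE(all.equal(reference$domain, partition$domain))) {
    abort("`reference` must share the partition's domain.",
          class = "hdim_error_domain")
  }
  F_ref <- obj$f_values(partition_edges(reference))
  F_par <- obj$f_values(partition_edges(partition))
  mean((F_ref / F_par)^2)
}
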