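# Independent numerical oracles used across the test suite. Everything here
# is computed by quadrature or from closed forms derived separately from the
# package's own code paths.

# quadrature oracle for decay_fractions: integrate the exponential density
quad_decay_fractions <- function(edges, tau, T) {
  dens <- function(t) exp(-t / tau)
  total <- integrate(dens, 0, T, rel.tol = 1e-12)$value
  vapply(seq_len(length(edges) - 1L), function(i) {
    integrate(dens, edges[i], edges[i + 1L], rel.tol = 1e-12)$value / total
  }, numeric(1))
}

# quadrature oracle for the polarization-resolved decay
quad_pol_fractions <- function(edges, tau, r0, theta, T) {
  ipar <- function(t) exp(-t / tau) * (1 + 2 * r0 * exp(-t / theta)) / 3
  iperp <- function(t) exp(-t / tau) * (1 - r0 * exp(-t / theta)) / 3
  total <- integrate(function(t) ipar(t) + iperp(t), 0, T,
                     rel.tol = 1e-13)$value
  gate <- function(f) vapply(seq_len(length(edges) - 1L), function(i) {
    integrate(f, edges[i], edges[i + 1L], rel.tol = 1e-13)$value / total
  }, numeric(1))
  rbind(parallel = gate(ipar), perpendicular = gate(iperp))
}

# quadrature oracle for the gamma-shaped spectrum (same mode/FWHM
# parameterization, but integrating the density numerically per bin)
quad_gamma_fractions <- function(edges, peak, fwhm, k = 16) {
  mode0 <- k - 1
  half <- dgamma(mode0, shape = k) / 2
  lo <- uniroot(function(x) dgamma(x, shape = k) - half,
                c(1e-12, mode0), tol = 1e-12)$root
  hi <- uniroot(function(x) dgamma(x, shape = k) - half,
                c(mode0, mode0 + 30 * sqrt(k) + 10), tol = 1e-12)$root
  s <- fwhm / (hi - lo)
  off <- peak - mode0 * s
  dens <- function(w) dgamma((w - off) / s, shape = k) / s
  raw <- vapply(seq_len(length(edges) - 1L), function(i) {
    integrate(dens, edges[i], edges[i + 1L], rel.tol = 1e-12)$value
  }, numeric(1))
  raw / sum(raw)
}

# exact per-gate fractions and their analytic tau-derivatives for the
# periodic mono-exponential model (used by the Fisher/split-gain oracles)
exp_gate_fractions_exact <- function(edges, tau, T) {
  a <- head(edges, -1); b <- tail(edges, -1)
  (exp(-a / tau) - exp(-b / tau)) / (1 - exp(-T / tau))
}

exp_gate_dfractions_dtau <- function(edges, tau, T) {
  a <- head(edges, -1); b <- tail(edges, -1)
  D <- 1 - exp(-T / tau)
  num <- exp(-a / tau) - exp(-b / tau)
  dnum <- (a * exp(-a / tau) - b * exp(-b / tau)) / tau^2
  dD <- -T * exp(-T / tau) / tau^2
  (dnum * D - num * dD) / D^2
}

# direct evaluation of the Poisson-channel information with exact derivatives
analytic_exp_info <- function(edges, tau, T, N = 1) {
  f <- exp_gate_fractions_exact(edges, tau, T)
  df <- exp_gate_dfractions_dtau(edges, tau, T)
  keep <- f > 1e-12
  N * sum(df[keep]^2 / f[keep])
}

# small grids / fluorophores shared across tests
tiny_grid <- function() default_grid(n_time = 16, n_spectral = 8)

# flatten an hdss to the package's channel order (pol-major, time fastest)
flatten_sig <- function(h) c(aperm(h$fractions, c(3, 2, 1)))

random_fluorophore <- function() {
  fluorophore(tau_ns = runif(1, 0.8, 4), r0 = runif(1, 0.05, 0.4),
              theta_ns = runif(1, 0.5, 15), peak_nm = runif(1, 470, 560),
              fwhm_nm = runif(1, 30, 70))
}
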