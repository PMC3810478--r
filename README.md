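# hdimtools

Fisher-information analysis and detection-channel optimization for
multi-parametric (time / wavelength / polarization resolved) fluorescence
microscopy.

## The problem

Fluorescence microscopes read out biochemistry through photophysical
parameters — excited-state lifetime τ, anisotropy decay r(t) = r₀·e^(−t/θ),
emission spectrum — but every experiment runs on a limited photon budget.
How precisely a parameter x can be estimated from N detected photons is
bounded by the Fisher information of the channel partition: for independent
Poisson counting channels with expected counts G\_i(x) = N·f\_i(x),

    I(x) = Σ_i (dG_i/dx)² / G_i ,      σ_x ≥ I(x)^(−1/2) .

`hdimtools` works with the *photon economy* F = (σ\_x/x)·√N: F = 1 means the
measurement is shot-limited, and the photon efficiency p = F⁻² is the
fraction of photons effectively used. Splitting a detection channel never
decreases I (photon partitioning), and the gain from splitting a channel with
count G by a partitioning fraction φ(x) is ΔI = G·(∂φ/∂x)²/(φ(1−φ)) — zero
exactly for "trivial" splits. On top of these identities the package builds:

- **Forward models** (`fluorophore()`, `detection_grid()`, `build_hdss()`):
  closed-form per-channel photon fractions for mono-exponential decays with
  anisotropy and gamma-shaped emission spectra on joint
  polarization × wavelength × time grids (the hyper-dimensional spectral
  signature, HDSS).
- **Fisher metrics** (`fisher_scalar()`, `fisher_matrix()`,
  `technique_fvalue_scan()`): scalar-parameter information, the abundance
  Fisher matrix of linear unmixing (I\_jk = N·Σ\_i g\_ij g\_ik / Σ\_l a\_l g\_il),
  per-fluorophore and combined F-values, separability S = Δx/√(σ₁²+σ₂²) and
  biochemical resolving power R = √(p·N)/(2√2).
- **Partition optimizers** (`optimize_split()`, `optimize_merge()`,
  `refine_boundaries()`, `relative_efficiency()`): greedy bottom-up
  splitting, top-down merging and golden-section boundary refinement of time
  gates or spectral bins, optimized over a range of lifetimes or abundances.
- **Monte Carlo validation** (`mc_two_gate_scan()`, `monte_carlo_fvalue()`):
  empirical F-values of time-gated lifetime estimation against the analytic
  two-gate curve F(u) = √(eᵘ−1)/u.
- **Synthetic imaging and unmixing** (`simulate_gradient_image()`,
  `lstsq_unmix()`, `unmix_benchmark()`): Poisson-noise abundance-gradient
  images on the 2×16×64 = 2048-channel reference grid, least-squares
  unmixing, and bias/precision figures of merit per detection modality.
- **Hyper-dimensional phasors** (`hdph_transform()`, `hdph_image()`): linear
  cosine/sine projections reducing 2048 channels to 16 coefficients while
  retaining almost all unmixing precision.

## Worked example

```r
library(hdimtools)

# optimal two-gate FLIM: boundary in units of the lifetime
two_gate_optimum()
#> $u_opt
#> [1] 1.593624
#> $f_opt
#> [1] 1.242634

# which detection modality separates two typical fluorophores best?
fl <- example_fluorophores(spectral_shift_nm = 10)   # tau 3/2 ns, r0 0.4/0.2
scan <- technique_fvalue_scan(fl$A, fl$B, default_grid())
glance(scan)
#> # A tibble: 7 × 5
#>   technique F_min abundance_at_min F_at_half photons_5pct
#>   <chr>     <dbl>            <dbl>     <dbl>        <dbl>
#> 1 ANISO      4.32             0.53      4.32         7455
#> 2 FLIM       4.00             0.42      4.04         6404
#> 3 SPEC       3.12             0.43      3.14         3897
#> 4 TR_ANISO   2.92             0.48      2.92         3402
#> 5 SR_ANISO   2.62             0.46      2.63         2750
#> 6 SLIM       2.55             0.43      2.57         2602
#> 7 HDIM       2.24             0.46      2.25         2009
```

Reading the table: unmixing these two fluorophores by lifetime alone (FLIM)
costs a factor F ≈ 4 over shot noise, i.e. ≈ 6,400 photons/pixel for a 5%
abundance error, while the full 2048-channel hyper-dimensional system (HDIM)
needs only ≈ 2,000 — every extra detection dimension buys precision from the
same photons. `autoplot(scan)` draws the F-value curves versus abundance;
`fisher_matrix()` exposes the underlying fits with `tidy()`/`glance()`.

A thin command-line wrapper with the same workflows
(`fvalue`, `optimize-gates`, `optimize-spectral`, `dimensionality`,
`simulate`, `unmix`, `phasor`) lives at `inst/cli/hdimtools.R`.

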