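Package: hdimtools
Title: Fisher Information Analysis and Detection-Channel Optimization for
    Multi-Parametric Fluorescence Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify and maximize the biochemical resolving power of
    photon-counting fluorescence microscopy. Provides forward photophysical
    models for fluorophores (mono-exponential decays, anisotropy decay,
    gamma-shaped emission spectra) on joint time/wavelength/polarization
    detection grids, Poisson-channel Fisher information and photon-economy
    (F-value) metrics, greedy split/merge and boundary-refinement optimizers
    for detection-channel partitions, Monte Carlo validation of time-gated
    lifetime estimation, synthetic gradient-image generation with Poisson
    noise, linear spectral unmixing with accuracy/precision figures of merit,
    and hyper-dimensional phasor (HDPH) reductions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
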