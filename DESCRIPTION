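Package: optigate
Title: Optical Single-Emitter Gating Analysis and Pore Hydration Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of single-emitter fluorescence recordings of ion
    channel gating and of molecular-dynamics structure ensembles of the
    channel pore. Provides generators for two-state telegraph (gating and
    blinking) fluorescence traces with stepwise photobleaching, Poisson
    photon-count frame stacks and toy pore structures; autocovariance noise
    analysis with exponential-decay fitting; threshold idealization with
    dwell-time statistics and bleach-step counting; blinking-corrected
    dose-response (Hill) and conductance-voltage (Boltzmann) fitting; and
    grid-based trajectory post-processing (pore radius profiles, occupancy
    maps, water linear density, normalized grid SASA, ring orientation and
    pore continuity).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    bio3d,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
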