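Package: rrpool
Title: Readily Releasable Pool and Presynaptic Function Analysis for
    Whole-Cell Synaptic Currents
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of presynaptic function from whole-cell voltage-clamp
    recordings at central synapses. Implements readily-releasable-pool (RRP)
    estimation from 20 Hz stimulus trains using a first-order vesicle
    depletion-refill model (two-equation numerical solution for fusion
    efficiency and refill rate), RRP measurement from hypertonic sucrose
    transients, quantal content from evoked/miniature ratios, paired-pulse
    ratio, MK-801 use-dependent block kinetics, and a short-term
    facilitation-depression model fit. A synthetic-data module generates
    miniature and evoked current traces from known ground truth so every
    estimator is validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
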