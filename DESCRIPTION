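Package: nanotrace
Title: Single-Particle ICP-MS Data Reduction and Censored Survey Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Data reduction for single-particle inductively coupled plasma
    mass spectrometry (SP-ICP-MS) surveys of nanoparticles in biota.
    Implements rolling-median baseline estimation, Poisson false-positive
    thresholding and maximum-peak-intensity event discrimination on raw
    time-resolved count traces; ionic calibration, transport-efficiency
    determination with reference nanoparticles, conversion of event
    integrals to element mass per particle and mass-equivalent spherical
    diameter, and blank-corrected particle number and mass concentrations
    with per-day detection and quantification limits. Companion tools
    cover total-element quantification with blank-derived detection
    limits, particle fractions, and censoring-aware survey statistics
    (summary tables, z-scored PCA with group mean confidence ellipses,
    and Ward hierarchical clustering). A synthetic trace and survey
    generator with known ground truth makes every stage testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    yaml,
    ape,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'utils.R'
    'AllClasses.R'
    'simulate.R'
    'detect.R'
    'quantify.R'
    'totals.R'
    'survey.R'
    'io.R'
    'pipeline.R'
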