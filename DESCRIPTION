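Package: ccsflow
Title: Intracellular Flow, Particle Tracking and Cell-Stiffness Analysis for
    Live-Cell Punctate Fluorescence Movies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the movement of punctate fluorescent structures
    (such as clathrin-coated structures) in live-cell time-lapse movies and
    the mechanical stiffness of cells from AFM nanoindentation. Provides
    translational drift correction by phase correlation, a static-background
    intensity correction for punctate movies, multipass FFT
    cross-correlation particle image velocimetry (PIV) with outlier
    filtering and time averaging, radial flow profiles and flow-direction
    histograms about the cell center, single-particle detection and
    linking with per-track velocity statistics, kymographs, FRAP
    double-normalization and recovery fitting, and Sneddon
    spherical-indenter force-curve fitting for the Young's modulus.
    Seeded synthetic-data generators (movies, analytic flow fields, force
    curves, FRAP traces) with recorded ground truth make every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tiff,
    jsonlite,
    yaml,
    withr,
    minpack.lm,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
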