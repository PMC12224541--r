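Package: synca
Title: Detection, Kinetics and Quantal Analysis of Synaptic Calcium Imaging Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying evoked and spontaneous synaptic calcium
    transients from fluorescence trace tables. Reads multi-ROI intensity
    tables exported from image-analysis software, computes dF/F and
    ratiometric dR/R normalizations, detects events with customizable
    threshold, width and inter-peak distance parameters, fits exponential
    rise and decay kinetics by Levenberg-Marquardt least squares, partitions
    evoked responses by stimulation protocol, and matches optical quantal
    events against electrophysiological mEPSP records (detection fraction,
    paired-amplitude correlation, Kolmogorov-Smirnov comparison of amplitude
    distributions). A two-channel trace simulator with ground truth makes
    every stage verifiable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
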