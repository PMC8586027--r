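Package: cortexmap
Title: Quantitative Analysis of Actomyosin Cortex Architecture and Tension
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for measuring how deeply myosin motors
    penetrate the cortical actin network of animal cells. Implements
    post-processing of single-molecule localization microscopy (SMLM)
    tables (fiducial and redundant cross-correlation drift correction,
    chromatic affine registration, Gaussian density-map rendering),
    cortex straightening with per-bin FWHM, peak-to-peak distance and
    signed cytoplasmic-overhang statistics, bipolar myosin-minifilament
    detection in structured-illumination images with projected-length,
    angle and relative-tension inference, confocal cortex segmentation
    and step-convolution linescan fitting for cortex thickness and
    myosin penetration depth, cortical-tension computation from AFM
    parallel-plate force plateaus, and the accompanying group statistics.
    Every input has a seed-deterministic synthetic generator with
    recorded ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    stats,
    jsonlite,
    yaml,
    tiff,
    EBImage,
    signal,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
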