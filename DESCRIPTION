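Package: hubtrack
Title: Quantification of Transcriptional Hubs and Reporter Dynamics in
    Live Embryo Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for multi-channel time-lapse confocal
    movies of early fly embryos: maximum-intensity projection and
    rolling-ball background subtraction; bright-focus-suppressed Otsu
    segmentation of nuclei and chromosome territories with watershed
    splitting; per-mask intensity time series and temporal-peak
    extraction for protein hub dynamics; nucleus tracking, Laplacian-of-
    Gaussian focus detection and per-nucleus transcriptional ON/OFF state
    kinetics with cumulative appearance/disappearance curves; dual
    5'/3' stem-loop reporter spot tracking with gap closing, fixed-window
    quantification, montages and cumulative intensity relationships;
    rank-based group comparisons; and a ground-truth-annotated synthetic
    movie generator so every stage is testable without raw imaging data.
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    tiff,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
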