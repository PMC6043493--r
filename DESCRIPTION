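Package: myelinmetrics
Title: Cross-Method Myelin Volume Fraction Mapping on Synthetic Quantitative MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates quantitative-MRI brain phantoms with known myelin content
    and compares three voxelwise myelin proxies on them: a magnetization-transfer
    saturation index computed from spoiled gradient-echo triplets with dual-angle
    B1 correction, a relaxometry-based myelin volume fraction obtained by
    projecting R1/R2/proton-density maps onto a four-compartment lookup grid, and
    a calibrated T1-weighted/T2-weighted intensity ratio. Provides the
    partial-volume-aware ROI extraction, white-matter-mean calibration, and the
    comparison statistics (Spearman correlations with Fisher confidence
    intervals, correlation-equality Z tests, Steel-Dwass multiple comparisons,
    linear regression and analysis of covariance) used to judge agreement
    between the proxies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
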