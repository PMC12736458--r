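Package: thermoseries
Title: Dynamic Breast Thermography Analysis with Physiological Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for cold-stress dynamic infrared thermography
    of the breast. Generates synthetic post-stress thermogram sequences from a
    closed-form bio-heat forward model, extracts per-frame physiological
    descriptors (maximum and mean temperature, spatial heterogeneity, and the
    depth and intensity of a buried spherical heat source obtained by inverting
    the point-source surface temperature law), assembles per-subject
    multivariate time series, and classifies cancer versus control sequences
    with an interval-based Time Series Forest and a stacked LSTM network,
    including stratified cross-validation, normalized confusion matrices, ROC
    averaging, and Friedman/Wilcoxon comparison of feature sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    png,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    pROC
Config/testthat/edition: 3
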