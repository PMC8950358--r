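Package: vagdx
Title: Vibroarthrographic Signal Analysis for Knee Joint Condition Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis pipeline for vibroarthrography (VAG): seeded
    simulation of two-channel knee-joint acoustic recordings with an angle-encoder
    trace for healthy-control and osteoarthritis cohorts; encoder-driven motion
    segmentation; signal cleaning by ensemble empirical mode decomposition (EEMD)
    with monotonic-trend removal; twelve time-domain vibration state indicators
    (mean, straightened average, RMS, peak, peak-to-peak, crest/impact/shape
    factors, variance, kurtosis, M6A, M8A); neighbourhood component analysis (NCA)
    feature weighting with cross-validated regularisation and relative-threshold
    selection; MLP and radial-basis-function binary classifiers with an automatic
    architecture search; and ROC/AUROC evaluation reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
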