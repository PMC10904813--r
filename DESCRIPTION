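Package: mmdrift
Title: Drift Detection for Medical Imaging Cohorts via Kernel Two-Sample Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for monitoring deployed imaging classifiers for data drift.
    Generates synthetic radiograph-like cohorts with demographic metadata and
    learnable pathology labels, injects categorical (enrichment) and temporal
    (regime-change) covariate shifts, reduces images to low-dimensional
    representations with a trained autoencoder (TAE) and a black-box shift
    detector (BBSD, classifier outputs), and tests source versus target
    samples with an unbiased maximum mean discrepancy (MMD^2) permutation
    test. Includes aggregate and per-class performance monitoring (AUROC, F1,
    precision, recall, Brier score) as the baseline drift signal, rolling
    temporal window and stratified enrichment sampling designs, and
    experiment harnesses that sweep drift magnitude and sample size.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    optparse,
    jsonlite
Config/testthat/edition: 3
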