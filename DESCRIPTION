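Package: hepatoscreen
Title: Assay Performance Evaluation for In Vitro Hepatotoxicity Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for benchmarking in vitro cytotoxicity assays as
    predictors of clinical drug-induced liver injury (DILI). Fits
    constrained four-parameter logistic dose-response curves to plate
    viability data with right-censoring at the highest tested
    concentration, converts IC50 values to exposure-corrected margins of
    safety (IC50/Cmax), makes censoring-aware binary DILI calls at
    practical thresholds, and evaluates assay performance against known
    DILI labels: sensitivity, specificity, likelihood ratios, Cohen's
    kappa with a null-hypothesis test, ROC analysis with a
    distance-optimized threshold, and stratified tenfold cross-validation.
    Includes a synthetic compound-panel generator with known ground truth
    so every pipeline stage is testable without proprietary assay data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    minpack.lm,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
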