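Package: radsig
Title: Radiomic Signatures for Predicting Plan Adaptation During
    Chemoradiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: A tested pipeline for building radiomic signatures that
    predict whether a stage-III non-small cell lung cancer patient will
    need treatment-plan adaptation during concurrent chemoradiation.
    Extracts 12 first-order histogram statistics, 130 directional 3D
    gray-level co-occurrence features and 100 LBP-TOP texture features
    from a CT volume and tumour mask, fuses them with 9 clinician-scored
    semantic features into a 251-element vector, selects a signature by a
    leave-one-out-wrapped Random-Forest wrapper with a selection-frequency
    threshold, and evaluates the final Random-Forest classifier by pooled
    leave-one-out ROC analysis and the .632+ bootstrap. Includes a
    synthetic phantom and cohort generator so every stage is testable
    without clinical data.
License: MIT
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
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
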