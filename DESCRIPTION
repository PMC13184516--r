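Package: drpval
Title: Standardized Validation for Drug Response Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating drug response prediction models against
    clinically meaningful standards: standardized dose-response summaries
    (four-parameter logistic fits integrated over a fixed 100 pM - 100 uM
    window to a range-independent AUDRC), entity-aware cross-validation
    (random, cell-blind, drug-blind, completely-blind and cancer-type-blind
    K-fold splits with machine-checkable disjointness guarantees), overall and
    per-drug/per-cell metric reports with threshold-exceedance summaries,
    cross-dataset response harmonization (pairwise Spearman matrices with
    matched-pair counts), and a synthetic screen generator with known ground
    truth so every component is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
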