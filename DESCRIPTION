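Package: aucpower
Title: Simulation-Based Power Analysis for ROC Curve and AUC Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Confidence-interval-focused power analysis for receiver
    operating characteristic (ROC) curve and (partial) area-under-the-curve
    (AUC) studies. Provides a binormal rating-data simulator for ordinal
    confidence-rating designs, empirical ROC curves with trapezoidal AUC and
    partial AUC, DeLong and stratified-bootstrap variance estimation and
    confidence intervals for single curves and (un)paired two-group
    comparisons, and Monte Carlo power estimation for null-hypothesis
    significance testing, minimum-effect testing, and equivalence testing
    against a smallest effect size of interest (SESOI).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
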