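Package: irrs
Title: Immune Cell-Pair Risk Scores for Survival Prognosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates immune-related risk scores (IRRS) from bulk
    tumor transcriptomes. Per-sample enrichment scores for immune-cell
    signatures (rank-based single-sample gene set enrichment) are compared
    within each sample to form binary cell-pair indicators; a prevalence
    filter, univariate Cox screening, L1-penalized Cox selection and a final
    multivariate Cox fit yield a linear risk score with median-based risk
    stratification. Includes a prognostic evaluation battery (Kaplan-Meier,
    log-rank, Harrell's concordance, time-dependent ROC/AUC, integrated
    discrimination improvement, decision-curve net benefit, calibration,
    nomogram-style combined clinical prediction) and a synthetic cohort
    generator with planted signatures, latent cell abundances and
    proportional-hazards survival for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    MASS,
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
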