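Package: phenoclock
Title: Clinical Blood-Marker Biological Age Clocks for Companion Animals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains and applies Gompertz proportional-hazards biological age
    ("phenoage") clocks from longitudinal complete-blood-count and serum
    chemistry panels with survival outcomes. Longitudinal measurements are
    converted to counting-process records with time-dependent covariates and
    left truncation; markers are screened per standard deviation with Cox
    models, selected by cross-validated LASSO-penalized Cox regression, and
    combined by maximum-likelihood Gompertz regression. Biological age is
    obtained in closed form by equating the survival functions of the full
    and reference models; its deviation from chronological age (AgeDev) is
    evaluated through hazard ratios, quintile contrasts, log-rank cutpoint
    scans, incident/dynamic time-dependent ROC, reference-range counts, and
    calorie-restriction group comparisons. A synthetic-cohort generator with
    known ground truth supports parameter-recovery and power studies.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    utils,
    yaml
Suggests:
    flexsurv,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
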