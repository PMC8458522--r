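Package: cslvr
Title: Chromosome-Scale Length Variation Genetic Risk Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds genetic risk scores from SNP-array log2-ratio (l2r)
    intensity data via chromosome-scale length variation (CSLV) features:
    each chromosome is split into k nominally equal probe blocks and the
    mean l2r within each block becomes one predictor. Provides readers and
    writers for probe maps, l2r matrices and phenotype tables; a synthetic
    cohort simulator with planted copy-number segments, a sex-linked X
    intensity shift and an age-structured population; exact age-matched
    (optionally sex-matched) case-control resampling with replicate-distinct
    control sets; cross-validated binary classifiers (random forest,
    gradient-boosted trees, regularized linear, stacked ensemble) with
    holdout AUC and max-normalized feature importances; quintile odds-ratio
    risk stratification; Welch two-sample comparisons of AUC distributions;
    and importance-based localization of predictive chromosome regions with
    BED export.
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
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    xgboost
Suggests:
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
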