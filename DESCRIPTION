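Package: pwlscore
Title: Point-Wise Linear Models and Simple Prediction Scores for
    Clinical-Genomic Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building interpretable predictive models of treatment
    response from mixed clinical and SNP genotype data. Implements a
    point-wise linear (PWL) model, a densely connected neural network that
    emits a per-sample logistic weight vector, together with elastic-net
    logistic regression and gradient-boosting baselines under a shared
    cross-validation protocol; importance-score based feature extraction and
    simple (signed-sum) prediction scores; landmark responder labeling from
    longitudinal PSA series; quartile risk stratification with Kaplan-Meier,
    log-rank and Harrell's C-index evaluation; a Hardy-Weinberg
    allele-frequency effect estimator for comparing a signed SNP panel across
    populations; and a synthetic cohort generator with Hardy-Weinberg
    genotypes, mixed-type clinical features, missingness, and linked
    proportional-hazards survival endpoints.
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
    tidyr,
    utils,
    withr,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
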