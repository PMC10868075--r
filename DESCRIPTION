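Package: msdbayes
Title: Discrete Bayesian Network Modelling of Psychosocial Risk and
    Musculoskeletal Symptoms in Occupational Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling how job stress and post-traumatic stress
    relate to musculoskeletal symptoms through burnout and depression
    mediators in occupational survey cohorts, using a seven-node discrete
    Bayesian network. Scores the standard instruments (HSE-MS IT, PTSD
    Checklist, Maslach Burnout Inventory, CES-D, Nordic Musculoskeletal
    Questionnaire), dichotomizes constructs at the cohort median, learns
    conditional probability tables by maximum likelihood or
    expectation-maximization under missing data, answers exact posterior
    queries, quantifies evidence-propagation sensitivity and per-arc
    influence, and validates predictions of symptom status with k-fold
    cross-validation, ROC curves and confusion-matrix metrics. Includes a
    calibrated synthetic-cohort generator with known ground truth, and
    study-design helpers (finite-population Cochran sample size).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests: testthat (>= 3.0.0), pROC, withr
Config/testthat/edition: 3
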