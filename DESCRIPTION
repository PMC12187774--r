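Package: obsuplift
Title: Uplift Modeling for Observational Cohorts with IPTW Pseudo-Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Two-model (T-learner) uplift modeling for observational cohorts with a
    dichotomized joint continuous exposure. Provides treatment dichotomization of a
    fluid-balance/norepinephrine plane, propensity-score estimation and inverse
    probability of treatment weighting, confounder-balanced pseudo-population sampling,
    logistic and random-forest outcome learners, Qini-curve/AUQC evaluation with random
    and idealized-optimal benchmarks, uplift-by-decile summaries, and a nested
    bootstrap-by-pseudo-sample-by-cross-validation experiment runner. Includes a
    synthetic cohort generator with confounded regime assignment and a known
    ground-truth conditional average treatment effect.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    randomForest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
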