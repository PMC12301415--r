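Package: delirisk
Title: Flood-Algorithm AutoML for Delirium Risk Prediction in Polytrauma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and interrogating an automated machine learning
    model of post-traumatic delirium risk. Implements the Flood Algorithm (FLA),
    a swarm-intelligence continuous optimizer, and an improved variant (IFLA)
    with chaotic sine-map initialization and Cauchy mutation; a 12-function
    benchmark suite for validating the optimizer; joint wrapper feature
    selection and hyperparameter tuning of a gradient-boosted classifier by
    cross-validated AUC; a seeded synthetic polytrauma cohort generator
    parameterized by published two-group summary statistics; threshold metrics,
    ROC/PR curves, and decision-curve analysis; exact and Monte Carlo Shapley
    attribution; and a command-line decision-support workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    xgboost,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
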