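Package: cctrial
Title: Simulation and Analysis of Adaptive Computerised Cognitive Training Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A virtual randomised-controlled-trial harness for computerised
    cognitive training (CCT) in mild cognitive impairment. Simulates synthetic
    cohorts with the covariate structure of a six-month CCT trial, implements
    the adaptive difficulty engine used by individualised CCT software
    (per-exercise, per-level penalised logistic success classifiers with a
    65 percent predicted-success cut-off and online retraining), a fixed-level
    basic comparator policy, stochastic-minimisation randomisation with
    household coupling, and the trial's complete statistical pipeline: effect
    sizes (Cohen's d, Cramer's V, partial eta squared), an effect-size-gated
    covariate-selection rule, a 1.5 IQR outlier rule, expectation-maximisation
    imputation of missing follow-up scores, two-occasion mixed-model ANCOVA
    with estimated marginal means, MCI transition analysis, and User
    Experience Questionnaire scoring and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    car,
    optparse
Config/testthat/edition: 3
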