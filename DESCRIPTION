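Package: drprogress
Title: Mixture-of-Weibull Survival Modelling of Diabetic Retinopathy Progression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Interval-censored survival modelling of diabetic retinopathy (DR)
    progression from annual eye exams. Models each eye's time to progression as
    a fixed-size mixture of Weibull distributions whose mixing weights are
    produced by a small multilayer perceptron trained on baseline covariates
    with an interval-censored likelihood loss. Includes derivation of
    interval-censored records from longitudinal visit tables on the ICDRDSS
    grading scale, mode-of-density time-to-progression prediction, survival
    evaluation metrics (Harrell concordance, IPCW Brier and integrated Brier
    score, time-dependent ROC, Kaplan-Meier, one-sided log-rank, clustered
    bootstrap), a personalized screening-interval policy layer (risk triage,
    screening-year recommendation, delayed-detection and eye-year incidence
    accounting), and a seeded synthetic-cohort simulator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse,
    flexsurv,
    withr
Config/testthat/edition: 3
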