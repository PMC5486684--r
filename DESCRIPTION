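Package: dosegap
Title: Persistence, Adherence, and Medication Coverage for Long-Acting
    Injectable Therapy
Version: 1.0.0
Authors@R:
    person("dosegap", "maintainers", email = "maintainers@dosegap.dev",
           role = c("aut", "cre"))
Description: Classifies per-patient persistence and adherence with
    long-acting injectable osteoporosis therapy (6-monthly subcutaneous
    dosing) under configurable gap windows, computes the medication
    coverage ratio (MCR), summarizes proportions with confidence
    intervals across sensitivity-window grids, and fits country-stratified
    stepwise multivariable logistic regressions of baseline factors
    associated with 24-month persistence.  Includes a discrete-hazard
    synthetic-cohort simulator so every stage of the pipeline is testable
    without patient-level data, plus a command-line interface that
    orchestrates simulate, metrics, and model stages end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
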