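Package: prpcea
Title: Markov Cohort Cost-Effectiveness Model of Early Versus Deferred
    Panretinal Photocoagulation in Diabetic Retinopathy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A state-transition (Markov) cohort model of diabetic retinopathy
    progression used to compare panretinal photocoagulation (PRP) given at the
    severe non-proliferative stage against PRP deferred until high-risk
    proliferative retinopathy. Provides the health-state space, parameter pack
    loading and validation, life-table based mortality adjustment, the cohort
    trace engine, discounted cost and QALY accrual with incremental
    cost-effectiveness and net monetary benefit, deterministic one-way
    (tornado) and scenario sensitivity analyses, probabilistic sensitivity
    analysis with cost-effectiveness planes and acceptability curves, and a
    synthetic-data generator for life tables and transition sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
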