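Package: htnce
Title: Cost-Effectiveness Microsimulation of Drug Treatment for Stage 1
    Hypertension
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A seven-state Markov model of cardiovascular disease
    progression in young and middle-aged stage 1 hypertensive patients at
    high cardiovascular risk, used to compare antihypertensive drug
    treatment against non-drug management from a societal perspective.
    Provides an individual-level microsimulation and a matched
    deterministic cohort solver, QALY and cost accrual with discounting
    and half-cycle correction, ICER and dominance classification, one-way
    (tornado) sensitivity analysis, probabilistic sensitivity analysis
    with beta/gamma/lognormal parameter distributions,
    cost-effectiveness acceptability curves, and a synthetic person-time
    cohort generator for estimator-recovery testing. All model inputs
    are read from a documented JSON parameter file; results are returned
    as tibbles with broom-style tidiers and ggplot2 plotting helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
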