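Package: cfcea
Title: Cost-Effectiveness Modelling of CFTR Modulator Therapy in Cystic Fibrosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A Markov cohort state-transition model of cystic fibrosis disease
    progression used to evaluate the cost-effectiveness of lumacaftor/ivacaftor
    combination therapy against usual care from a United States payer
    perspective. Disease severity is stratified by FEV1 percent predicted
    (mild, moderate, severe), with pulmonary exacerbation and lung transplant
    as within-cycle transition events, post-transplant and death as further
    states. The package provides a validated parameter registry with
    literature-based defaults, a synthetic natural-history stage that
    reconstructs unpublished inputs (FEV1 cohort bootstrap, decline-rate and
    mortality calibration), a deterministic cohort engine with discounted cost
    and QALY accrual, and an analysis layer: incremental cost-effectiveness
    ratios, scenario grids over horizon, starting age, long-term efficacy and
    cost assumptions, threshold price search, one-way (tornado) sensitivity
    analysis, and probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
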