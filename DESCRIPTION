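Package: irapen
Title: Markov Cohort Cost-Effectiveness Model for Risk-Based Cardiovascular Prevention
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A risk-stratified four-state Markov cohort model of primary
    cardiovascular disease prevention (the IraPEN essential-NCD program)
    versus no prevention. Index cohorts are defined by WHO/ISH 10-year CVD
    risk bands from Framingham-type risk equations; the model tracks
    event-free, post-CHD, post-stroke and dead states with first-year
    tunnel sub-states over a 40-year horizon, and accumulates discounted
    costs, QALYs and life years. Includes incremental cost-effectiveness
    analysis with dominance classification and net monetary benefit,
    one-way deterministic sensitivity analysis (tornado), probabilistic
    sensitivity analysis with gamma/beta/lognormal parameter distributions
    and CEAC summaries, a synthetic-data generator for unpublished inputs
    (life tables, incidences, post-event fatalities), and an independent
    individual-level microsimulation used to validate the cohort engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
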