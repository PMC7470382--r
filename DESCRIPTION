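Package: quinpk
Title: Population Pharmacokinetic Simulation and Overdose Mortality
    Analysis for Chloroquine and Hydroxychloroquine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates whole-blood concentration-time profiles of
    chloroquine and hydroxychloroquine under COVID-19 treatment and
    prophylaxis regimens using a linear multi-compartment oral-absorption
    model with between-patient variability and allometric weight scaling.
    Provides salt/base dose arithmetic and tablet-quantised regimen
    construction, exposure summaries (Cmax, AUC, 95 percent prediction
    intervals), whole-blood scaling of in vitro EC50 values, safety
    threshold reports, a renal-impairment clearance adjustment, and a
    pooled self-poisoning concentration-mortality analysis with
    nonparametric bootstrap confidence intervals. Includes a seeded
    synthetic-data generator so every stage is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
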