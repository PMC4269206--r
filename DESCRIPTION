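Package: acsCEA
Title: Lifetime Cost-Effectiveness of Dual Antiplatelet Therapy After
    Acute Coronary Syndrome
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-part decision-analytic model for the lifetime
    cost-effectiveness of ticagrelor versus clopidogrel after acute
    coronary syndrome, from the perspective of the German statutory
    health insurance: a one-year decision tree populated with trial-observed
    event probabilities and utilities, followed by a lifetime Markov cohort
    model with tunnel states for the first post-event year, background
    mortality from sex-specific life tables inflated by state-specific
    hazard ratios, and Weibull survival calibration/extrapolation of annual
    event probabilities.  Produces discounted costs, life-years and QALYs,
    incremental cost-effectiveness ratios with dominance handling,
    deterministic scenario and tornado analyses, and probabilistic
    sensitivity analysis with cost-effectiveness acceptability curves.
    Includes a synthetic individual-patient-data generator (Weibull event
    times with administrative censoring) and a Gompertz-Makeham life-table
    generator so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
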