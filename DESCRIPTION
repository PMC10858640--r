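Package: hfscore
Title: Simulation and Trend Analysis of a Multiparametric Remote-Monitoring
    Heart Failure Score
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to simulate implantable-device remote-monitoring telemetry,
    compute a seven-component composite heart-failure risk score with an alert
    hysteresis state machine, apply cohort eligibility and event-anchored
    weekly windowing rules, and compare 12-week pre-hospitalization score
    trends between patients with and without worsening heart-failure
    hospitalizations using two-level nested random-intercept linear mixed
    models fitted by restricted maximum likelihood.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    lme4,
    jsonlite
Config/testthat/edition: 3
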