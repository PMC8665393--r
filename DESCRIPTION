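Package: steptrack
Title: Remote Activity-Tracker Monitoring of Performance Status in
    Oncology Cohorts
Version: 0.1.0
Authors@R:
    person("steptrack", "developers", email = "steptrack@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for daily step-count data collected with
    consumer activity trackers around a chemotherapy cycle. Classifies
    wear days and applies a full-day adherence rule, scores the Memorial
    Symptom Assessment Scale-Short Form (MSAS-SF) subscales, computes
    day-over-day step-count volatility and its annualized summaries, and
    runs cohort-level correlation and group-comparison analyses linking
    activity to ECOG performance status and symptom burden. Includes a
    synthetic cohort generator (negative-binomial step counts, adherence
    drop-off, symptom-activity coupling) so the full pipeline is testable
    without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
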