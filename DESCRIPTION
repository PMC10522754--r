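Package: ipmntraj
Title: Prediagnostic Marker and Morphology Trajectories in IPMN Surveillance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing longitudinal surveillance data of patients
    with intraductal papillary mucinous neoplasms (IPMNs) of the pancreas who
    progress to pancreatic carcinoma. Implements rule-based classification of
    prediagnostic CA19-9 trajectories against a cumulative-average reference
    (aberrant elevation, high-to-high, low-to-low), detection of HbA1c and
    pancreatic-enzyme elevations, a rules engine for the consensus-guideline
    worrisome features and high-risk stigmata with first-occurrence timing and
    lead times, cohort-level contingency and survival analyses, and a seeded
    synthetic surveillance-cohort generator for testing the full pipeline
    without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    survival,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
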