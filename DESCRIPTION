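Package: polypharm
Title: Detection and Prevalence of CNS-Active Polypharmacy from Prescription Claims
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring out-of-hospital central nervous system (CNS)-active
    polypharmacy in cohorts of older adults from pharmacy claims. Maps ATC codes to
    six CNS-active medication classes, converts dated prescription fills into
    per-agent exposure intervals on a monthly or ISO-week grid under configurable
    grace-period rules, enumerates concurrent-use events (three or more distinct
    agents), estimates period prevalence with Clopper-Pearson exact confidence
    intervals including subgroup and prevalent/incident splits, and fits bivariate
    and multivariable logistic models for factors associated with polypharmacy.
    Includes a synthetic claims generator with known ground truth for validating
    every downstream estimate, and an end-to-end reporting pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
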