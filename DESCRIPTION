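Package: icscreen
Title: Information-Component Disproportionality Screening for Spontaneous
    Adverse-Event Report Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Case/non-case disproportionality analysis of individual case
    safety report (ICSR) databases using the Bayesian information component
    (IC) with Gamma-posterior credibility bounds. Provides a relational data
    model for spontaneous reports (CSV and JSON-lines dialects), a synthetic
    report-database generator with planted relative reporting rates for
    method validation, a staged drug-exclusion procedure (non-significant
    signal, single-country reporting, protopathic bias), French-method
    case informativity (NI0-NI2) and extrinsic imputability (B1-B4) scoring,
    clinical presentation classification from co-reported preferred terms,
    and per-drug and cohort summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
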