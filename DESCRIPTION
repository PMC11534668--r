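Package: faersignal
Title: Disproportionality Signal Detection for FAERS-Style Spontaneous Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pharmacovigilance analysis of FAERS-style spontaneous
    adverse-event report data: reading and writing the FDA quarterly ASCII
    table dialect, deduplicating case versions, selecting primary-suspect
    cases for a target drug, mapping MedDRA Preferred Terms to System Organ
    Classes, classifying administration route from free-text drug fields,
    reporting odds ratio (ROR) signal detection with 95% confidence
    intervals, route-stratified formulation comparison, time-to-onset and
    descriptive frequency tables, and a seeded synthetic report generator
    with known embedded signal strengths for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
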