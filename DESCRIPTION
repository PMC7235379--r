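Package: epipathways
Title: Treatment-Pathway Analysis for Pediatric Epilepsy over OMOP-CDM Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds new-user anti-seizure-medication (ASM) cohorts from
    minimal OMOP Common Data Model tables using 120-day prescription
    persistence windows, mines ordered ingredient-level treatment pathways,
    classifies drug-resistant epilepsy by distinct-ASM count, stratifies
    results by epilepsy category, onset age and electro-clinical syndrome,
    and summarizes annual monotherapy prescription trends. Ships a synthetic
    EHR generator with per-patient ground truth so the whole pipeline is
    testable without access to protected health data, plus lossless
    sunburst-hierarchy export of pathway frequency tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
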