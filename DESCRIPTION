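Package: crsbiologic
Title: Biologic Indication Criteria for Chronic Rhinosinusitis with Nasal Polyps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computable phenotyping of biologic-treatment indication in
    chronic rhinosinusitis with nasal polyps (CRSwNP). Evaluates the
    EUFOREA 2021 and EPOS/EUFOREA 2023 recommendation rule sets on
    per-patient records with arbitrary missingness using strong-Kleene
    three-valued logic, aggregates verdicts into criterion prevalence
    tables, indication-by-treatment cross-tabulations with Fisher's exact
    test, treatment-gap percentages and between-rule-set concordance, and
    generates synthetic CRSwNP cohorts whose marginal distributions and
    per-field missingness are calibrated to published cohort
    characteristics, so the whole pipeline runs without access to
    registry data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
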