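Package: psakit
Title: PSA Kinetics, Risk Stratification and Treatment-Guideline Tools for
    Prostate Cancer Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale tools for longitudinal prostate-specific antigen
    (PSA) records: PSA kinetics (velocity by linear regression or two-marker
    secant, doubling time by log-linear regression or two-marker
    interpolation, density), three-tier D'Amico risk stratification with the
    published five- and ten-year failure/survival lookup, a pluggable Partin
    pathologic-stage table, a data-driven treatment-guideline decision graph
    with three-valued predicate evaluation and path highlighting,
    post-treatment biochemical-success auditing, and a synthetic-cohort
    simulator with ground-truth bookkeeping so every component is testable
    without clinical data. Includes a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
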