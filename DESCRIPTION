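Package: epiregister
Title: Descriptive Epidemiology from Longitudinal Patient Registries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes annual incidence and point/period prevalence series from
    a longitudinal patient registry and a coded clinical-event stream, under
    explicit eligibility, wash-in and disease-duration rules as used in UK
    primary-care database research. Follow-up windows are derived from
    registration, data-quality, transfer-out, death and data-collection dates;
    incident events respect a 90-day post-registration wash-in and a
    recurrence lookback commensurate with the expected disease duration;
    person-time denominators are partitioned by calendar year. Estimate series
    can be validated against external published series with Lin's concordance
    correlation coefficient, including asymptotic confidence intervals and
    interpretation bands. A synthetic-registry simulator with known ground
    truth supports end-to-end testing, and a batch command-line pipeline
    orchestrates the full analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
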