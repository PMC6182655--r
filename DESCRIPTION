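Package: t2dregistry
Title: Registry-Based Incidence and Prevalence Analysis of Type 2 Diabetes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for nationwide health-registry analyses of type 2
    diabetes: a synthetic registry simulator emulating linked prescription,
    specialist-care and primary-care event tables; a rule-based
    case-ascertainment (phenotyping) algorithm with washout, treatment-class
    and initial-regimen classification; an open-cohort person-time engine
    with Lexis expansion by calendar year and attained age; and estimators
    for stratified incidence rates with confidence intervals, period
    prevalence, annual percent change by log-linear count regression,
    interrupted time series with a slope-change test, and Cox
    proportional-hazards regression.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    survival,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
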