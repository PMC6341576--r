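Package: sclcehr
Title: Identification, Validation and Characterisation of Small Cell Lung
    Cancer Cases in Primary-Care Electronic Health Records
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for ascertaining incident small cell lung cancer (SCLC)
    cases in UK-style primary-care electronic health record extracts, where
    no dedicated diagnosis code for SCLC exists. Implements the multi-step
    case-identification algorithm: cohort eligibility and person-time,
    detection of index lung-cancer or small-cell-cancer codes, cross-code
    confirmation within a +/-90-day window, negation-aware free-text string
    search in a -30/+90-day window, stratum classification, and
    confirmation-rate extrapolation to an expected case count. Includes
    simulation of manual chart review against ground truth with positive
    predictive value (exact binomial intervals), event-date backdating to
    the first related symptom or procedure, incidence rates per person-year,
    one-year all-cause mortality tables, a product-limit survival estimator,
    and baseline characterisation of cases. A synthetic EHR generator with
    configurable ground truth makes every stage testable without access to
    restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    survival,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
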