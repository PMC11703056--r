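Package: hdlomop
Title: Claims-Data ETL from German Health Data Lab Formats to the OMOP Common Data Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transforms German statutory health-insurance claims data, as delivered by the
    Health Data Lab (HDL) in its Format 1/2 (2009-2018) and Format 3 (2019 onwards) table
    layouts, into the OMOP Common Data Model version 5.4. Ships typed source-table schemas
    with CSV readers, writers and validators, a deterministic synthetic claims-data
    generator for desk-scale testing, an OMOP-style vocabulary store with ICD-10-GM code
    normalisation and domain routing, the transformation rules themselves (vague-date
    imputation, case ordering, observation-period derivation, drug-exposure intervals,
    cost mapping), and a quality-assessment layer computing field coverage, per-domain
    concept-mapping coverage and a catalog of conformance/completeness/plausibility checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
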