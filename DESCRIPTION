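Package: cmmbia
Title: Budget Impact Analysis of Pharmacist-Led Comprehensive Medication
    Management
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deterministic budget-impact model for a nationwide
    pharmacist-led Comprehensive Medication Management (CMM) service in
    cardiovascular and type 2 diabetic patients, from the payer's
    perspective. Projects the eligible polypharmacy population over a
    multi-year horizon, costs pharmacist labour, training and therapy
    modification, prices avoided healthcare services and avoided clinical
    events with DRG unit costs, and aggregates costs and savings into the
    net budget impact with a one-way deterministic sensitivity analysis.
    Ships the full Croatian parameterization in two replication modes,
    a scenario document format (YAML/JSON) with strict validation, a
    seeded random-scenario generator for property testing, and CSV report
    emission for every result table.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
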