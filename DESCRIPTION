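Package: rtworkflow
Title: Risk and Cost Modelling for Radiotherapy Treatment Workflows
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for prospective risk and cost analysis of radiotherapy
    treatment workflows. Implements TG-100-style failure modes and effects
    analysis (FMEA) with exact rational consensus scoring, risk priority
    numbers (RPN = O x S x D), configurable monotone risk matrices with a
    severity override, and top-fraction prioritisation globally or per
    personnel role. Implements time-driven activity-based costing (TDABC)
    over staged process maps: capacity cost rates, per-step cost rollups by
    resource, stage and category, and modality difference tables. Technology
    interventions are expressed as edits to a process map and evaluated for
    personnel, equipment and space cost savings and time savings, singly and
    combined. Ships the published capacity cost rates, process-map rollups
    and failure-mode register for five-fraction MR-guided versus CT-guided
    SBRT as plain-text fixtures, plus a seeded synthetic generator for
    workflows and registers with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
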