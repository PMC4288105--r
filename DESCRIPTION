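Package: neurocds
Title: Knowledge-Base Driven Clinical Decision Support for Neuropathic
    Pain Pharmacotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reusable clinical-decision-support engine modelled on
    point-of-care advisory systems for first-line pharmacologic
    management of neuropathic pain.  Provides a small knowledge-base
    language for if-then derivation rules and conditional comments
    routed to named interface locations with sort orders; a compiler
    and evaluation engine with live fact override; an EHR condensation
    layer that stages ICD9-derived comorbidity flags and five-year
    medication histories for fast patient-level queries; a reproducible
    synthetic-cohort generator; and a sectioned patient-report
    assembler with JSON, HTML and plain-text renderings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
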