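Package: phenokb
Title: Modular Knowledge Base and Rule Engine for Adolescent Obesity
    Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A modular, ontology-style knowledge base for rule-based
    assessment of obesity-related health conditions in adolescents. Ships
    a health-condition taxonomy (body mass, fat distribution, central
    obesity, adiposity), derived anthropometric measures (age at
    assessment, BMI, waist-to-hip and waist-to-height ratios), a DL-safe
    forward-chaining rule engine with fixpoint semantics and per-fact
    explanations, a table-driven generator for the 76-rule teenager
    physical-status rule pack, a privacy-motivated three-way partitioned
    fact store (persons / conditions / links), CSV/JSON cohort readers,
    Turtle/N-Triples export, a seeded synthetic-cohort generator, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
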