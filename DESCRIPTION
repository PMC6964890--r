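Package: spirotext
Title: Rule-Based Extraction of FEV1 Values from Free-Text Clinical Notes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-pass, rule-based tool for recovering quantifiable forced
    expiratory volume in one second (FEV1) values from free-text clinical
    notes. A keyword candidate pass retrieves notes containing any
    FEV-prefixed token; a pattern pass then locates FEV1 surface variants
    (FEV1, FEV-1, FEV_1, FEV 1) with negation of fever-type words, scans a
    bounded character window for the first numeric token, and validates it
    against plausibility ranges for liters and percent-predicted. Includes
    an evaluation module (precision/positive predictive value with Wilson
    confidence interval, recall, F-measure, value-level accuracy, Spearman
    rank agreement), a patient-level yield merge against structured
    pulmonary function test tables, a seeded synthetic note-corpus
    generator with gold annotations, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
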