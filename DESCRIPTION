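Package: fabryscreen
Title: Lexicon-Based NLP Screening for Fabry Disease in Electronic Health Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A decision-support screening pipeline for Fabry disease built on
    free-text electronic health records. A lexicon-driven named-entity
    extractor with typo correction, lemmatization, negation detection and
    cosine-similarity term linking recovers clinical evidence from notes;
    evidence from notes, ICD-10 codes and laboratory results is mapped onto
    13 scored clinical features (with confounder-based exclusion rules), and
    the per-patient sum of feature scores forms a screening risk factor.
    Includes cohort-level evaluation (confusion matrix, cut-off sweep,
    ROC/PR curves, enrichment versus population prevalence, group
    comparisons) and a seeded synthetic-cohort generator with mention-level
    gold annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
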