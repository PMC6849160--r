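Package: notecoder
Title: Rule-Based Coding of Primary Care Free Text and Phenotype Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A rule-based clinical natural language engine that maps short
    primary-care notes to a Read-like clinical terminology with contextual
    attributes (negation, suspicion, medical history) and quantitative test
    results, emitting only coded or numeric output. Includes seeded synthetic
    note and cohort generators with gold-standard annotations, myocardial
    infarction subtype adjudication against a registry gold standard,
    symptom-recording comparisons between structured and free-text sources,
    and cause-of-death extraction with ICD-10 underlying-cause selection and
    registry concordance reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
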