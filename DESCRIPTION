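Package: nermacro
Title: Macrofactor Analysis for Biomedical Named Entity Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating biomedical named entity recognition (NER)
    corpora and model predictions through corpus-level "macrofactors".
    Reads and writes BIO-annotated CoNLL-style corpora, scores predictions
    against gold annotations at the per-tag level with leveraged micro and
    macro F1 averages, computes six macrofactor metrics per entity word
    (sentence length, entity phrase length, entity word count per phrase,
    entity density, total entity word count per type, and entity label
    consistency), applies categorical relaxation of entity taxonomies,
    assembles supervised macrofactor datasets, and runs a three-layer
    multilevel factor elimination (MFE) algorithm -- correlation screening,
    iterative random-forest importance elimination, and regression
    coefficient elimination -- to identify the macrofactors that drive
    prediction accuracy. Includes a synthetic corpus and dataset generator
    with planted statistical structure for validation, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
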