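Package: medrex
Title: Medical Relation Extraction with a Pre-Trained Transformer Encoder and a 1d-CNN Head
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale framework for extracting medical relations
    (chemical-induced disease, herb/formula-syndrome, clinical temporal
    links) from annotated abstracts. Reads PubTator-format corpora and
    tab-delimited relation tables, generates balanced positive/negative
    sentence-pair samples from abstract-level annotations, tokenizes with
    greedy WordPiece, pre-trains a bidirectional transformer encoder from
    scratch with masked-token and next-sentence objectives, and fine-tunes
    it under a multi-filter one-dimensional convolutional classification
    head with a margin ranking loss. Includes precision/recall/F1
    evaluation, stratified cross-validation, and a synthetic corpus
    generator with a planted lexical trigger signal for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
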