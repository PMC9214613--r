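Package: bioevents
Title: Joint Extraction of Nested Biomedical Events with a Syntax-Aware Neural Tagger
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end framework for extracting (possibly nested) biomedical
    events from annotated sentences. Reads and writes BioNLP-ST style standoff
    annotation (.txt/.a1/.a2) and CoNLL-U dependency parses, builds a simplified
    three-relation syntactic multigraph per sentence, and runs a joint neural
    model: concatenated contextual/POS/entity embeddings, a bidirectional LSTM
    context encoder, a gated graph convolutional network over the dependency
    graph followed by multi-head self-attention, and a tagger LSTM whose trigger
    softmax distribution is fused into the argument-role classifier so that
    argument decisions condition on trigger uncertainty. Training uses a joint
    self-adjusting Dice loss suited to heavily imbalanced BIO tagging. Includes
    a seed-deterministic synthetic corpus generator, strict recursive event
    evaluation with a simple/nested stratification, and plotting helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
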