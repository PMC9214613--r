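# Shared fixtures: tiny documents and model setups built in code.

tiny_doc <- function() {
  text <- "TNF-alpha activator of IL-8 expression ."
  annotated_document(
    "tiny", text,
    entities = list(
      entity_span("T1", "Protein", 0L, 9L, "TNF-alpha"),
      entity_span("T2", "Protein", 23L, 27L, "IL-8")
    ),
    triggers = list(
      trigger_span("T3", "Pos_Reg", 10L, 19L, "activator"),
      trigger_span("T4", "Expression", 28L, 38L, "expression")
    ),
    events = list(
      event_record("E2", "T4", list(list(role = "Theme", filler_id = "T2"))),
      event_record("E1", "T3", list(list(role = "Theme", filler_id = "E2"),
                                    list(role = "Cause", filler_id = "T1")))
    )
  )
}

tiny_tokens <- function(words, gap = 1L) {
  starts <- cumsum(c(0L, head(nchar(words), -1L) + gap))
  tibble::tibble(surface = words, start = starts, end = starts + nchar(words))
}

# a random projective-ish tree over n nodes: each node's head drawn from
# earlier nodes (node 1 is the root)
random_arcs <- function(n) {
  if (n <= 1) return(tibble::tibble(head = integer(), dep = integer()))
  tibble::tibble(head = vapply(2:n, function(i) sample.int(i - 1L, 1L), 0L),
                 dep = 2:n)
}

random_graph <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  words <- replicate(n, paste(sample(letters, 4), collapse = ""))
  build_sentence_graph(tiny_tokens(words), rep("NOUN", n), random_arcs(n))
}

toy_model <- function(seed = 1, ...) {
  event_model(toy_corpus_schema(), toy_model_config(...), seed = seed)
}

small_corpus <- function(n_docs = 4, sentences = 3, nesting = 0.5, seed = 7) {
  generate_corpus(generator_config(n_docs = n_docs, sentences_per_doc = sentences,
                                   nesting_prob = nesting, seed = seed))
}
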