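#' Forward pass for one sentence (evaluation mode)
#'
#' Runs the numeric (dropout-free) pipeline and returns the intermediate
#' matrices: fused embeddings `X`, context `L`, syntax `S`, attention `M`,
#' source `O` and the trigger distribution `soft`.
#'
#' @param sent An encoded sentence record (see [prepare_corpus()]).
#' @param model An [event_model()].
#' @return List with `X`, `L`, `S`, `M`, `O`, `soft`.
#' @export
forward_sentence <- function(sent, model) {
  X <- cbind(sent$A,
             sent$pos_onehot %*% model$params$embed$pos_table,
             sent$ent_onehot %*% model$params$embed$ent_table)
  L <- bilstm_context(X, model$params$bilstm)
  S <- run_gcn(sent$A, sent$graph, model$params$gcn)
  M <- multi_head_attention(S, model$params$attn)
  O <- tagger(L, M, model$params$tagger)
  soft <- trigger_scores(O, model$params$tri)
  list(X = X, L = L, S = S, M = M, O = O, soft = soft)
}

decode_triggers <- function(soft, sent, model) {
  labels <- model$schema$trigger_bio_labels[apply(soft, 1L, which.max)]
  bio_to_spans(labels, sent$graph$tokens)
}

#' Predict events for one document
#'
#' End-to-end inference: per sentence, run the encoder stack, decode trigger
#' spans from the argmax BIO labels, enumerate (trigger, candidate) pairs
#' against the document's gold entities, classify roles with the fused
#' trigger distribution, and assemble (possibly nested) events. The returned
#' document reuses the gold entities (entity recognition is an input, not a
#' task) and is always a valid standoff document — in particular, the
#' predicted event set is acyclic and every filler resolves.
#'
#' @param model A trained [event_model()].
#' @param doc The input [annotated_document()] (its `.a2` content, if any, is
#'   ignored).
#' @param parses CoNLL-U sentences for `doc`.
#' @return An [annotated_document()] holding predicted triggers and events.
#' @export
predict_document <- function(model, doc, parses) {
  gold_free <- annotated_document(doc$doc_id, doc$text, doc$entities,
                                  triggers = list(), events = list())
  sents <- prepare_sentences(gold_free, parses, model$schema)
  sents <- lapply(sents, encode_sentence, model = model)
  ent_nums <- suppressWarnings(as.integer(sub("^T", "", vapply(doc$entities, `[[`, "", "id"))))
  next_t <- max(c(0L, ent_nums), na.rm = TRUE)
  next_e <- 0L
  triggers <- list()
  events <- list()
  for (sent in sents) {
    fw <- forward_sentence(sent, model)
    spans <- decode_triggers(fw$soft, sent, model)
    if (nrow(spans) == 0) next
    spans$id <- paste0("T", next_t + seq_len(nrow(spans)))
    next_t <- next_t + nrow(spans)
    event_ids <- paste0("E", next_e + seq_len(nrow(spans)))
    next_e <- next_e + nrow(spans)
    pairs <- enumerate_candidates(spans, sent$entities)
    probs <- role_classify(pairs, spans, sent$entities, fw$O, fw$soft,
                           model$params$event, fusion = model$config$fusion)
    evs <- assemble_events(pairs, probs, spans, sent$entities,
                           model$schema$role_labels, event_ids)
    for (k in seq_len(nrow(spans))) {
      triggers[[length(triggers) + 1L]] <- trigger_span(
        spans$id[k], spans$type[k], spans$start[k], spans$end[k],
        slice_text(doc$text, spans$start[k], spans$end[k]))
    }
    events <- c(events, evs)
  }
  annotated_document(doc$doc_id, doc$text, doc$entities, triggers, events)
}

#' Predict events for a corpus
#'
#' @param model A trained [event_model()].
#' @param corpus A `synthetic_corpus` or a list of
#'   `list(document =, parses =)` entries.
#' @return List of predicted [annotated_document()]s.
#' @export
predict_corpus <- function(model, corpus) {
  entries <- if (inherits(corpus, "synthetic_corpus")) corpus$docs else corpus
  lapply(entries, function(d) predict_document(model, d$document, d$parses))
}

#' Attention heat-map scores for a sentence
#'
#' Convenience wrapper: encodes a sentence, runs the GCN, and returns the
#' head-averaged attention matrix for visualisation.
#'
#' @param model An [event_model()].
#' @param sent An encoded sentence record.
#' @return An `attention_matrix` (see [export_attention()]).
#' @export
sentence_attention <- function(model, sent) {
  S <- run_gcn(sent$A, sent$graph, model$params$gcn)
  export_attention(S, model$params$attn, tokens = sent$graph$tokens$surface)
}
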