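# Convert annotated documents + parses into model-ready sentence records:
# the sentence graph, gold span tables in token coordinates, the enumerated
# gold candidate pairs with their role labels, and cached contextual
# embeddings. Sentences are the modelling unit; annotations that cross
# sentence boundaries are dropped with a warning.

align_spans_to_tokens <- function(spans, tokens) {
  if (length(spans) == 0) {
    return(tibble::tibble(id = character(), type = character(),
                          start = integer(), end = integer(),
                          token_start = integer(), token_end = integer()))
  }
  tibble::tibble(
    id = vapply(spans, `[[`, "", "id"),
    type = vapply(spans, `[[`, "", "type"),
    start = vapply(spans, `[[`, 0L, "start"),
    end = vapply(spans, `[[`, 0L, "end"),
    token_start = vapply(spans, function(s) {
      i <- which(tokens$start == s$start)
      if (length(i) != 1) stop_bioevents("bioevents_misaligned",
                                         sprintf("span %s start does not align", s$id))
      i
    }, 0L),
    token_end = vapply(spans, function(s) {
      i <- which(tokens$end == s$end)
      if (length(i) != 1) stop_bioevents("bioevents_misaligned",
                                         sprintf("span %s end does not align", s$id))
      i
    }, 0L)
  )
}

one_hot <- function(idx, ncol) {
  m <- matrix(0, length(idx), ncol)
  if (length(idx) > 0) m[cbind(seq_along(idx), idx)] <- 1
  m
}

# mean-pooling matrix: one row per span, 1/len over the span's token run
pooling_matrix <- function(token_start, token_end, n) {
  m <- matrix(0, length(token_start), n)
  for (k in seq_along(token_start)) {
    run <- token_start[k]:token_end[k]
    m[k, run] <- 1 / length(run)
  }
  m
}

#' Prepare a document's sentences for the model
#'
#' Splits a document's annotations across its parsed sentences, builds each
#' sentence's simplified dependency multigraph, aligns entity and trigger
#' spans to tokens, and labels every enumerated (trigger, candidate) pair
#' with its gold role (pairs not realised in any gold event get `None`).
#'
#' @param doc An [annotated_document()].
#' @param parses Sentence list from [read_conllu()] for the same document.
#' @param schema A [corpus_schema()].
#' @return List of sentence records (internal structure consumed by
#'   [train_event_model()] and [predict_document()]).
#' @export
prepare_sentences <- function(doc, parses, schema) {
  ent_ids_in <- character()
  trig_ids_in <- character()
  out <- lapply(seq_along(parses), function(si) {
    p <- parses[[si]]
    lo <- min(p$tokens$start); hi <- max(p$tokens$end)
    in_sent <- function(sp) sp$start >= lo && sp$end <= hi
    ents <- Filter(in_sent, doc$entities)
    trigs <- Filter(in_sent, doc$triggers)
    ent_ids_in <<- c(ent_ids_in, vapply(ents, `[[`, "", "id"))
    trig_ids_in <<- c(trig_ids_in, vapply(trigs, `[[`, "", "id"))
    graph <- build_sentence_graph(p$tokens, p$pos, p$arcs, ents, trigs)
    ent_tbl <- align_spans_to_tokens(ents, p$tokens)
    trig_tbl <- align_spans_to_tokens(trigs, p$tokens)
    trig_ids <- trig_tbl$id
    events <- Filter(function(ev) ev$trigger_id %in% trig_ids, doc$events)
    event_of_trigger <- setNames(vapply(events, `[[`, "", "id"),
                                 vapply(events, `[[`, "", "trigger_id"))
    pairs <- enumerate_candidates(trig_tbl, ent_tbl)
    role_gold <- vapply(seq_len(nrow(pairs)), function(k) {
      t_id <- trig_tbl$id[pairs$trigger[k]]
      filler <- if (pairs$candidate_kind[k] == "entity") {
        ent_tbl$id[pairs$candidate[k]]
      } else {
        unname(event_of_trigger[trig_tbl$id[pairs$candidate[k]]])
      }
      if (is.na(filler)) filler <- ""  # candidate trigger anchors no gold event
      role <- "None"
      for (ev in events) {
        if (ev$trigger_id != t_id) next
        for (a in ev$args) {
          if (identical(a$filler_id, filler)) { role <- a$role; break }
        }
      }
      role
    }, "")
    list(
      doc_id = doc$doc_id, sent_id = p$sent_id, graph = graph,
      entities = ent_tbl, triggers = trig_tbl, events = events,
      pairs = pairs,
      role_gold = match(role_gold, schema$role_labels),
      trigger_gold = match(graph$trigger_bio, schema$trigger_bio_labels)
    )
  })
  n_dropped <- length(setdiff(vapply(doc$entities, `[[`, "", "id"), ent_ids_in)) +
    length(setdiff(vapply(doc$triggers, `[[`, "", "id"), trig_ids_in))
  if (n_dropped > 0) {
    rlang::warn(sprintf("document %s: %d annotation(s) cross sentence boundaries and were dropped",
                        doc$doc_id, n_dropped),
                class = "bioevents_cross_sentence")
  }
  out
}

#' Prepare a whole corpus for training
#'
#' Runs [prepare_sentences()] over every document and caches the (frozen)
#' contextual embeddings plus the one-hot/adjacency/pooling matrices that the
#' training loop reuses every epoch.
#'
#' @param corpus A `synthetic_corpus`, or a list of
#'   `list(document =, parses =)` entries as returned by [read_corpus_dir()].
#' @param model An [event_model()].
#' @return List of encoded sentence records.
#' @export
prepare_corpus <- function(corpus, model) {
  entries <- if (inherits(corpus, "synthetic_corpus")) corpus$docs else corpus
  sentences <- list()
  for (d in entries) {
    sents <- prepare_sentences(d$document, d$parses, model$schema)
    sentences <- c(sentences, sents)
  }
  lapply(sentences, encode_sentence, model = model)
}

# Cache everything the tape forward needs that does not depend on trainable
# parameters.
encode_sentence <- function(sent, model) {
  g <- sent$graph
  n <- graph_size(g)
  schema <- model$schema
  sent$A <- contextual_embeddings(g$tokens$surface, model$config$embedding)
  sent$pos_onehot <- one_hot(label_indices(g$pos, schema$pos_vocab, "POS"),
                             length(schema$pos_vocab) + 1L)
  sent$ent_onehot <- one_hot(
    label_indices(g$entity_bio, schema$entity_bio_labels, "entity-BIO"),
    length(schema$entity_bio_labels) + 1L)
  sent$adj_t <- lapply(c(along = "along", rev = "rev", loop = "loop"),
                       function(r) t(relation_adjacency(g, r)))
  if (nrow(sent$pairs) > 0) {
    tr_i <- sent$pairs$trigger
    cn_i <- sent$pairs$candidate
    is_ent <- sent$pairs$candidate_kind == "entity"
    sent$pool_trig <- pooling_matrix(sent$triggers$token_start[tr_i],
                                     sent$triggers$token_end[tr_i], n)
    cand_start <- ifelse(is_ent, sent$entities$token_start[cn_i],
                         sent$triggers$token_start[cn_i])
    cand_end <- ifelse(is_ent, sent$entities$token_end[cn_i],
                       sent$triggers$token_end[cn_i])
    sent$pool_cand <- pooling_matrix(cand_start, cand_end, n)
  }
  sent
}
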