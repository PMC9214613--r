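#' Configuration for the synthetic corpus generator
#'
#' The generator emits seed-deterministic toy corpora in exactly the dialects
#' the readers consume: standoff triples (`.txt`/`.a1`/`.a2`) plus CoNLL-U
#' parses with document-level `TokenRange` offsets. Sentences are templated:
#' a *simple* sentence holds one trigger whose arguments are entities, a
#' *nested* sentence holds a regulation-style trigger whose Theme is another
#' event (mirroring the positive-regulation-of-expression chains typical of
#' biomedical corpora). Gold events are derived by applying `role_rule` to
#' every intra-sentence (trigger, candidate) pair, so the correct role is a
#' deterministic function of the trigger type and candidate kind — the
#' property the learnability tests rely on.
#'
#' @param n_docs Number of documents.
#' @param sentences_per_doc Sentences per document.
#' @param nesting_prob Probability that a sentence uses the nested template;
#'   since each sentence contributes one root (outermost) event, this is the
#'   expected fraction of *root* events that are nested.
#' @param multi_token_trigger_prob Probability that a trigger surface uses its
#'   multi-token variant.
#' @param no_event_prob Probability that a sentence carries no trigger at all
#'   (an entity-only filler sentence). Raising this dilutes the fraction of
#'   non-`O` trigger tokens, e.g. for heavily imbalanced (mostly-`O`)
#'   tagging experiments; such sentences contribute no root event.
#' @param ambiguous_triggers When `TRUE`, the lexicon includes surfaces
#'   shared between a simple and a regulation trigger type (`"induction"`,
#'   `"stimulation"`), so the event type — and hence the correct role — is
#'   resolvable only from sentence context, never from the surface alone.
#'   This is the condition under which fusing the trigger distribution into
#'   the role classifier carries non-redundant information. Default `FALSE`.
#' @param role_rule Data frame with columns `trigger_type`, `candidate`
#'   (an entity type or `"event"`), `role`; pairs not listed get role `None`.
#' @param seed Integer seed; the whole corpus is a pure function of the
#'   configuration.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_docs = 10, sentences_per_doc = 5,
                             nesting_prob = 0.3, multi_token_trigger_prob = 0.3,
                             no_event_prob = 0, ambiguous_triggers = FALSE,
                             role_rule = default_role_rule(), seed = 1) {
  stopifnot(nesting_prob >= 0, nesting_prob <= 1,
            multi_token_trigger_prob >= 0, multi_token_trigger_prob <= 1,
            no_event_prob >= 0, no_event_prob <= 1)
  structure(list(n_docs = n_docs, sentences_per_doc = sentences_per_doc,
                 nesting_prob = nesting_prob,
                 multi_token_trigger_prob = multi_token_trigger_prob,
                 no_event_prob = no_event_prob,
                 ambiguous_triggers = isTRUE(ambiguous_triggers),
                 role_rule = role_rule, seed = seed),
            class = "generator_config")
}

#' @rdname generator_config
#' @export
default_role_rule <- function() {
  tibble::tibble(
    trigger_type = c("Expression", "Development", "Growth",
                     "Pos_Reg", "Pos_Reg", "Neg_Reg", "Neg_Reg"),
    candidate = c("Protein", "Cell", "Cell",
                  "event", "Protein", "event", "Protein"),
    role = c("Theme", "Theme", "Theme", "Theme", "Cause", "Theme", "Cause")
  )
}

# Closed toy lexicon. Trigger types split into simple types (arguments are
# entities) and nesting-capable regulation types (an event can fill Theme);
# at most one regulation trigger per sentence keeps event references acyclic.
# With ambiguous = TRUE some surfaces are shared across types, so only
# sentence context identifies the event type.
toy_lexicon <- function(ambiguous = FALSE) {
  lex <- list(
    entities = list(
      Protein = c("IL-2", "IL-8", "TNF-alpha", "STAT3", "VEGF", "p53"),
      Cell = c("T-cells", "monocytes", "fibroblasts", "neurons")
    ),
    simple_triggers = list(
      Expression = list(single = c("expression", "overexpression"),
                        multi = c("gene expression"), arg_type = "Protein"),
      Development = list(single = c("development"),
                         multi = c("vessel development"), arg_type = "Cell"),
      Growth = list(single = c("growth"),
                    multi = c("cell growth"), arg_type = "Cell")
    ),
    reg_triggers = list(
      Pos_Reg = list(single = c("activation", "upregulation"),
                     multi = c("positive regulation")),
      Neg_Reg = list(single = c("inhibition", "suppression"),
                     multi = c("negative regulation"))
    )
  )
  if (ambiguous) {
    lex$simple_triggers$Growth$single <- c(lex$simple_triggers$Growth$single,
                                           "induction", "stimulation")
    lex$reg_triggers$Pos_Reg$single <- c(lex$reg_triggers$Pos_Reg$single,
                                         "induction", "stimulation")
  }
  lex
}

#' Schema of the toy corpus
#'
#' Label vocabularies implied by the generator's lexicon: entity types,
#' trigger (event) types with their nesting-capable subset, POS tags and role
#' labels. This is what a model needs to size its embedding tables and
#' classifier heads.
#' @return A list with `entity_types`, `trigger_types`, `nesting_capable`,
#'   `pos_vocab`, `role_labels`.
#' @export
toy_schema <- function() {
  lex <- toy_lexicon()
  list(
    entity_types = names(lex$entities),
    trigger_types = c(names(lex$simple_triggers), names(lex$reg_triggers)),
    nesting_capable = names(lex$reg_triggers),
    pos_vocab = c("DET", "NOUN", "VERB", "ADP", "PUNCT"),
    role_labels = c("Theme", "Cause", "None")
  )
}

lookup_role <- function(rule, trigger_type, candidate_kind) {
  hit <- rule$role[rule$trigger_type == trigger_type & rule$candidate == candidate_kind]
  if (length(hit) == 0) "None" else hit[[1]]
}

pick <- function(x) x[[sample.int(length(x), 1L)]]

# One templated sentence. Returns tokens (surface/pos/head), trigger and
# entity span descriptors in token indices, and whether it is nested.
gen_sentence <- function(cfg, lex) {
  # draw only when the condition is active so default corpora keep the same
  # RNG stream regardless of this option's existence
  if ((cfg$no_event_prob %||% 0) > 0 && runif(1) < cfg$no_event_prob) {
    ty <- pick(names(lex$entities))
    surf <- pick(lex$entities[[ty]])
    # the <Ent> was observed in culture .
    words <- c("the", surf, "was", "observed", "in", "culture", ".")
    pos <- c("DET", "NOUN", "VERB", "VERB", "ADP", "NOUN", "PUNCT")
    heads <- c(2L, 4L, 4L, 0L, 4L, 5L, 4L)
    return(list(tokens = tibble::tibble(surface = words), pos = pos,
                heads = heads,
                spans = list(triggers = list(),
                             entities = list(list(type = ty, from = 2L, to = 2L))),
                nested = FALSE, no_event = TRUE))
  }
  nested <- runif(1) < cfg$nesting_prob
  trig_surface <- function(entry) {
    if (runif(1) < cfg$multi_token_trigger_prob) pick(entry$multi) else pick(entry$single)
  }
  ent <- function(type) list(type = type, surface = pick(lex$entities[[type]]))
  mk <- function(words, pos, heads, spans, nested) {
    list(tokens = tibble::tibble(surface = words), pos = pos, heads = heads,
         spans = spans, nested = nested)
  }
  if (!nested) {
    ty <- pick(names(lex$simple_triggers))
    entry <- lex$simple_triggers[[ty]]
    tw <- strsplit(trig_surface(entry), " ")[[1]]
    a <- ent(entry$arg_type)
    # the <trig> of <Ent> was observed .
    words <- c("the", tw, "of", a$surface, "was", "observed", ".")
    nt <- length(tw)
    trig_idx <- 2:(1 + nt)
    of_i <- 2 + nt; ent_i <- 3 + nt; was_i <- 4 + nt; obs_i <- 5 + nt; dot_i <- 6 + nt
    pos <- c("DET", rep("NOUN", nt), "ADP", "NOUN", "VERB", "VERB", "PUNCT")
    heads <- integer(length(words))
    th <- 1 + nt  # head token of the trigger span
    heads[1] <- th
    if (nt > 1) heads[trig_idx[-nt]] <- th
    heads[th] <- obs_i
    heads[of_i] <- th
    heads[ent_i] <- of_i
    heads[was_i] <- obs_i
    heads[obs_i] <- 0L
    heads[dot_i] <- obs_i
    mk(words, pos, heads,
       list(triggers = list(list(type = ty, from = trig_idx[1], to = trig_idx[nt])),
            entities = list(list(type = a$type, from = ent_i, to = ent_i))),
       FALSE)
  } else {
    rty <- pick(names(lex$reg_triggers))
    sty <- pick(names(lex$simple_triggers))
    sentry <- lex$simple_triggers[[sty]]
    rw <- strsplit(trig_surface(lex$reg_triggers[[rty]]), " ")[[1]]
    sw <- strsplit(trig_surface(sentry), " ")[[1]]
    b <- ent("Protein")
    a <- ent(sentry$arg_type)
    # <B> caused the <R> of the <S> of <A> .
    words <- c(b$surface, "caused", "the", rw, "of", "the", sw, "of", a$surface, ".")
    nr <- length(rw); ns <- length(sw)
    b_i <- 1L; caus_i <- 2L
    r_idx <- 4:(3 + nr); rh <- 3 + nr
    of1 <- 4 + nr; the2 <- 5 + nr
    s_idx <- (6 + nr):(5 + nr + ns); sh <- 5 + nr + ns
    of2 <- 6 + nr + ns; a_i <- 7 + nr + ns; dot_i <- 8 + nr + ns
    pos <- c("NOUN", "VERB", "DET", rep("NOUN", nr), "ADP", "DET",
             rep("NOUN", ns), "ADP", "NOUN", "PUNCT")
    heads <- integer(length(words))
    heads[b_i] <- caus_i; heads[caus_i] <- 0L; heads[3] <- rh
    if (nr > 1) heads[r_idx[-nr]] <- rh
    heads[rh] <- caus_i
    heads[of1] <- rh; heads[the2] <- sh
    if (ns > 1) heads[s_idx[-ns]] <- sh
    heads[sh] <- of1
    heads[of2] <- sh; heads[a_i] <- of2; heads[dot_i] <- caus_i
    mk(words, pos, heads,
       list(triggers = list(list(type = rty, from = r_idx[1], to = rh),
                            list(type = sty, from = s_idx[1], to = sh)),
            entities = list(list(type = "Protein", from = b_i, to = b_i),
                            list(type = a$type, from = a_i, to = a_i))),
       TRUE)
  }
}

#' Generate a synthetic standoff + CoNLL-U corpus
#'
#' @param cfg A [generator_config()].
#' @return An object of class `synthetic_corpus`: a list with
#'   \describe{
#'     \item{docs}{One entry per document: `doc_id`, the file contents
#'       (`txt`, `a1`, `a2`, `conllu` character vectors), the gold
#'       [annotated_document()] and the parsed sentence list.}
#'     \item{log}{Emission log tibble with per-document gold counts
#'       (`entities`, `triggers`, `events`, `nested_events`, `root_events`,
#'       `nested_root_events`).}
#'     \item{schema}{[toy_schema()] vocabularies.}
#'     \item{config}{The generating configuration.}
#'   }
#' @export
generate_corpus <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  lex <- toy_lexicon(ambiguous = isTRUE(cfg$ambiguous_triggers))
  with_preserved_rng({
    set.seed(cfg$seed)
    docs <- vector("list", cfg$n_docs)
    log <- vector("list", cfg$n_docs)
    for (d in seq_len(cfg$n_docs)) {
      doc_id <- sprintf("synth%03d", d)
      sents <- lapply(seq_len(cfg$sentences_per_doc), function(i) gen_sentence(cfg, lex))
      built <- assemble_doc(doc_id, sents, cfg$role_rule)
      docs[[d]] <- built$doc_entry
      log[[d]] <- built$log_row
    }
    structure(list(docs = docs, log = dplyr::bind_rows(log),
                   schema = toy_schema(), config = cfg),
              class = "synthetic_corpus")
  })
}

assemble_doc <- function(doc_id, sents, role_rule) {
  offset <- 0L
  text_parts <- character()
  entities <- list(); triggers <- list(); events <- list()
  conllu_sents <- list()
  ent_n <- 0L; ev_n <- 0L
  trig_pending <- list()  # trigger spans get ids after all entities (a1 first)
  n_nested <- 0L; n_root <- 0L; n_nested_root <- 0L
  for (si in seq_along(sents)) {
    s <- sents[[si]]
    words <- s$tokens$surface
    starts <- integer(length(words)); ends <- integer(length(words))
    pos_cursor <- offset
    for (i in seq_along(words)) {
      starts[i] <- pos_cursor
      ends[i] <- pos_cursor + nchar(words[i])
      pos_cursor <- ends[i] + 1L  # single space between tokens
    }
    sent_text <- paste(words, collapse = " ")
    text_parts <- c(text_parts, sent_text)
    tok <- tibble::tibble(surface = words, start = starts, end = ends)
    sent_entities <- lapply(s$spans$entities, function(e) {
      ent_n <<- ent_n + 1L
      entity_span(paste0("T", ent_n), e$type, starts[e$from], ends[e$to],
                  paste(words[e$from:e$to], collapse = " "))
    })
    sent_triggers <- lapply(s$spans$triggers, function(t) {
      list(type = t$type, start = starts[t$from], end = ends[t$to],
           surface = paste(words[t$from:t$to], collapse = " "))
    })
    entities <- c(entities, sent_entities)
    trig_pending[[si]] <- sent_triggers
    heads <- s$heads
    conllu_sents[[si]] <- list(
      sent_id = sprintf("%s.s%d", doc_id, si),
      text = sent_text,
      tokens = tok,
      pos = s$pos,
      arcs = tibble::tibble(head = heads[heads != 0L],
                            dep = seq_along(heads)[heads != 0L])
    )
    offset <- pos_cursor
  }
  # assign trigger ids after entity ids, then derive events from the role rule
  trig_objs <- list()
  per_sent_trig_ids <- list()
  tn <- ent_n
  for (si in seq_along(trig_pending)) {
    ids <- character(length(trig_pending[[si]]))
    for (k in seq_along(trig_pending[[si]])) {
      tn <- tn + 1L
      t <- trig_pending[[si]][[k]]
      ids[k] <- paste0("T", tn)
      trig_objs[[length(trig_objs) + 1L]] <-
        trigger_span(ids[k], t$type, t$start, t$end, t$surface)
    }
    per_sent_trig_ids[[si]] <- ids
  }
  ent_by_sent <- split_spans_by_sentence(entities, conllu_sents)
  trig_global <- setNames(trig_objs, vapply(trig_objs, `[[`, "", "id"))
  for (si in seq_along(sents)) {
    tids <- per_sent_trig_ids[[si]]
    sent_trigs <- trig_global[tids]
    sent_ents <- ent_by_sent[[si]]
    eid_of_trig <- setNames(character(length(tids)), tids)
    for (tid in tids) {
      ev_n <- ev_n + 1L
      eid_of_trig[[tid]] <- paste0("E", ev_n)
    }
    for (tid in tids) {
      trg <- sent_trigs[[tid]]
      args <- list()
      any_event_arg <- FALSE
      for (e in sent_ents) {
        role <- lookup_role(role_rule, trg$type, e$type)
        if (role != "None") args[[length(args) + 1L]] <- list(role = role, filler_id = e$id)
      }
      for (other in setdiff(tids, tid)) {
        role <- lookup_role(role_rule, trg$type, "event")
        if (role != "None") {
          args[[length(args) + 1L]] <- list(role = role,
                                            filler_id = eid_of_trig[[other]])
          any_event_arg <- TRUE
        }
      }
      events[[length(events) + 1L]] <- event_record(eid_of_trig[[tid]], tid, args)
      if (any_event_arg) n_nested <- n_nested + 1L
    }
    if (!isTRUE(sents[[si]]$no_event)) {
      n_root <- n_root + 1L
      if (sents[[si]]$nested) n_nested_root <- n_nested_root + 1L
    }
  }
  doc <- annotated_document(doc_id, paste(text_parts, collapse = " "),
                            entities, trig_objs, events)
  files <- write_standoff(doc)
  list(
    doc_entry = list(doc_id = doc_id, txt = files$txt, a1 = files$a1,
                     a2 = files$a2, conllu = format_conllu(conllu_sents),
                     document = doc, parses = conllu_sents),
    log_row = tibble::tibble(
      doc_id = doc_id, entities = length(entities), triggers = length(trig_objs),
      events = length(events), nested_events = n_nested,
      root_events = n_root, nested_root_events = n_nested_root
    )
  )
}

split_spans_by_sentence <- function(spans, conllu_sents) {
  lapply(conllu_sents, function(s) {
    lo <- min(s$tokens$start); hi <- max(s$tokens$end)
    keep <- Filter(function(sp) sp$start >= lo && sp$end <= hi, spans)
    setNames(keep, vapply(keep, `[[`, "", "id"))
  })
}

#' Write a synthetic corpus to disk
#'
#' @param corpus A `synthetic_corpus`.
#' @param dir Output directory; one `.txt`/`.a1`/`.a2`/`.conllu` quadruple per
#'   document.
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (d in corpus$docs) {
    writeLines(d$txt, file.path(dir, paste0(d$doc_id, ".txt")))
    writeLines(d$a1, file.path(dir, paste0(d$doc_id, ".a1")))
    writeLines(d$a2, file.path(dir, paste0(d$doc_id, ".a2")))
    writeLines(d$conllu, file.path(dir, paste0(d$doc_id, ".conllu")))
  }
  invisible(dir)
}

#' Read a directory of standoff + CoNLL-U documents
#'
#' @param dir Directory containing `<id>.txt`, `<id>.a1`, optional `<id>.a2`
#'   and `<id>.conllu` files.
#' @return A list with one entry per document: `document` (the
#'   [annotated_document()]) and `parses` (sentences from [read_conllu()]).
#' @export
read_corpus_dir <- function(dir) {
  stems <- sort(sub("\\.txt$", "", basename(Sys.glob(file.path(dir, "*.txt")))))
  lapply(stems, function(stem) {
    doc <- read_standoff(file.path(dir, paste0(stem, ".txt")),
                         file.path(dir, paste0(stem, ".a1")),
                         file.path(dir, paste0(stem, ".a2")),
                         doc_id = stem)
    conllu_path <- file.path(dir, paste0(stem, ".conllu"))
    parses <- if (file.exists(conllu_path)) read_conllu(conllu_path) else NULL
    list(document = doc, parses = parses)
  })
}
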