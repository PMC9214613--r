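#' Model configuration
#'
#' Hyperparameters of the joint extractor. Defaults follow the reference
#' setting: 768/64/64 embedding dims, a 1-layer BiLSTM with 128 hidden units
#' per direction, a 2-layer gated GCN, 2-head self-attention, dropout 0.3.
#' The tagger hidden size (unstated in the reference setting) defaults
#' to 256. [toy_model_config()] gives the small desk-scale configuration
#' used throughout the package's tests and examples: 32/8/8 embeddings, a
#' 32-unit BiLSTM, a 64-unit tagger, and the sharper Dice constants
#' `lambda = 0.01`, `beta = 0.5` that desk-scale SGD training needs (see
#' the methods vignette for the analysis behind those values).
#'
#' @param embedding An [embedding_config()].
#' @param bilstm_hidden Hidden units per BiLSTM direction (`phi`).
#' @param gcn_layers Number of gated GCN layers (`k`).
#' @param attention_heads Number of self-attention heads (`H`); must divide
#'   the contextual width `m`.
#' @param tagger_hidden Tagger LSTM hidden size (`d_O`).
#' @param dropout Dropout rate applied during training to the fused input
#'   embeddings.
#' @param fusion Fuse the trigger softmax into the role classifier
#'   (`FALSE` gives the shared-source ablation variant).
#' @param loss `"dice"` or `"ce"`.
#' @param lambda,beta Dice loss constants ([dice_config()]).
#' @param loss_reduction Within-sentence reduction of the per-decision
#'   losses: `"sum"` (default; gradient magnitude grows with sentence
#'   length, which the small fixed SGD step needs) or `"mean"`
#'   (scale-free in sentence length).
#' @return A list of class `model_config`.
#' @export
model_config <- function(embedding = embedding_config(), bilstm_hidden = 128,
                         gcn_layers = 2, attention_heads = 2,
                         tagger_hidden = 256, dropout = 0.3, fusion = TRUE,
                         loss = c("dice", "ce"), lambda = 1, beta = 1,
                         loss_reduction = c("sum", "mean")) {
  loss <- match.arg(loss)
  loss_reduction <- match.arg(loss_reduction)
  if (embedding$contextual_dim %% attention_heads != 0) {
    stop_bioevents("bioevents_dimension_error",
                   "attention heads must divide the contextual width")
  }
  structure(list(embedding = embedding, bilstm_hidden = bilstm_hidden,
                 gcn_layers = gcn_layers, attention_heads = attention_heads,
                 tagger_hidden = tagger_hidden, dropout = dropout,
                 fusion = fusion, loss = loss, loss_reduction = loss_reduction,
                 dice = dice_config(lambda, beta)),
            class = "model_config")
}

#' @param ... Overrides passed to [model_config()].
#' @rdname model_config
#' @export
toy_model_config <- function(...) {
  defaults <- list(
    embedding = embedding_config(contextual_dim = 32, pos_dim = 8, entity_dim = 8),
    bilstm_hidden = 32, tagger_hidden = 64,
    lambda = 0.01, beta = 0.5
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(model_config, args)
}

#' Build the corpus schema for a model
#'
#' Derives the label vocabularies a model needs: the BIO trigger vocabulary
#' (`O` plus `B-`/`I-` per event type — 39 labels for a 19-type corpus), the
#' BIO entity vocabulary, POS tags and role labels.
#'
#' @param trigger_types Event (trigger) type vocabulary.
#' @param entity_types Entity type vocabulary.
#' @param pos_vocab POS tag vocabulary.
#' @param role_labels Role vocabulary; must end in `"None"`.
#' @param nesting_capable Subset of `trigger_types` whose events may take
#'   event-typed arguments (used by the type-based evaluation stratification).
#' @return A list of class `corpus_schema`.
#' @export
corpus_schema <- function(trigger_types, entity_types, pos_vocab,
                          role_labels = c("Theme", "Cause", "None"),
                          nesting_capable = character()) {
  stopifnot(tail(role_labels, 1) == "None")
  structure(list(
    trigger_types = trigger_types,
    entity_types = entity_types,
    pos_vocab = pos_vocab,
    role_labels = role_labels,
    nesting_capable = nesting_capable,
    trigger_bio_labels = c("O", as.vector(rbind(paste0("B-", trigger_types),
                                                paste0("I-", trigger_types)))),
    entity_bio_labels = c("O", as.vector(rbind(paste0("B-", entity_types),
                                               paste0("I-", entity_types))))
  ), class = "corpus_schema")
}

#' Schema for the synthetic toy corpus
#' @return A [corpus_schema()] matching [toy_schema()].
#' @export
toy_corpus_schema <- function() {
  s <- toy_schema()
  corpus_schema(s$trigger_types, s$entity_types, s$pos_vocab, s$role_labels,
                s$nesting_capable)
}

#' Initialise a joint event-extraction model
#'
#' Allocates and randomly initialises all trainable parameters: POS and
#' entity embedding tables (each with a reserved UNK row), the BiLSTM, the
#' gated GCN layers, the attention heads, the tagger LSTM and the two
#' classifier heads. Initialisation is a deterministic function of `seed`.
#'
#' @param schema A [corpus_schema()].
#' @param config A [model_config()].
#' @param seed Integer seed for parameter initialisation.
#' @return An object of class `event_model`.
#' @export
event_model <- function(schema, config = model_config(), seed = 1) {
  ecfg <- config$embedding
  m <- ecfg$contextual_dim
  phi <- config$bilstm_hidden
  u <- config$tagger_hidden
  vt <- length(schema$trigger_bio_labels)
  nr <- length(schema$role_labels)
  role_in <- 2L * (u + if (config$fusion) vt else 0L)
  params <- with_preserved_rng({
    set.seed(seed)
    list(
      embed = list(
        pos_table = init_mat(length(schema$pos_vocab) + 1L, ecfg$pos_dim, ecfg$pos_dim),
        ent_table = init_mat(length(schema$entity_bio_labels) + 1L, ecfg$entity_dim,
                             ecfg$entity_dim)
      ),
      bilstm = list(fwd = init_lstm_params(ecfg$mu, phi),
                    bwd = init_lstm_params(ecfg$mu, phi)),
      gcn = init_gcn_params(m, config$gcn_layers),
      attn = init_attention_params(m, config$attention_heads),
      tagger = init_lstm_params(2L * phi + m, u),
      tri = list(W = init_mat(u, vt, u), b = matrix(0, 1L, vt)),
      event = list(W = init_mat(role_in, nr, role_in), b = matrix(0, 1L, nr))
    )
  })
  structure(list(schema = schema, config = config, params = params,
                 log = tibble::tibble(epoch = integer(), loss = numeric())),
            class = "event_model")
}

#' @export
print.event_model <- function(x, ...) {
  np <- sum(vapply(flatten_params(x$params), length, 0L))
  cat(sprintf("<event_model: %d trigger types, %d BIO labels, %d parameters%s>\n",
              length(x$schema$trigger_types), length(x$schema$trigger_bio_labels),
              np, if (nrow(x$log) > 0) sprintf(", trained %d epochs", max(x$log$epoch)) else ""))
  invisible(x)
}

flatten_params <- function(x, prefix = "") {
  if (is.matrix(x)) return(setNames(list(x), prefix))
  out <- list()
  for (nm in names(x)) {
    out <- c(out, flatten_params(x[[nm]],
                                 if (nzchar(prefix)) paste0(prefix, ".", nm) else nm))
  }
  out
}

relist_params <- function(skeleton, flat, prefix = "") {
  if (is.matrix(skeleton)) return(flat[[prefix]])
  for (nm in names(skeleton)) {
    skeleton[[nm]] <- relist_params(
      skeleton[[nm]], flat,
      if (nzchar(prefix)) paste0(prefix, ".", nm) else nm)
  }
  skeleton
}
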