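#' Embedding configuration
#'
#' Per-token input vectors are the concatenation `x_i = [a_i ; b_i ; c_i]` of
#' a contextual word embedding, a POS-tag embedding and an entity-BIO-label
#' embedding; the total width is `mu = contextual_dim + pos_dim + entity_dim`
#' (896 with the defaults of 768 + 64 + 64). The contextual part either comes
#' from a user-supplied pretrained embedder (`provider`: a function mapping a
#' character vector of token surfaces to an `n x contextual_dim` matrix, with
#' any subword pooling — mean pooling is recommended — already applied) or
#' from the deterministic fallback, a seeded unit-variance draw keyed by the
#' token surface so that experiments need no checkpoint download. The
#' contextual embedder is frozen; POS and entity tables are trained.
#'
#' @param contextual_dim,pos_dim,entity_dim Embedding widths.
#' @param embedder `"deterministic_fallback"` or `"pretrained_transformer"`.
#' @param provider Token-embedding function, required for the pretrained kind.
#' @param embed_seed Seed for the fallback embedder.
#' @return A list of class `embedding_config` with a derived `mu` field.
#' @export
embedding_config <- function(contextual_dim = 768, pos_dim = 64, entity_dim = 64,
                             embedder = c("deterministic_fallback",
                                          "pretrained_transformer"),
                             provider = NULL, embed_seed = 1) {
  embedder <- match.arg(embedder)
  if (embedder == "pretrained_transformer" && !is.function(provider)) {
    stop_bioevents("bioevents_config_error",
                   "pretrained_transformer embedder requires a provider function")
  }
  structure(list(contextual_dim = contextual_dim, pos_dim = pos_dim,
                 entity_dim = entity_dim, mu = contextual_dim + pos_dim + entity_dim,
                 embedder = embedder, provider = provider,
                 embed_seed = embed_seed),
            class = "embedding_config")
}

contextual_embeddings <- function(surfaces, ecfg) {
  if (length(surfaces) == 0) {
    return(matrix(0, 0L, ecfg$contextual_dim))
  }
  if (ecfg$embedder == "pretrained_transformer") {
    A <- ecfg$provider(surfaces)
    stopifnot(nrow(A) == length(surfaces), ncol(A) == ecfg$contextual_dim)
    return(A)
  }
  t(vapply(surfaces, hash_embedding, numeric(ecfg$contextual_dim),
           dim = ecfg$contextual_dim, seed = ecfg$embed_seed))
}

# Map labels to 1-based rows of an embedding table whose last row is the
# reserved UNK slot; out-of-vocabulary labels are reported once per call.
label_indices <- function(labels, vocab, what) {
  idx <- match(labels, vocab)
  if (anyNA(idx)) {
    rlang::warn(sprintf("%d unknown %s label(s) mapped to UNK: %s",
                        sum(is.na(idx)), what,
                        paste(unique(labels[is.na(idx)]), collapse = ", ")),
                class = "bioevents_unknown_label")
    idx[is.na(idx)] <- length(vocab) + 1L
  }
  idx
}

#' Fused per-token input embeddings
#'
#' Produces the `n x mu` matrix `X` whose row `i` is
#' `[a_i ; b_i ; c_i]`: contextual embedding, POS embedding and entity-BIO
#' embedding of token `i`.
#'
#' @param sentence A [build_sentence_graph()] result.
#' @param model An [event_model()] (holds the embedding tables and config).
#' @return Numeric matrix of dimension `n x mu`.
#' @export
embed_tokens <- function(sentence, model) {
  n <- graph_size(sentence)
  ecfg <- model$config$embedding
  A <- contextual_embeddings(sentence$tokens$surface, ecfg)
  if (n == 0) return(matrix(0, 0L, ecfg$mu))
  bi <- label_indices(sentence$pos, model$schema$pos_vocab, "POS")
  ci <- label_indices(sentence$entity_bio, model$schema$entity_bio_labels, "entity-BIO")
  cbind(A, model$params$embed$pos_table[bi, , drop = FALSE],
        model$params$embed$ent_table[ci, , drop = FALSE])
}

# --- LSTM ------------------------------------------------------------------

# Gate layout in the fused weight matrices: columns [input, forget, cell, output].
init_lstm_params <- function(input_dim, hidden) {
  b <- matrix(0, 1L, 4L * hidden)
  b[1, (hidden + 1L):(2L * hidden)] <- 1  # forget-gate bias
  list(Wx = init_mat(input_dim, 4L * hidden, input_dim),
       Wh = init_mat(hidden, 4L * hidden, hidden),
       b = b)
}

lstm_forward <- function(X, p, reverse = FALSE) {
  hidden <- nrow(p$Wh)
  n <- nrow(X)
  H <- matrix(0, n, hidden)
  h <- matrix(0, 1L, hidden)
  cc <- matrix(0, 1L, hidden)
  order <- if (reverse) rev(seq_len(n)) else seq_len(n)
  for (t in order) {
    z <- X[t, , drop = FALSE] %*% p$Wx + h %*% p$Wh + p$b
    i <- sigmoid(z[, 1:hidden, drop = FALSE])
    f <- sigmoid(z[, (hidden + 1):(2 * hidden), drop = FALSE])
    g <- tanh(z[, (2 * hidden + 1):(3 * hidden), drop = FALSE])
    o <- sigmoid(z[, (3 * hidden + 1):(4 * hidden), drop = FALSE])
    cc <- f * cc + i * g
    h <- o * tanh(cc)
    H[t, ] <- h
  }
  H
}

#' Bidirectional LSTM context encoding
#'
#' Runs a forward and a backward LSTM over the fused embeddings and
#' concatenates the hidden states, giving the `n x 2*phi` context matrix `L`
#' (256 columns with the default 128 hidden units per direction).
#'
#' @param X `n x mu` input matrix from [embed_tokens()].
#' @param params List with `fwd` and `bwd` LSTM parameter sets
#'   (`Wx`, `Wh`, `b`), as created by [event_model()].
#' @return Numeric matrix `L` of dimension `n x 2*phi`.
#' @export
bilstm_context <- function(X, params) {
  cbind(lstm_forward(X, params$fwd, reverse = FALSE),
        lstm_forward(X, params$bwd, reverse = TRUE))
}

# --- Gated GCN -------------------------------------------------------------

init_gcn_params <- function(m, n_layers = 2) {
  layers <- lapply(seq_len(n_layers), function(j) {
    setNames(lapply(c("along", "rev", "loop"), function(r) {
      list(W = init_mat(m, m, m), b = matrix(0, 1L, m),
           V = init_mat(m, 1L, m), d = matrix(0, 1L, 1L))
    }), c("along", "rev", "loop"))
  })
  setNames(layers, paste0("layer", seq_len(n_layers)))
}

#' One gated graph-convolution layer
#'
#' Each token aggregates messages over its incoming edges in the simplified
#' three-relation multigraph. An edge `(u, v)` with relation class `r`
#' contributes `g_uv * (W_r h_u + b_r)` to node `v`, where the scalar gate
#' `g_uv = sigmoid(V_r h_u + d_r)` learns the importance of the edge. The sum
#' over incoming edges is passed through a ReLU; no neighbour-count
#' normalisation is applied. Because every node carries a self-loop, no node
#' is ever isolated.
#'
#' @param H `n x m` node representations entering the layer.
#' @param graph A `sentence_graph`.
#' @param layer_params One layer's parameter set: per relation class, a list
#'   `W` (`m x m`), `b` (`1 x m`), `V` (`m x 1`), `d` (scalar).
#' @param activation `"relu"` (default) or `"identity"`.
#' @return `n x m` node representations.
#' @export
gcn_layer <- function(H, graph, layer_params, activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  out <- matrix(0, nrow(H), ncol(H))
  for (r in c("along", "rev", "loop")) {
    p <- layer_params[[r]]
    adj <- relation_adjacency(graph, r)
    gate <- sigmoid(H %*% p$V + p$d[1])
    msg <- sweep(H %*% p$W, 2L, as.vector(p$b), "+")
    out <- out + crossprod(adj, msg * as.vector(gate))
  }
  if (activation == "relu") relu(out) else out
}

#' Stacked gated GCN
#'
#' Composes `k` gated graph-convolution layers (default 2), initialised from
#' the contextual embeddings `A`, and returns the syntactic information
#' matrix `S`.
#'
#' @param A `n x m` contextual embedding matrix.
#' @param graph A `sentence_graph`.
#' @param layers List of per-layer parameter sets ([gcn_layer()]).
#' @return `n x m` matrix `S`.
#' @export
run_gcn <- function(A, graph, layers) {
  H <- A
  for (lp in layers) H <- gcn_layer(H, graph, lp)
  H
}

# --- Multi-head self-attention --------------------------------------------

init_attention_params <- function(m, n_heads = 2) {
  if (m %% n_heads != 0) {
    stop_bioevents("bioevents_dimension_error",
                   sprintf("number of heads %d does not divide model width %d",
                           n_heads, m))
  }
  dk <- m %/% n_heads
  heads <- lapply(seq_len(n_heads), function(i) {
    list(Wq = init_mat(m, dk, m), Wk = init_mat(m, dk, m), Wv = init_mat(m, dk, m))
  })
  list(heads = setNames(heads, paste0("head", seq_len(n_heads))),
       Wo = init_mat(m, m, m))
}

attention_head_scores <- function(S, head) {
  dk <- ncol(head$Wq)
  softmax_rows((S %*% head$Wq) %*% t(S %*% head$Wk) / sqrt(dk))
}

#' Multi-head self-attention over GCN outputs
#'
#' Standard scaled dot-product attention with `H` heads of width `m/H`:
#' `head_i = softmax(Q_i K_i' / sqrt(d_k)) V_i`, heads concatenated and
#' projected by `W_O`. Applied to the syntactic matrix `S` to yield `M`.
#'
#' @param S `n x m` input matrix.
#' @param params Attention parameters: `heads` (each with `Wq`, `Wk`, `Wv`)
#'   and the output projection `Wo`.
#' @return `n x m` matrix `M`.
#' @export
multi_head_attention <- function(S, params) {
  m <- ncol(S)
  if (m %% length(params$heads) != 0) {
    stop_bioevents("bioevents_dimension_error",
                   "number of heads does not divide model width")
  }
  heads <- lapply(params$heads, function(h) {
    attention_head_scores(S, h) %*% (S %*% h$Wv)
  })
  do.call(cbind, heads) %*% params$Wo
}

#' Averaged attention score matrix
#'
#' The `n x n` matrix of attention scores averaged over heads, used for
#' heat-map visualisation of which tokens attend to which. Each row sums
#' to 1.
#'
#' @inheritParams multi_head_attention
#' @return `n x n` row-stochastic matrix of class `attention_matrix` with
#'   token surfaces as dimnames when available.
#' @param tokens Optional character vector of token surfaces for labelling.
#' @export
export_attention <- function(S, params, tokens = NULL) {
  scores <- lapply(params$heads, function(h) attention_head_scores(S, h))
  avg <- Reduce(`+`, scores) / length(scores)
  if (!is.null(tokens)) dimnames(avg) <- list(tokens, tokens)
  structure(avg, class = c("attention_matrix", "matrix"))
}

# --- Tagger ----------------------------------------------------------------

#' Tagger LSTM over fused context and syntax streams
#'
#' A unidirectional LSTM reads the row-wise concatenation `[L ; M]` of the
#' BiLSTM context matrix and the attention output, producing the source
#' matrix `O` consumed by both the trigger and the argument-role classifier.
#'
#' @param L `n x 2*phi` context matrix.
#' @param M `n x m` syntax-attention matrix.
#' @param params Tagger LSTM parameters (`Wx`, `Wh`, `b`).
#' @return `n x d_O` source matrix `O`.
#' @export
tagger <- function(L, M, params) {
  if (nrow(L) != nrow(M)) {
    stop_bioevents("bioevents_shape_mismatch",
                   sprintf("L has %d rows but M has %d", nrow(L), nrow(M)))
  }
  lstm_forward(cbind(L, M), params)
}

#' Per-token trigger label distribution
#'
#' Softmax over the BIO trigger vocabulary for every token:
#' `soft_k = softmax(W_tri O_k + b_tri)`. This distribution is both decoded
#' into trigger spans and fused into the argument-role classifier.
#'
#' @param O Source matrix from [tagger()].
#' @param params List with `W` (`d_O x |V_tri|`) and `b` (`1 x |V_tri|`).
#' @return `n x |V_tri|` row-stochastic matrix.
#' @export
trigger_scores <- function(O, params) {
  softmax_rows(sweep(O %*% params$W, 2L, as.vector(params$b), "+"))
}
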