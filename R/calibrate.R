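#' Data-dependent initialisation of a freshly created model
#'
#' Deep stacks of randomly initialised LSTMs propagate a large
#' token-independent mean while shrinking the per-token variation that
#' carries the labelling signal; with a small fixed SGD learning rate the
#' classifier heads then receive almost no gradient. Before training, this
#' routine runs the untrained network over (a sample of) the training
#' sentences and rescales each module so that, at initialisation, its
#' pre-activations are centred with roughly unit variance across tokens:
#' per-unit column scaling and mean-absorbing bias for the BiLSTM, GCN
#' layers, tagger and both classifier heads, plus column scaling of the
#' attention output projection. This is the classic layer-sequential
#' unit-variance idea adapted to the recurrent/graph stack; it changes only
#' the starting point of optimisation, not the architecture.
#'
#' @param model A freshly initialised [event_model()].
#' @param sentences Encoded sentences from [prepare_corpus()]; a few dozen
#'   suffice.
#' @param gate_bias Initial bias for the input and output gates of the
#'   calibrated LSTMs (default 1: mostly-open gates, so the current token
#'   passes through at initialisation).
#' @param tagger_gain Extra gain on the tagger's input weights after
#'   normalisation (default 2.5), pushing its gates into their
#'   high-contrast regime so the source matrix has strong per-token
#'   variation at initialisation.
#' @return The calibrated `event_model`.
#' @export
calibrate_model <- function(model, sentences, gate_bias = 1, tagger_gain = 2.5) {
  stopifnot(length(sentences) > 0)
  embed_matrix <- function(s) {
    cbind(s$A, s$pos_onehot %*% model$params$embed$pos_table,
          s$ent_onehot %*% model$params$embed$ent_table)
  }
  col_sds <- function(m) {
    s <- apply(m, 2L, stats::sd)
    s[!is.finite(s) | s < 1e-6] <- 1
    s
  }
  # absorb the data mean and variance of Z = X %*% Wx into Wx and b so the
  # non-recurrent pre-activation is ~N(0,1) per unit, with chosen gate biases
  normalise_lstm <- function(p, X_all, hidden) {
    Z <- X_all %*% p$Wx
    s <- col_sds(Z)
    p$Wx <- sweep(p$Wx, 2L, s, "/")
    base <- rep(0, 4L * hidden)
    base[1:hidden] <- gate_bias                       # input gate open
    base[(3L * hidden + 1L):(4L * hidden)] <- gate_bias  # output gate open
    p$b <- matrix(base - colMeans(Z) / s, 1L)
    p  # recurrent weights keep their 1/sqrt(hidden) scale
  }
  X_all <- do.call(rbind, lapply(sentences, embed_matrix))
  phi <- model$config$bilstm_hidden
  model$params$bilstm$fwd <- normalise_lstm(model$params$bilstm$fwd, X_all, phi)
  model$params$bilstm$bwd <- normalise_lstm(model$params$bilstm$bwd, X_all, phi)

  # GCN layers, sequentially: centre/scale the summed pre-activation
  gcn_preact <- function(H, graph, lp) {
    out <- matrix(0, nrow(H), ncol(H))
    for (r in c("along", "rev", "loop")) {
      p <- lp[[r]]
      adj <- relation_adjacency(graph, r)
      gate <- sigmoid(H %*% p$V + p$d[1])
      msg <- sweep(H %*% p$W, 2L, as.vector(p$b), "+")
      out <- out + crossprod(adj, msg * as.vector(gate))
    }
    out
  }
  H_list <- lapply(sentences, `[[`, "A")
  for (l in seq_along(model$params$gcn)) {
    pre <- do.call(rbind, lapply(seq_along(sentences), function(k) {
      gcn_preact(H_list[[k]], sentences[[k]]$graph, model$params$gcn[[l]])
    }))
    s <- col_sds(pre)
    mu <- colMeans(pre)
    for (r in c("along", "rev", "loop")) {
      model$params$gcn[[l]][[r]]$W <-
        sweep(model$params$gcn[[l]][[r]]$W, 2L, s, "/")
      # each relation absorbs a third of the centring shift
      model$params$gcn[[l]][[r]]$b <- matrix(-mu / (3 * s), 1L)
    }
    H_list <- lapply(seq_along(sentences), function(k) {
      gcn_layer(H_list[[k]], sentences[[k]]$graph, model$params$gcn[[l]])
    })
  }

  # attention output projection: unit-variance columns of M
  M_pre <- do.call(rbind, lapply(seq_along(sentences), function(k) {
    S <- H_list[[k]]
    heads <- lapply(model$params$attn$heads, function(h) {
      attention_head_scores(S, h) %*% (S %*% h$Wv)
    })
    do.call(cbind, heads) %*% model$params$attn$Wo
  }))
  model$params$attn$Wo <- sweep(model$params$attn$Wo, 2L, col_sds(M_pre), "/")

  # tagger LSTM over the now-calibrated [L ; M]
  fws <- lapply(sentences, forward_sentence, model = model)
  LM <- do.call(rbind, lapply(fws, function(f) cbind(f$L, f$M)))
  model$params$tagger <- normalise_lstm(model$params$tagger, LM,
                                        model$config$tagger_hidden)
  # push the tagger pre-activations into the gates' high-contrast regime so
  # the source matrix O carries strong per-token variation at initialisation
  model$params$tagger$Wx <- model$params$tagger$Wx * tagger_gain
  model$params$tagger$b <- model$params$tagger$b * tagger_gain

  # classifier heads: centred, unit-variance logits
  fws <- lapply(sentences, forward_sentence, model = model)
  O_all <- do.call(rbind, lapply(fws, `[[`, "O"))
  Zt <- O_all %*% model$params$tri$W
  st <- col_sds(Zt)
  model$params$tri$W <- sweep(model$params$tri$W, 2L, st, "/")
  model$params$tri$b <- matrix(-colMeans(Zt) / st, 1L)
  feats <- list()
  for (k in seq_along(sentences)) {
    s <- sentences[[k]]
    if (is.null(s$pool_trig)) next
    FM <- if (model$config$fusion) cbind(fws[[k]]$O, fws[[k]]$soft) else fws[[k]]$O
    feats[[length(feats) + 1L]] <- cbind(s$pool_trig %*% FM, s$pool_cand %*% FM)
  }
  if (length(feats) > 0) {
    Fa <- do.call(rbind, feats)
    Ze <- Fa %*% model$params$event$W
    se <- col_sds(Ze)
    model$params$event$W <- sweep(model$params$event$W, 2L, se, "/")
    model$params$event$b <- matrix(-colMeans(Ze) / se, 1L)
  }
  model
}
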