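# Tape-recorded forward pass used by the training loop. The numeric layer
# functions in layers.R are the reference semantics; a regression test pins
# the tape forward (in eval mode) to them.

lstm_tape <- function(tp, X_id, n, Wx, Wh, b, hidden, reverse = FALSE) {
  ad_lstm(tp, X_id, Wx, Wh, b, hidden, reverse = reverse)
}

gcn_tape <- function(tp, H_id, sent, leaf, layer_name) {
  parts <- integer(0)
  for (r in c("along", "rev", "loop")) {
    pre <- paste0("gcn.", layer_name, ".", r)
    gate <- ad_sigmoid(tp, ad_add_bias(tp, ad_matmul(tp, H_id, leaf[[paste0(pre, ".V")]]),
                                       leaf[[paste0(pre, ".d")]]))
    msg <- ad_add_bias(tp, ad_matmul(tp, H_id, leaf[[paste0(pre, ".W")]]),
                       leaf[[paste0(pre, ".b")]])
    adj_t <- ad_leaf(tp, sent$adj_t[[r]])
    parts <- c(parts, ad_matmul(tp, adj_t, ad_scale_rows(tp, msg, gate)))
  }
  ad_relu(tp, ad_add(tp, ad_add(tp, parts[1], parts[2]), parts[3]))
}

attention_tape <- function(tp, S_id, leaf, n_heads) {
  heads <- integer(n_heads)
  for (i in seq_len(n_heads)) {
    pre <- paste0("attn.heads.head", i)
    Q <- ad_matmul(tp, S_id, leaf[[paste0(pre, ".Wq")]])
    K <- ad_matmul(tp, S_id, leaf[[paste0(pre, ".Wk")]])
    V <- ad_matmul(tp, S_id, leaf[[paste0(pre, ".Wv")]])
    dk <- ncol(tp_val(tp, Q))
    scores <- ad_softmax_rows(tp, ad_affine(tp, ad_matmul(tp, Q, ad_transpose(tp, K)),
                                            1 / sqrt(dk)))
    heads[i] <- ad_matmul(tp, scores, V)
  }
  ad_matmul(tp, ad_cbind(tp, heads), leaf[["attn.Wo"]])
}

dice_term_tape <- function(tp, p_id, cfg, reduce = "mean") {
  # y = 1 for every scored decision: 1 - (2 w + lambda) / (w + 1 + lambda),
  # w = (1 - p)^beta * p
  w <- if (cfg$beta == 0) {
    p_id
  } else {
    ad_mul(tp, ad_pow(tp, ad_affine(tp, p_id, -1, 1), cfg$beta), p_id)
  }
  frac <- ad_div(tp, ad_affine(tp, w, 2, cfg$lambda), ad_affine(tp, w, 1, 1 + cfg$lambda))
  v <- ad_affine(tp, frac, -1, 1)
  if (reduce == "sum") ad_sum(tp, v) else ad_mean(tp, v)
}

ce_term_tape <- function(tp, p_id, reduce = "mean") {
  v <- ad_affine(tp, ad_log(tp, p_id), -1, 0)
  if (reduce == "sum") ad_sum(tp, v) else ad_mean(tp, v)
}

# Full forward pass for one sentence; returns the scalar loss node.
forward_sentence_tape <- function(tp, sent, model, leaf, train = TRUE) {
  cfg <- model$config
  n <- graph_size(sent$graph)
  phi <- cfg$bilstm_hidden
  u <- cfg$tagger_hidden
  A_id <- ad_leaf(tp, sent$A)
  B_id <- ad_matmul(tp, ad_leaf(tp, sent$pos_onehot), leaf[["embed.pos_table"]])
  C_id <- ad_matmul(tp, ad_leaf(tp, sent$ent_onehot), leaf[["embed.ent_table"]])
  X_id <- ad_cbind(tp, c(A_id, B_id, C_id))
  if (train && cfg$dropout > 0) X_id <- ad_dropout(tp, X_id, cfg$dropout)
  L_id <- ad_cbind(tp, c(
    lstm_tape(tp, X_id, n, leaf[["bilstm.fwd.Wx"]], leaf[["bilstm.fwd.Wh"]],
              leaf[["bilstm.fwd.b"]], phi, reverse = FALSE),
    lstm_tape(tp, X_id, n, leaf[["bilstm.bwd.Wx"]], leaf[["bilstm.bwd.Wh"]],
              leaf[["bilstm.bwd.b"]], phi, reverse = TRUE)))
  S_id <- A_id
  for (ln in names(model$params$gcn)) S_id <- gcn_tape(tp, S_id, sent, leaf, ln)
  M_id <- attention_tape(tp, S_id, leaf, cfg$attention_heads)
  T_id <- ad_cbind(tp, c(L_id, M_id))
  O_id <- lstm_tape(tp, T_id, n, leaf[["tagger.Wx"]], leaf[["tagger.Wh"]],
                    leaf[["tagger.b"]], u)
  soft_id <- ad_softmax_rows(tp, ad_add_bias(tp, ad_matmul(tp, O_id, leaf[["tri.W"]]),
                                             leaf[["tri.b"]]))
  p_trig <- ad_gather(tp, soft_id, seq_len(n), sent$trigger_gold)
  reduce <- cfg$loss_reduction %||% "sum"
  trig_term <- if (cfg$loss == "dice") {
    dice_term_tape(tp, p_trig, cfg$dice, reduce)
  } else {
    ce_term_tape(tp, p_trig, reduce)
  }
  loss_id <- trig_term
  np <- nrow(sent$pairs)
  if (np > 0) {
    FM_id <- if (cfg$fusion) ad_cbind(tp, c(O_id, soft_id)) else O_id
    Ftr <- ad_matmul(tp, ad_leaf(tp, sent$pool_trig), FM_id)
    Fcn <- ad_matmul(tp, ad_leaf(tp, sent$pool_cand), FM_id)
    feats <- ad_cbind(tp, c(Ftr, Fcn))
    probs <- ad_softmax_rows(tp, ad_add_bias(tp, ad_matmul(tp, feats, leaf[["event.W"]]),
                                             leaf[["event.b"]]))
    p_role <- ad_gather(tp, probs, seq_len(np), sent$role_gold)
    ev_term <- if (cfg$loss == "dice") {
      dice_term_tape(tp, p_role, cfg$dice, reduce)
    } else {
      ce_term_tape(tp, p_role, reduce)
    }
    loss_id <- ad_add(tp, trig_term, ev_term)
  }
  loss_id
}
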