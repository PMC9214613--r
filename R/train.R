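#' Train the joint extraction model
#'
#' Stochastic gradient descent on the joint loss. Each epoch the prepared
#' sentences are sorted by length and chunked into batches; for every batch
#' the full forward pass (embeddings, BiLSTM, gated GCN, attention, tagger,
#' both classifier heads) is recorded on an autodiff tape, the batch-mean
#' loss is backpropagated, and all parameters are updated. Candidate pairs
#' use gold trigger locations (teacher forcing) while the fused trigger
#' distribution remains the model's own prediction. Training is a
#' deterministic function of the model, the data and `seed`.
#'
#' @param model An [event_model()].
#' @param sentences Encoded sentences from [prepare_corpus()].
#' @param epochs Number of epochs (default 50).
#' @param batch_size Sentences per SGD update (default 1: at the fixed
#'   small learning rate, toy corpora need many updates per epoch).
#' @param lr Learning rate (default 0.01, plain SGD).
#' @param clip Global gradient-norm clip (default 5); an occasional
#'   exploding recurrent gradient would otherwise throw a single SGD step —
#'   and the run — far off course.
#' @param seed Seed for dropout masks.
#' @param verbose Print the epoch loss.
#' @return The trained `event_model`, with an appended `log` tibble
#'   (`epoch`, `loss`). Throws `bioevents_nonfinite_loss` (with the epoch in
#'   the message) if the loss diverges.
#' @export
train_event_model <- function(model, sentences, epochs = 50, batch_size = 1,
                              lr = 0.01, clip = 5, seed = 1, verbose = FALSE) {
  stopifnot(epochs >= 0, batch_size >= 1, lr > 0)
  if (length(sentences) == 0 || epochs == 0) return(model)
  flat <- flatten_params(model$params)
  lens <- vapply(sentences, function(s) graph_size(s$graph), 0L)
  sentences <- sentences[order(lens)]
  n_batches <- ceiling(length(sentences) / batch_size)
  batches <- split(sentences, rep(seq_len(n_batches), each = batch_size,
                                  length.out = length(sentences)))
  epoch0 <- if (nrow(model$log) > 0) max(model$log$epoch) else 0L
  log <- vector("list", epochs)
  with_preserved_rng({
    set.seed(seed)
    for (ep in seq_len(epochs)) {
      batch_losses <- numeric(n_batches)
      for (bi in seq_len(n_batches)) {
        batch <- batches[[bi]]
        tp <- tape_new(4096L)
        leaf <- lapply(flat, ad_leaf, tp = tp)
        sent_losses <- vapply(batch, function(s) {
          forward_sentence_tape(tp, s, model, leaf, train = TRUE)
        }, 0L)
        total <- ad_affine(tp, Reduce(function(a, b) ad_add(tp, a, b), sent_losses),
                           1 / length(sent_losses))
        batch_losses[bi] <- tp_val(tp, total)[1]
        if (!is.finite(batch_losses[bi])) {
          stop_bioevents("bioevents_nonfinite_loss",
                         sprintf("non-finite loss in epoch %d, batch %d",
                                 epoch0 + ep, bi))
        }
        grads <- backward(tp, total)
        gs <- grads[vapply(leaf, identity, 0L)]
        gnorm <- sqrt(sum(vapply(gs, function(g) {
          if (is.null(g)) 0 else sum(g * g)
        }, 0)))
        scale <- if (is.finite(gnorm) && gnorm > clip) clip / gnorm else 1
        for (nm in names(flat)) {
          g <- grads[[leaf[[nm]]]]
          if (!is.null(g)) flat[[nm]] <- flat[[nm]] - lr * scale * g
        }
        # updated parameters must be visible to the next batch's forward
        model$params <- relist_params(model$params, flat)
      }
      log[[ep]] <- tibble::tibble(epoch = epoch0 + ep, loss = mean(batch_losses))
      if (verbose) {
        message(sprintf("epoch %d: loss %.5f", epoch0 + ep, mean(batch_losses)))
      }
    }
  })
  model$log <- dplyr::bind_rows(model$log, dplyr::bind_rows(log))
  model
}

#' Save / load a trained model as plain text
#'
#' Serialises the model (schema, configuration minus any embedding provider
#' function, and all parameter matrices) to JSON so checkpoints survive in
#' text-only repositories.
#'
#' @param model An [event_model()].
#' @param path Destination file.
#' @return `path` (write) or the restored `event_model` (read).
#' @export
write_model_json <- function(model, path) {
  flat <- flatten_params(model$params)
  payload <- list(
    schema = unclass(model$schema),
    config = serialise_config(model$config),
    params = lapply(flat, function(m) list(dim = dim(m), data = as.vector(m))),
    log = model$log
  )
  writeLines(jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE), path)
  invisible(path)
}

serialise_config <- function(cfg) {
  e <- cfg$embedding
  list(contextual_dim = e$contextual_dim, pos_dim = e$pos_dim,
       entity_dim = e$entity_dim, embedder = e$embedder,
       embed_seed = e$embed_seed, bilstm_hidden = cfg$bilstm_hidden,
       gcn_layers = cfg$gcn_layers, attention_heads = cfg$attention_heads,
       tagger_hidden = cfg$tagger_hidden, dropout = cfg$dropout,
       fusion = cfg$fusion, loss = cfg$loss,
       loss_reduction = cfg$loss_reduction %||% "sum",
       lambda = cfg$dice$lambda, beta = cfg$dice$beta)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  payload <- jsonlite::fromJSON(paste(readLines(path, warn = FALSE), collapse = ""),
                                simplifyVector = TRUE)
  sc <- payload$schema
  schema <- corpus_schema(sc$trigger_types, sc$entity_types, sc$pos_vocab,
                          sc$role_labels, sc$nesting_capable %||% character())
  cj <- payload$config
  cfg <- model_config(
    embedding = embedding_config(cj$contextual_dim, cj$pos_dim, cj$entity_dim,
                                 embedder = cj$embedder, embed_seed = cj$embed_seed),
    bilstm_hidden = cj$bilstm_hidden, gcn_layers = cj$gcn_layers,
    attention_heads = cj$attention_heads, tagger_hidden = cj$tagger_hidden,
    dropout = cj$dropout, fusion = cj$fusion, loss = cj$loss,
    lambda = cj$lambda, beta = cj$beta,
    loss_reduction = cj$loss_reduction %||% "sum")
  model <- event_model(schema, cfg, seed = 1)
  flat <- lapply(payload$params, function(p) {
    matrix(p$data, p$dim[1], p$dim[2])
  })
  model$params <- relist_params(model$params, flat)
  model$log <- tibble::as_tibble(payload$log)
  model
}
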