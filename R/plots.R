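#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_line labs
#'   scale_fill_gradient theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Tidy an attention matrix into long format
#'
#' @param x An `attention_matrix` from [export_attention()] or
#'   [sentence_attention()].
#' @param ... Unused.
#' @return Tibble with `from`, `to` (token labels or indices) and `score`.
#' @export
tidy.attention_matrix <- function(x, ...) {
  n <- nrow(x)
  labels <- rownames(x) %||% as.character(seq_len(n))
  labels <- make.unique(labels)
  tibble::tibble(
    from = factor(rep(labels, times = n), levels = labels),
    to = factor(rep(labels, each = n), levels = labels),
    score = as.vector(unclass(x))
  )
}

#' Heat map of head-averaged attention scores
#'
#' Row-wise heat map: each row shows how strongly a token attends to every
#' other token, averaged over attention heads. Darker cells mark stronger
#' interactions — for a well-trained model, trigger rows light up on their
#' arguments.
#'
#' @param object An `attention_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.attention_matrix <- function(object, ...) {
  df <- tidy.attention_matrix(object)
  ggplot(df, aes(x = .data$to, y = .data$from, fill = .data$score)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "darkblue") +
    labs(x = "attended token", y = "token", fill = "score") +
    theme_minimal()
}

#' Training loss curve
#'
#' @param object A trained [event_model()].
#' @param ... Unused.
#' @return A ggplot object of epoch versus mean batch loss.
#' @export
autoplot.event_model <- function(object, ...) {
  ggplot(object$log, aes(x = .data$epoch, y = .data$loss)) +
    geom_line() +
    labs(x = "epoch", y = "joint loss") +
    theme_minimal()
}

#' @export
glance.event_model <- function(x, ...) {
  tibble::tibble(
    n_parameters = sum(vapply(flatten_params(x$params), length, 0L)),
    epochs_trained = if (nrow(x$log) > 0) max(x$log$epoch) else 0L,
    final_loss = if (nrow(x$log) > 0) x$log$loss[nrow(x$log)] else NA_real_
  )
}
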