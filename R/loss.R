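#' Self-adjusting Dice loss configuration
#'
#' @param lambda Nonnegative smoothing constant (default 1).
#' @param beta Nonnegative focusing exponent; the `(1-p)^beta` factor
#'   down-weights easy examples (default 1).
#' @return A list of class `dice_config`.
#' @export
dice_config <- function(lambda = 1, beta = 1) {
  stopifnot(lambda >= 0, beta >= 0)
  structure(list(lambda = lambda, beta = beta), class = "dice_config")
}

#' Self-adjusting Dice loss for one decision
#'
#' A soft-F1-style loss on the probability `p` the model assigns to the gold
#' class of a decision:
#' \deqn{1 - \frac{2 (1-p)^\beta p \, y + \lambda}{(1-p)^\beta p + y + \lambda}}
#' With `beta = 0, lambda = 0` this is the plain soft Dice; the
#' `(1-p)^beta` factor self-adjusts the contribution of easy examples, which
#' balances precision and recall on heavily imbalanced label sets such as
#' mostly-`O` BIO tagging. Vectorised over `p` and `y`.
#'
#' @param p Predicted probability/ies of the gold class, in `[0, 1]`.
#' @param y Gold indicator(s), 0 or 1 (1 when scoring the gold class).
#' @param cfg A [dice_config()].
#' @return Loss value(s) in `[0, 1]` for `lambda = 0`.
#' @export
token_dice <- function(p, y = 1, cfg = dice_config()) {
  stopifnot(all(p >= 0), all(p <= 1))
  w <- (1 - p)^cfg$beta * p
  1 - (2 * w * y + cfg$lambda) / (w + y + cfg$lambda)
}

gold_probs <- function(dist, gold_idx) {
  stopifnot(nrow(dist) == length(gold_idx))
  dist[cbind(seq_len(nrow(dist)), gold_idx)]
}

#' Joint Dice loss over trigger and argument decisions
#'
#' For each sentence, the reduced [token_dice()] over its per-token trigger
#' decisions plus the reduced loss over its (trigger, candidate) role
#' decisions — the two task terms weighted equally — averaged over the `N`
#' sentences. Each decision is scored on the probability the model assigns
#' to its gold label; the within-sentence reduction is a sum by default
#' (see [model_config()]). Sentences without candidate pairs contribute
#' their trigger term alone.
#'
#' @param sentences List, one entry per sentence, each a list with
#'   `trigger_probs` (`n x |V_tri|` row-stochastic), `trigger_gold`
#'   (1-based gold column per token), and optionally `role_probs` /
#'   `role_gold` for the pair decisions.
#' @param cfg A [dice_config()].
#' @param reduction Within-sentence reduction, `"sum"` (default) or
#'   `"mean"`.
#' @return Scalar loss.
#' @export
joint_dice_loss <- function(sentences, cfg = dice_config(),
                            reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  red <- if (reduction == "sum") sum else mean
  per_sentence <- vapply(sentences, function(s) {
    trig <- red(token_dice(gold_probs(s$trigger_probs, s$trigger_gold), 1, cfg))
    ev <- if (!is.null(s$role_probs) && nrow(s$role_probs) > 0) {
      red(token_dice(gold_probs(s$role_probs, s$role_gold), 1, cfg))
    } else {
      0
    }
    trig + ev
  }, 0)
  mean(per_sentence)
}

#' Cross-entropy baseline loss
#'
#' Negative log-likelihood of the gold labels with the same
#' per-sentence-mean, then mean-over-sentences reduction as
#' [joint_dice_loss()]; used by the loss-function ablation.
#'
#' @inheritParams joint_dice_loss
#' @return Scalar loss.
#' @export
cross_entropy_loss <- function(sentences, reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  red <- if (reduction == "sum") sum else mean
  per_sentence <- vapply(sentences, function(s) {
    trig <- red(-log(gold_probs(s$trigger_probs, s$trigger_gold)))
    ev <- if (!is.null(s$role_probs) && nrow(s$role_probs) > 0) {
      red(-log(gold_probs(s$role_probs, s$role_gold)))
    } else {
      0
    }
    trig + ev
  }, 0)
  mean(per_sentence)
}
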