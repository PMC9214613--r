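#' Enumerate (trigger, candidate) pairs for argument classification
#'
#' Candidates for a trigger's role slots are all entities of the sentence and
#' all *other* triggers (an event filling a role of another event is what
#' makes a structure nested). With `k_t` triggers and `k_e` entities this
#' yields `k_t * k_e + k_t * (k_t - 1)` pairs, ordered deterministically by
#' trigger start then candidate start.
#'
#' @param triggers Tibble of trigger spans (`type`, `token_start`,
#'   `token_end`, optionally `id`), typically decoded by [bio_to_spans()].
#' @param entities Tibble of entity spans (same columns plus `id`).
#' @return Tibble of pairs: `trigger` (row index into `triggers`),
#'   `candidate_kind` (`"entity"` or `"trigger"`), `candidate` (row index
#'   into the respective table).
#' @export
enumerate_candidates <- function(triggers, entities) {
  kt <- nrow(triggers)
  out <- list()
  if (kt > 0) {
    for (i in order(triggers$token_start)) {
      cand <- list()
      if (nrow(entities) > 0) {
        for (j in seq_len(nrow(entities))) {
          cand[[length(cand) + 1L]] <- list(kind = "entity", idx = j,
                                            start = entities$token_start[j])
        }
      }
      for (j in seq_len(kt)) {
        if (j != i) {
          cand[[length(cand) + 1L]] <- list(kind = "trigger", idx = j,
                                            start = triggers$token_start[j])
        }
      }
      if (length(cand) > 0) {
        cand <- cand[order(vapply(cand, `[[`, 0L, "start"))]
        for (cn in cand) {
          out[[length(out) + 1L]] <- list(trigger = i, candidate_kind = cn$kind,
                                          candidate = cn$idx)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(trigger = integer(), candidate_kind = character(),
                          candidate = integer()))
  }
  tibble::tibble(
    trigger = vapply(out, `[[`, 0L, "trigger"),
    candidate_kind = vapply(out, `[[`, "", "candidate_kind"),
    candidate = vapply(out, `[[`, 0L, "candidate")
  )
}

span_token_range <- function(tbl, idx) tbl$token_start[idx]:tbl$token_end[idx]

# Mean-pool rows of FM over each span's token run; FM is [O ; soft] (fusion)
# or O alone.
pool_span <- function(FM, run) {
  if (length(run) == 0) {
    stop_bioevents("bioevents_empty_span", "cannot pool an empty span")
  }
  colMeans(FM[run, , drop = FALSE])
}

#' Classify the role of each (trigger, candidate) pair
#'
#' For each pair, the trigger vector `Tr` and candidate vector `Can` are
#' mean-pooled over the span's tokens from the fused per-token representation
#' `[O_k ; soft_k]` — the source matrix concatenated with the trigger
#' classifier's softmax distribution, so the role decision conditions on
#' trigger uncertainty. The pair feature `[Tr ; Can]` goes through a softmax
#' over the role vocabulary. With `fusion = FALSE` the `soft` blocks are
#' omitted (the conventional shared-source joint model, kept for ablation).
#'
#' @param pairs Pair table from [enumerate_candidates()].
#' @param triggers,entities Span tables the pair indices refer to.
#' @param O Source matrix from [tagger()].
#' @param soft Trigger distribution from [trigger_scores()].
#' @param params Role classifier parameters `W`, `b`.
#' @param fusion Include the trigger softmax blocks (default `TRUE`).
#' @return `nrow(pairs) x |roles|` row-stochastic matrix.
#' @export
role_classify <- function(pairs, triggers, entities, O, soft, params,
                          fusion = TRUE) {
  FM <- if (fusion) cbind(O, soft) else O
  feats <- t(vapply(seq_len(nrow(pairs)), function(k) {
    tr_run <- span_token_range(triggers, pairs$trigger[k])
    cn_tbl <- if (pairs$candidate_kind[k] == "entity") entities else triggers
    cn_run <- span_token_range(cn_tbl, pairs$candidate[k])
    c(pool_span(FM, tr_run), pool_span(FM, cn_run))
  }, numeric(2L * ncol(FM))))
  if (nrow(pairs) == 0) return(matrix(0, 0L, ncol(params$W)))
  softmax_rows(sweep(feats %*% params$W, 2L, as.vector(params$b), "+"))
}

#' Assemble (possibly nested) events from role decisions
#'
#' Builds one event per predicted trigger. Every pair whose argmax role is
#' not `None` becomes an argument; a trigger-typed filler is resolved to that
#' trigger's event, which is how nesting arises. Should the predicted
#' event-to-event links form a cycle, links are admitted greedily in
#' decreasing probability and any link that would close a cycle is discarded.
#' Triggers without arguments still yield (argument-less) events.
#'
#' @param pairs Pair table from [enumerate_candidates()].
#' @param role_probs Matrix from [role_classify()], columns named or ordered
#'   as `role_labels`.
#' @param triggers Trigger table with an `id` column (`T` ids).
#' @param entities Entity table with an `id` column.
#' @param role_labels Role vocabulary; the last label must be `None`.
#' @param event_ids Optional character vector of ids for the events (one per
#'   trigger); defaults to `E1, E2, ...`.
#' @return List of [event_record()] objects, one per trigger, in trigger
#'   order.
#' @export
assemble_events <- function(pairs, role_probs, triggers, entities,
                            role_labels = c("Theme", "Cause", "None"),
                            event_ids = NULL) {
  kt <- nrow(triggers)
  event_ids <- event_ids %||% paste0("E", seq_len(kt))
  args_of <- rep(list(list()), kt)
  decided <- if (nrow(pairs) > 0) {
    lab_idx <- apply(role_probs, 1L, which.max)
    keep <- role_labels[lab_idx] != "None"
    tibble::tibble(
      trigger = pairs$trigger[keep],
      candidate_kind = pairs$candidate_kind[keep],
      candidate = pairs$candidate[keep],
      role = role_labels[lab_idx][keep],
      prob = role_probs[cbind(seq_len(nrow(pairs)), lab_idx)][keep]
    )
  } else {
    tibble::tibble(trigger = integer(), candidate_kind = character(),
                   candidate = integer(), role = character(), prob = numeric())
  }
  # entity arguments are always admitted
  ent_rows <- which(decided$candidate_kind == "entity")
  for (k in ent_rows) {
    t <- decided$trigger[k]
    args_of[[t]][[length(args_of[[t]]) + 1L]] <-
      list(role = decided$role[k], filler_id = entities$id[decided$candidate[k]])
  }
  # event-to-event links: greedy by probability, skipping cycle-closing links
  ev_rows <- which(decided$candidate_kind == "trigger")
  ev_rows <- ev_rows[order(-decided$prob[ev_rows])]
  reach <- matrix(FALSE, kt, kt)  # reach[i, j]: j reachable from i via links
  for (k in ev_rows) {
    from <- decided$trigger[k]
    to <- decided$candidate[k]
    if (reach[to, from] || from == to) next  # would close a cycle
    args_of[[from]][[length(args_of[[from]]) + 1L]] <-
      list(role = decided$role[k], filler_id = event_ids[to])
    reach[from, to] <- TRUE
    for (i in seq_len(kt)) {
      if (reach[i, from]) reach[i, ] <- reach[i, ] | reach[from, ]
    }
    reach[from, ] <- reach[from, ] | reach[to, ]
  }
  lapply(seq_len(kt), function(i) {
    event_record(event_ids[i], triggers$id[i], args_of[[i]])
  })
}
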