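# Strict recursive evaluation of predicted against gold events, with the
# simple/nested stratification.

trigger_signature <- function(tr) sprintf("%s[%d,%d)", tr$type, tr$start, tr$end)

# Recursive structural signature of an event: trigger (span + type) plus the
# sorted multiset of (role, filler signature); event fillers recurse.
event_signatures <- function(doc) {
  trig_by_id <- setNames(doc$triggers, vapply(doc$triggers, `[[`, "", "id"))
  ent_by_id <- setNames(doc$entities, vapply(doc$entities, `[[`, "", "id"))
  ev_by_id <- setNames(doc$events, vapply(doc$events, `[[`, "", "id"))
  memo <- new.env(parent = emptyenv())
  sig <- function(eid) {
    if (!is.null(memo[[eid]])) return(memo[[eid]])
    ev <- ev_by_id[[eid]]
    args <- vapply(ev$args, function(a) {
      fs <- if (a$filler_id %in% names(ev_by_id)) {
        sig(a$filler_id)
      } else if (a$filler_id %in% names(ent_by_id)) {
        e <- ent_by_id[[a$filler_id]]
        sprintf("%s[%d,%d)", e$type, e$start, e$end)
      } else {
        trigger_signature(trig_by_id[[a$filler_id]])
      }
      paste0(a$role, "=", fs)
    }, "")
    s <- paste0(trigger_signature(trig_by_id[[ev$trigger_id]]),
                "{", paste(sort(args), collapse = ","), "}")
    memo[[eid]] <- s
    s
  }
  vapply(names(ev_by_id), sig, "")
}

# TRUE per event: does any argument chain contain an event filler?
event_is_nested <- function(doc) {
  ev_ids <- vapply(doc$events, `[[`, "", "id")
  vapply(doc$events, function(ev) {
    any(vapply(ev$args, `[[`, "", "filler_id") %in% ev_ids)
  }, logical(1))
}

multiset_tp <- function(gold, pred) {
  if (length(gold) == 0 || length(pred) == 0) return(0L)
  gt <- table(gold)
  pt <- table(pred)
  common <- intersect(names(gt), names(pt))
  sum(pmin(gt[common], pt[common]))
}

# vectorised micro P/R/F1 in percent; undefined precision (no predictions)
# reported as 0 by convention
add_prf <- function(tbl) {
  dplyr::mutate(
    tbl,
    precision = ifelse(.data$tp + .data$fp > 0, 100 * .data$tp / (.data$tp + .data$fp), 0),
    recall = ifelse(.data$tp + .data$fn > 0, 100 * .data$tp / (.data$tp + .data$fn), 0),
    f1 = ifelse(.data$precision + .data$recall > 0,
                2 * .data$precision * .data$recall / (.data$precision + .data$recall), 0)
  )
}

#' Evaluate predicted documents against gold
#'
#' Scoring is strict: a trigger counts as correct on exact span and type; an
#' event counts as correct under recursive structural equality (same matched
#' trigger and the same multiset of (role, filler), with event-typed fillers
#' compared recursively). Precision, recall and F1 are micro-averaged over
#' documents and reported overall and per stratum. The stratum of an event is
#' `nested` when any argument filler (recursively reachable) is an event,
#' `simple` otherwise; with `nested_rule = "type"` an event is instead
#' assigned by whether its type is in the schema's nesting-capable set (the
#' coarse regulation/planned-process rule). A trigger inherits the stratum of
#' the events it anchors.
#'
#' @param gold_docs,pred_docs Lists of [annotated_document()]s, aligned by
#'   `doc_id`.
#' @param nested_rule `"structural"` (default) or `"type"`.
#' @param nested_types Types counting as nested under the `"type"` rule.
#' @return A `metrics_report`: list with `metrics` (tibble: `task`,
#'   `stratum`, `tp`, `fp`, `fn`, `precision`, `recall`, `f1` in percent) and
#'   `by_type` (per-event-type breakdown). Use [tidy()]/[glance()] to
#'   extract.
#' @export
evaluate_events <- function(gold_docs, pred_docs,
                            nested_rule = c("structural", "type"),
                            nested_types = character()) {
  nested_rule <- match.arg(nested_rule)
  gold_ids <- vapply(gold_docs, `[[`, "", "doc_id")
  pred_ids <- vapply(pred_docs, `[[`, "", "doc_id")
  if (!setequal(gold_ids, pred_ids) || length(gold_ids) != length(pred_ids)) {
    stop_bioevents("bioevents_alignment_error",
                   "gold and predicted document ids do not align")
  }
  pred_docs <- pred_docs[match(gold_ids, pred_ids)]
  acc <- new.env(parent = emptyenv())
  acc$rows <- list()
  add <- function(task, stratum, type, gold_sigs, pred_sigs) {
    tp <- multiset_tp(gold_sigs, pred_sigs)
    acc$rows[[length(acc$rows) + 1L]] <- tibble::tibble(
      task = task, stratum = stratum, type = type,
      tp = tp, fp = length(pred_sigs) - tp, fn = length(gold_sigs) - tp)
  }
  for (k in seq_along(gold_docs)) {
    g <- gold_docs[[k]]; p <- pred_docs[[k]]
    stratum_of <- function(doc) {
      if (length(doc$events) == 0) return(character())
      if (nested_rule == "structural") {
        ifelse(event_is_nested(doc), "nested", "simple")
      } else {
        types <- vapply(doc$events, function(ev) {
          tr <- Filter(function(t) t$id == ev$trigger_id, doc$triggers)[[1]]
          tr$type
        }, "")
        ifelse(types %in% nested_types, "nested", "simple")
      }
    }
    g_str <- stratum_of(g); p_str <- stratum_of(p)
    g_sig <- if (length(g$events)) event_signatures(g) else character()
    p_sig <- if (length(p$events)) event_signatures(p) else character()
    g_type <- vapply(g$events, function(ev) {
      Filter(function(t) t$id == ev$trigger_id, g$triggers)[[1]]$type
    }, "")
    p_type <- vapply(p$events, function(ev) {
      Filter(function(t) t$id == ev$trigger_id, p$triggers)[[1]]$type
    }, "")
    add("event", "all", "all", g_sig, p_sig)
    for (s in c("simple", "nested")) {
      add("event", s, "all", g_sig[g_str == s], p_sig[p_str == s])
    }
    for (ty in unique(c(g_type, p_type))) {
      add("event", "all", ty, g_sig[g_type == ty], p_sig[p_type == ty])
    }
    # triggers: exact span + type; stratum inherited from anchored events
    g_trig <- vapply(g$triggers, trigger_signature, "")
    p_trig <- vapply(p$triggers, trigger_signature, "")
    trig_stratum <- function(doc, strat) {
      anchors <- vapply(doc$events, `[[`, "", "trigger_id")
      vapply(doc$triggers, function(tr) {
        hit <- strat[anchors == tr$id]
        if (any(hit == "nested")) "nested" else "simple"
      }, "")
    }
    gt_str <- trig_stratum(g, g_str); pt_str <- trig_stratum(p, p_str)
    add("trigger", "all", "all", g_trig, p_trig)
    for (s in c("simple", "nested")) {
      add("trigger", s, "all", g_trig[gt_str == s], p_trig[pt_str == s])
    }
  }
  rows <- dplyr::bind_rows(acc$rows)
  metrics <- rows |>
    dplyr::filter(.data$type == "all") |>
    dplyr::group_by(.data$task, .data$stratum) |>
    dplyr::summarise(tp = sum(.data$tp), fp = sum(.data$fp), fn = sum(.data$fn),
                     .groups = "drop")
  metrics <- add_prf(metrics)
  by_type <- rows |>
    dplyr::filter(.data$task == "event", .data$type != "all") |>
    dplyr::group_by(.data$type) |>
    dplyr::summarise(tp = sum(.data$tp), fp = sum(.data$fp), fn = sum(.data$fn),
                     .groups = "drop") |>
    add_prf()
  structure(list(metrics = metrics, by_type = by_type), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Event extraction metrics (%, micro-averaged):\n")
  print(as.data.frame(x$metrics), row.names = FALSE)
  invisible(x)
}

metric_value <- function(report, task_, stratum_ = "all", what = "f1") {
  row <- report$metrics[report$metrics$task == task_ &
                          report$metrics$stratum == stratum_, ]
  row[[what]][1]
}

#' @export
tidy.metrics_report <- function(x, ...) x$metrics

#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(
    trigger_precision = metric_value(x, "trigger", what = "precision"),
    trigger_recall = metric_value(x, "trigger", what = "recall"),
    trigger_f1 = metric_value(x, "trigger", what = "f1"),
    event_precision = metric_value(x, "event", what = "precision"),
    event_recall = metric_value(x, "event", what = "recall"),
    event_f1 = metric_value(x, "event", what = "f1")
  )
}
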