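#' Convert typed character spans to BIO token tags
#'
#' Projects character-offset spans onto a token sequence using the BIO scheme:
#' the first token of a span is tagged `B-<type>`, subsequent tokens
#' `I-<type>`, and all remaining tokens `O`. Both triggers and entities are
#' encoded this way; a multi-token trigger such as "blood vessel development"
#' becomes `B-BVD I-BVD I-BVD`.
#'
#' @param tokens A data frame with columns `start`, `end` (0-based,
#'   end-exclusive character offsets), non-overlapping and sorted.
#' @param spans A data frame with columns `start`, `end`, `type`, or a list of
#'   [entity_span()]/[trigger_span()] objects.
#' @return Character vector of tags, aligned 1:1 with `tokens`.
#'   Throws `bioevents_misaligned` if a span boundary splits a token, the span
#'   does not cover a contiguous token run, or two spans claim the same token.
#' @export
spans_to_bio <- function(tokens, spans) {
  spans <- as_span_df(spans)
  n <- nrow(tokens)
  tags <- rep("O", n)
  claimed <- rep(FALSE, n)
  if (nrow(spans) == 0) return(tags)
  for (k in seq_len(nrow(spans))) {
    s <- spans$start[k]; e <- spans$end[k]; ty <- spans$type[k]
    first <- which(tokens$start == s)
    last <- which(tokens$end == e)
    if (length(first) != 1 || length(last) != 1 || last < first) {
      stop_bioevents("bioevents_misaligned",
                     sprintf("span [%d,%d) '%s' does not align to token boundaries",
                             s, e, ty))
    }
    run <- first:last
    if (any(claimed[run])) {
      stop_bioevents("bioevents_misaligned",
                     sprintf("span [%d,%d) overlaps a previously tagged token", s, e))
    }
    claimed[run] <- TRUE
    tags[first] <- paste0("B-", ty)
    if (last > first) tags[(first + 1L):last] <- paste0("I-", ty)
  }
  tags
}

as_span_df <- function(spans) {
  if (is.data.frame(spans)) return(spans)
  if (length(spans) == 0) {
    return(tibble::tibble(start = integer(), end = integer(), type = character()))
  }
  tibble::tibble(
    start = vapply(spans, `[[`, 0L, "start"),
    end = vapply(spans, `[[`, 0L, "end"),
    type = vapply(spans, `[[`, "", "type")
  )
}

#' Decode BIO token tags back to typed spans
#'
#' Inverse of [spans_to_bio()]. Decoding is lenient towards malformed
#' predictions: an orphan `I-t` (no preceding `B-t`/`I-t` of the same type)
#' opens a new span rather than being dropped, and a type change inside an
#' `I-` run closes the previous span.
#'
#' @param tags Character vector of BIO tags.
#' @param tokens Token data frame with `start`, `end` columns, aligned with
#'   `tags`.
#' @return A tibble with one row per decoded span: `type`, `start`, `end`
#'   (character offsets) and `token_start`, `token_end` (1-based token
#'   indices).
#' @export
bio_to_spans <- function(tags, tokens) {
  stopifnot(length(tags) == nrow(tokens))
  out <- list()
  open_type <- NULL
  open_from <- NA_integer_
  close_open <- function(upto) {
    if (!is.null(open_type)) {
      out[[length(out) + 1L]] <<- list(type = open_type, token_start = open_from,
                                       token_end = upto)
    }
    open_type <<- NULL
  }
  for (i in seq_along(tags)) {
    tag <- tags[i]
    if (tag == "O") {
      close_open(i - 1L)
    } else if (startsWith(tag, "B-")) {
      close_open(i - 1L)
      open_type <- substring(tag, 3L)
      open_from <- i
    } else {  # I-t
      ty <- substring(tag, 3L)
      if (is.null(open_type) || !identical(open_type, ty)) {
        close_open(i - 1L)  # orphan I-t: open a new span
        open_type <- ty
        open_from <- i
      }
    }
  }
  close_open(length(tags))
  if (length(out) == 0) {
    return(tibble::tibble(type = character(), start = integer(), end = integer(),
                          token_start = integer(), token_end = integer()))
  }
  tibble::tibble(
    type = vapply(out, `[[`, "", "type"),
    start = tokens$start[vapply(out, `[[`, 0L, "token_start")],
    end = tokens$end[vapply(out, `[[`, 0L, "token_end")],
    token_start = vapply(out, `[[`, 0L, "token_start"),
    token_end = vapply(out, `[[`, 0L, "token_end")
  )
}

#' Validate a BIO tag sequence
#'
#' A strictly well-formed BIO sequence never has an `I-t` that is not
#' preceded by `B-t` or `I-t` of the same type.
#'
#' @param tags Character vector of BIO tags.
#' @return `TRUE` if well-formed, `FALSE` otherwise.
#' @export
is_valid_bio <- function(tags) {
  prev <- "O"
  for (tag in tags) {
    if (startsWith(tag, "I-")) {
      ty <- substring(tag, 3L)
      ok <- (startsWith(prev, "B-") || startsWith(prev, "I-")) &&
        identical(substring(prev, 3L), ty)
      if (!ok) return(FALSE)
    }
    prev <- tag
  }
  TRUE
}
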