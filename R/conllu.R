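#' Read sentences from a CoNLL-U file
#'
#' Parses the 10-column CoNLL-U format into per-sentence token tables, POS
#' sequences and dependency arcs. Multiword-token ranges (`1-2`) and empty
#' nodes (`1.1`) are ignored; the root arc (head `0`) is dropped from the arc
#' list, so a single-token sentence has zero arcs. Character offsets for each
#' token are taken from a `TokenRange=start:end` entry in the MISC column when
#' present (document-level, 0-based, end-exclusive); otherwise tokens are
#' aligned against the `# text =` comment by sequential search.
#'
#' @param path Path to a CoNLL-U file, or a character vector of lines via
#'   `lines`.
#' @param lines Optional character vector of lines (overrides `path`).
#' @return A list of sentences, each a list with elements `sent_id`, `tokens`
#'   (tibble `surface`, `start`, `end`), `pos` (UPOS tags) and `arcs` (tibble
#'   `head`, `dep`, 1-based token indices, root arc removed).
#'   Throws `bioevents_parse_error` with the offending line number.
#' @export
read_conllu <- function(path = NULL, lines = NULL) {
  if (is.null(lines)) lines <- readLines(path, warn = FALSE)
  sentences <- list()
  cur <- list()
  meta <- list()
  flush <- function() {
    if (length(cur) > 0) {
      sentences[[length(sentences) + 1L]] <<- finish_conllu_sentence(cur, meta)
    }
    cur <<- list()
    meta <<- list()
  }
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(line)) { flush(); next }
    if (startsWith(line, "#")) {
      kv <- regmatches(line, regexec("^#\\s*([^=]+?)\\s*=\\s*(.*)$", line))[[1]]
      if (length(kv) == 3) meta[[kv[2]]] <- kv[3]
      next
    }
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) != 10) {
      stop_bioevents("bioevents_parse_error",
                     sprintf("line %d: expected 10 tab-separated fields, got %d",
                             i, length(f)), line = i)
    }
    if (grepl("-", f[1], fixed = TRUE) || grepl(".", f[1], fixed = TRUE)) next
    idx <- suppressWarnings(as.integer(f[1]))
    hd <- suppressWarnings(as.integer(f[7]))
    if (is.na(idx) || is.na(hd)) {
      stop_bioevents("bioevents_parse_error",
                     sprintf("line %d: non-integer ID or HEAD", i), line = i)
    }
    cur[[length(cur) + 1L]] <- list(idx = idx, form = f[2], upos = f[4],
                                    head = hd, deprel = f[8], misc = f[10],
                                    line = i)
  }
  flush()
  sentences
}

finish_conllu_sentence <- function(rows, meta) {
  n <- length(rows)
  surface <- vapply(rows, `[[`, "", "form")
  starts <- rep(NA_integer_, n)
  ends <- rep(NA_integer_, n)
  for (k in seq_len(n)) {
    m <- regmatches(rows[[k]]$misc,
                    regexec("TokenRange=([0-9]+):([0-9]+)", rows[[k]]$misc))[[1]]
    if (length(m) == 3) {
      starts[k] <- as.integer(m[2])
      ends[k] <- as.integer(m[3])
    }
  }
  if (anyNA(starts) && !is.null(meta$text)) {
    cursor <- 0L
    for (k in seq_len(n)) {
      if (!is.na(starts[k])) { cursor <- ends[k]; next }
      rel <- regexpr(surface[k], substring(meta$text, cursor + 1L), fixed = TRUE)
      if (rel > 0) {
        starts[k] <- cursor + rel - 1L
        ends[k] <- starts[k] + nchar(surface[k])
        cursor <- ends[k]
      }
    }
  }
  heads <- vapply(rows, `[[`, 0L, "head")
  keep <- heads != 0L
  if (any(heads[keep] < 1L | heads[keep] > n)) {
    bad <- rows[[which(keep & (heads < 1L | heads > n))[1]]]
    stop_bioevents("bioevents_parse_error",
                   sprintf("line %d: HEAD out of range", bad$line), line = bad$line)
  }
  list(
    sent_id = meta$sent_id %||% NA_character_,
    text = meta$text %||% NA_character_,
    tokens = tibble::tibble(surface = surface, start = starts, end = ends),
    pos = vapply(rows, `[[`, "", "upos"),
    arcs = tibble::tibble(head = heads[keep], dep = seq_len(n)[keep])
  )
}

# Serialise sentences back to CoNLL-U (used by the synthetic generator).
format_conllu <- function(sentences) {
  out <- character()
  for (s in sentences) {
    out <- c(out, paste0("# sent_id = ", s$sent_id), paste0("# text = ", s$text))
    n <- nrow(s$tokens)
    heads <- rep(0L, n)
    if (nrow(s$arcs) > 0) heads[s$arcs$dep] <- s$arcs$head
    for (i in seq_len(n)) {
      out <- c(out, paste(
        i, s$tokens$surface[i], "_", s$pos[i], "_", "_", heads[i],
        if (heads[i] == 0L) "root" else "dep", "_",
        sprintf("TokenRange=%d:%d", s$tokens$start[i], s$tokens$end[i]),
        sep = "\t"))
    }
    out <- c(out, "")
  }
  out
}
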