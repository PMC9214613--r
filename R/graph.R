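#' Build the simplified syntactic multigraph for a sentence
#'
#' Dependency parsers emit on the order of fifty distinct relation labels; for
#' graph convolution these are collapsed into three direction classes. For
#' every original arc head -> dependent the graph holds one `along` edge
#' (head, dependent) and one `rev` edge (dependent, head), and every token
#' additionally carries a `loop` self-edge, so that a sentence with `n` tokens
#' and `a` arcs yields exactly `2a + n` edges. The original relation labels
#' are discarded: the convolution is parameterised only by the direction
#' class.
#'
#' @param tokens Token tibble (`surface`, `start`, `end`).
#' @param pos Character vector of POS tags, aligned with tokens.
#' @param arcs Tibble with `head`, `dep` columns (1-based token indices,
#'   no root arc, no self-arcs).
#' @param entity_spans,trigger_spans Spans (data frame or span-object list)
#'   used to produce the aligned entity and gold-trigger BIO sequences; either
#'   may be empty.
#' @return An object of class `sentence_graph`: list with `tokens`, `pos`,
#'   `entity_bio`, `trigger_bio`, and `edges` (tibble `u`, `v`, `rel` with
#'   `rel` in `along`/`rev`/`loop`, canonically sorted).
#' @export
build_sentence_graph <- function(tokens, pos, arcs,
                                 entity_spans = NULL, trigger_spans = NULL) {
  n <- nrow(tokens)
  stopifnot(length(pos) == n)
  if (nrow(arcs) > 0) {
    if (any(arcs$head < 1 | arcs$head > n | arcs$dep < 1 | arcs$dep > n)) {
      stop_bioevents("bioevents_index_error", "dependency arc out of token range")
    }
    if (any(arcs$head == arcs$dep)) {
      stop_bioevents("bioevents_index_error", "self-arc in dependency input")
    }
  }
  edges <- rbind(
    data.frame(u = arcs$head, v = arcs$dep, rel = rep("along", nrow(arcs))),
    data.frame(u = arcs$dep, v = arcs$head, rel = rep("rev", nrow(arcs))),
    data.frame(u = seq_len(n), v = seq_len(n), rel = rep("loop", n))
  )
  edges <- edges[order(match(edges$rel, c("along", "rev", "loop")),
                       edges$u, edges$v), , drop = FALSE]
  rownames(edges) <- NULL
  structure(
    list(
      tokens = tokens,
      pos = pos,
      entity_bio = spans_to_bio(tokens, entity_spans %||% list()),
      trigger_bio = spans_to_bio(tokens, trigger_spans %||% list()),
      edges = tibble::as_tibble(edges)
    ),
    class = "sentence_graph"
  )
}

#' @export
print.sentence_graph <- function(x, ...) {
  cat(sprintf("<sentence_graph: %d tokens, %d edges>\n",
              nrow(x$tokens), nrow(x$edges)))
  invisible(x)
}

#' Number of tokens in a sentence graph
#' @param graph A `sentence_graph`.
#' @return Integer token count.
#' @export
graph_size <- function(graph) nrow(graph$tokens)

# Dense n x n adjacency for one relation class: adj[u, v] = 1 when there is
# an edge u -> v tagged rel. Messages flow u -> v, so propagation multiplies
# by t(adj).
relation_adjacency <- function(graph, rel) {
  n <- graph_size(graph)
  adj <- matrix(0, n, n)
  e <- graph$edges[graph$edges$rel == rel, , drop = FALSE]
  if (nrow(e) > 0) adj[cbind(e$u, e$v)] <- 1
  adj
}
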