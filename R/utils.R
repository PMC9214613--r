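# Internal helpers shared across modules.

# Character offsets follow the standoff convention: 0-based, end-exclusive,
# counted over Unicode code points. Token and node indices are 1-based, as is
# idiomatic in R.

slice_text <- function(text, start, end) {
  # 0-based [start, end) code-point slice
  substr(text, start + 1L, end)
}

stop_bioevents <- function(class, message, ...) {
  rlang::abort(message, class = c(class, "bioevents_error"), ...)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Uniform initialisation at 1/sqrt(fan_in) scale, drawn from the current RNG.
init_mat <- function(nrow, ncol, fan_in = nrow) {
  r <- 1 / sqrt(max(fan_in, 1))
  matrix(runif(nrow * ncol, -r, r), nrow, ncol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic per-token embedding: a seeded draw keyed by the token surface.
# Used when no pretrained contextual embedder is supplied; unit-variance and
# reproducible across sessions, so two tokens with the same surface always
# share a vector.
hash_embedding <- function(surface, dim, seed) {
  h <- 5381
  for (cp in utf8ToInt(surface)) h <- (h * 33 + cp) %% 2147483647
  h <- (h + 777 * seed) %% 2147483647
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(h))
  rnorm(dim)
}

with_preserved_rng <- function(code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}
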