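# Dense brute-force oracle: a triple loop over every edge (u, v, r),
# independent of the adjacency-matrix implementation.
gcn_layer_bruteforce <- function(H, graph, lp, relu = TRUE) {
  out <- matrix(0, nrow(H), ncol(H))
  for (k in seq_len(nrow(graph$edges))) {
    u <- graph$edges$u[k]; v <- graph$edges$v[k]; r <- graph$edges$rel[k]
    p <- lp[[r]]
    gate <- 1 / (1 + exp(-(sum(H[u, ] * p$V) + p$d[1])))
    out[v, ] <- out[v, ] + gate * (H[u, ] %*% p$W + p$b)
  }
  if (relu) pmax(out, 0) else out
}

mha_bruteforce <- function(S, params) {
  heads <- lapply(params$heads, function(h) {
    Q <- S %*% h$Wq; K <- S %*% h$Wk; V <- S %*% h$Wv
    sc <- Q %*% t(K) / sqrt(ncol(Q))
    A <- t(apply(sc, 1, function(r) { e <- exp(r - max(r)); e / sum(e) }))
    if (nrow(S) == 1) A <- matrix(A, 1, 1)
    A %*% V
  })
  do.call(cbind, heads) %*% params$Wo
}

random_gcn_params <- function(m) {
  setNames(lapply(1:3, function(i) {
    list(W = matrix(rnorm(m * m, sd = 0.5), m), b = matrix(rnorm(m), 1),
         V = matrix(rnorm(m), m, 1), d = matrix(rnorm(1), 1, 1))
  }), c("along", "rev", "loop"))
}

test_that("single node with zero parameters maps to zero", {
  g <- random_graph(1, seed = 1)
  lp <- setNames(lapply(1:3, function(i) {
    list(W = matrix(0, 4, 4), b = matrix(0, 1, 4),
         V = matrix(0, 4, 1), d = matrix(0, 1, 1))
  }), c("along", "rev", "loop"))
  expect_equal(gcn_layer(matrix(rnorm(4), 1), g, lp), matrix(0, 1, 4))
})

test_that("with gates forced open the layer equals an ungated relational GCN", {
  set.seed(4)
  m <- 6
  for (n in c(3, 7, 10)) {
    g <- random_graph(n)
    lp <- random_gcn_params(m)
    # d = 30 saturates the sigmoid gate to 1 within 1e-13
    for (r in names(lp)) { lp[[r]]$V <- lp[[r]]$V * 0; lp[[r]]$d <- matrix(30, 1, 1) }
    H <- matrix(rnorm(n * m), n)
    ungated <- matrix(0, n, m)
    for (k in seq_len(nrow(g$edges))) {
      u <- g$edges$u[k]; v <- g$edges$v[k]
      p <- lp[[g$edges$rel[k]]]
      ungated[v, ] <- ungated[v, ] + H[u, ] %*% p$W + p$b
    }
    expect_lt(max(abs(gcn_layer(H, g, lp) - pmax(ungated, 0))), 1e-6)
  }
})

test_that("adjacency implementation equals the brute-force triple loop", {
  set.seed(12)
  for (rep in 1:20) {
    n <- sample(2:10, 1)
    m <- sample(c(4, 6, 8), 1)
    g <- random_graph(n)
    lp <- random_gcn_params(m)
    H <- matrix(rnorm(n * m), n)
    expect_lt(max(abs(gcn_layer(H, g, lp) - gcn_layer_bruteforce(H, g, lp))), 1e-6)
  }
})

test_that("stacking: one layer equals a single call; self-loop-only sentences reduce to a closed form", {
  set.seed(5)
  m <- 4; n <- 3
  g <- build_sentence_graph(tiny_tokens(c("a", "b", "c")), rep("NOUN", 3),
                            tibble::tibble(head = integer(), dep = integer()))
  layers <- setNames(list(random_gcn_params(m), random_gcn_params(m)),
                     c("layer1", "layer2"))
  A <- matrix(rnorm(n * m), n)
  expect_equal(run_gcn(A, g, layers[1]), gcn_layer(A, g, layers[[1]]))
  # with only self-loops every layer is a per-token feed-forward map
  closed_form <- function(H, p) {
    gate <- as.vector(1 / (1 + exp(-(H %*% p$V + p$d[1]))))
    pmax(sweep(H %*% p$W, 2, as.vector(p$b), "+") * gate, 0)
  }
  expect_equal(run_gcn(A, g, layers),
               closed_form(closed_form(A, layers[[1]]$loop), layers[[2]]$loop),
               tolerance = 1e-12)
})

test_that("gates are strictly inside (0,1) for finite inputs", {
  set.seed(6)
  g <- random_graph(5)
  lp <- random_gcn_params(4)
  H <- matrix(rnorm(20), 5)
  for (r in names(lp)) {
    gate <- sigmoid(H %*% lp[[r]]$V + lp[[r]]$d[1])
    expect_true(all(gate > 0 & gate < 1))
  }
})

test_that("attention matches the naive oracle and rows are stochastic", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(2:8, 1)
    m <- 8
    S <- matrix(rnorm(n * m), n)
    ap <- bioevents:::init_attention_params(m, 2)
    expect_lt(max(abs(multi_head_attention(S, ap) - mha_bruteforce(S, ap))), 1e-6)
    avg <- export_attention(S, ap)
    expect_equal(rowSums(unclass(avg)), rep(1, n), tolerance = 1e-6)
    # the average really is the per-head mean
    per_head <- lapply(ap$heads, function(h) bioevents:::attention_head_scores(S, h))
    expect_equal(unclass(avg), (per_head[[1]] + per_head[[2]]) / 2,
                 ignore_attr = TRUE)
  }
})

test_that("head width is m/H and indivisible head counts are rejected", {
  ap <- bioevents:::init_attention_params(768, 2)
  expect_identical(ncol(ap$heads$head1$Wq), 384L)
  expect_error(bioevents:::init_attention_params(6, 4),
               class = "bioevents_dimension_error")
})

test_that("n = 1 attention weight is exactly 1 and uniform parameters give uniform rows", {
  S1 <- matrix(rnorm(8), 1)
  ap <- bioevents:::init_attention_params(8, 2)
  expect_equal(unclass(export_attention(S1, ap)), matrix(1, 1, 1), ignore_attr = TRUE)
  ap0 <- ap
  for (h in seq_along(ap0$heads)) {
    ap0$heads[[h]]$Wq <- ap0$heads[[h]]$Wq * 0
    ap0$heads[[h]]$Wk <- ap0$heads[[h]]$Wk * 0
  }
  S <- matrix(rnorm(32), 4)
  expect_equal(unclass(export_attention(S, ap0)), matrix(0.25, 4, 4),
               ignore_attr = TRUE)
})

test_that("token permutation equivariance of GCN + attention", {
  set.seed(33)
  n <- 6; m <- 6
  arcs <- random_arcs(n)
  toks <- tiny_tokens(replicate(n, paste(sample(letters, 3), collapse = "")))
  g <- build_sentence_graph(toks, rep("NOUN", n), arcs)
  perm <- sample(n)
  inv <- order(perm)
  arcs_p <- tibble::tibble(head = inv[arcs$head], dep = inv[arcs$dep])
  g_p <- build_sentence_graph(toks[perm, ], rep("NOUN", n), arcs_p)
  lp <- setNames(list(random_gcn_params(m)), "layer1")
  ap <- bioevents:::init_attention_params(m, 2)
  A <- matrix(rnorm(n * m), n)
  S <- run_gcn(A, g, lp)
  S_p <- run_gcn(A[perm, ], g_p, lp)
  expect_equal(S_p, S[perm, ], tolerance = 1e-10)
  expect_equal(multi_head_attention(S_p, ap), multi_head_attention(S, ap)[perm, ],
               tolerance = 1e-10)
})
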