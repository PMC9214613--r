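test_that("tagger output shape and determinism; shape mismatch rejected", {
  model <- toy_model()
  n <- 4
  L <- matrix(rnorm(n * 2 * model$config$bilstm_hidden), n)
  M <- matrix(rnorm(n * model$config$embedding$contextual_dim), n)
  O1 <- tagger(L, M, model$params$tagger)
  O2 <- tagger(L, M, model$params$tagger)
  expect_identical(O1, O2)
  expect_identical(dim(O1), c(as.integer(n), as.integer(model$config$tagger_hidden)))
  zero <- lapply(model$params$tagger, function(m) m * 0)
  expect_equal(tagger(L, M, zero), matrix(0, n, model$config$tagger_hidden))
  expect_error(tagger(L[1:3, ], M, model$params$tagger),
               class = "bioevents_shape_mismatch")
})

test_that("a 19-type schema yields a 39-label BIO trigger vocabulary", {
  schema <- corpus_schema(trigger_types = paste0("T", 1:19),
                          entity_types = "Protein",
                          pos_vocab = c("NOUN", "VERB"))
  expect_length(schema$trigger_bio_labels, 39L)
  O <- matrix(rnorm(3 * 8), 3)
  params <- list(W = matrix(0, 8, 39), b = matrix(0, 1, 39))
  soft <- trigger_scores(O, params)
  expect_identical(ncol(soft), 39L)
  expect_equal(soft, matrix(1 / 39, 3, 39))  # zero logits -> uniform
  expect_equal(rowSums(soft), rep(1, 3))
})

test_that("argmax decoding of forced one-hot logits reproduces the forcing labels", {
  schema <- toy_corpus_schema()
  v <- length(schema$trigger_bio_labels)
  forced <- c(3L, 1L, 5L)
  O <- diag(3)
  W <- matrix(0, 3, v)
  for (i in 1:3) W[i, forced[i]] <- 50
  soft <- trigger_scores(O, list(W = W, b = matrix(0, 1, v)))
  expect_identical(apply(soft, 1, which.max), forced)
})

test_that("candidate enumeration counts follow k_t*k_e + k_t*(k_t-1)", {
  trig1 <- tibble::tibble(type = "A", token_start = 2L, token_end = 2L)
  ent1 <- tibble::tibble(id = "T1", type = "P", token_start = 4L, token_end = 4L)
  expect_identical(nrow(enumerate_candidates(trig1, ent1)), 1L)
  expect_identical(nrow(enumerate_candidates(trig1[0, ], ent1)), 0L)
  trig2 <- tibble::tibble(type = c("A", "B"), token_start = c(2L, 6L),
                          token_end = c(2L, 6L))
  ent2 <- tibble::tibble(id = c("T1", "T2"), type = "P",
                         token_start = c(4L, 8L), token_end = c(4L, 8L))
  pairs <- enumerate_candidates(trig2, ent2)
  expect_identical(nrow(pairs), 6L)  # 2*2 + 2*1
  # deterministic order: by trigger start, then candidate start
  expect_identical(pairs$trigger, c(1L, 1L, 1L, 2L, 2L, 2L))
  expect_true(all(pairs$trigger != pairs$candidate |
                    pairs$candidate_kind != "trigger"))
})

test_that("single-token span pooling is the identity over that row", {
  set.seed(2)
  O <- matrix(rnorm(5 * 4), 5)
  soft <- softmax_rows(matrix(rnorm(5 * 3), 5))
  trig <- tibble::tibble(type = "A", token_start = 2L, token_end = 2L)
  ent <- tibble::tibble(id = "T1", type = "P", token_start = 4L, token_end = 4L)
  pairs <- enumerate_candidates(trig, ent)
  nr <- 3
  d <- 2 * (4 + 3)
  W <- diag(d)[, 1:nr]  # picks the first nr pooled features as logits
  probs <- role_classify(pairs, trig, ent, O, soft, list(W = W, b = matrix(0, 1, nr)))
  manual <- exp(c(O[2, 1:3]))
  expect_equal(as.vector(probs), manual / sum(manual), tolerance = 1e-12)
})

test_that("zero role-classifier weights give a uniform distribution over roles", {
  O <- matrix(rnorm(4 * 4), 4)
  soft <- matrix(1 / 3, 4, 3)
  trig <- tibble::tibble(type = "A", token_start = 1L, token_end = 2L)
  ent <- tibble::tibble(id = "T1", type = "P", token_start = 3L, token_end = 4L)
  pairs <- enumerate_candidates(trig, ent)
  d <- 2 * (4 + 3)
  probs <- role_classify(pairs, trig, ent, O, soft,
                         list(W = matrix(0, d, 3), b = matrix(0, 1, 3)))
  expect_equal(as.vector(probs), rep(1 / 3, 3))
})

test_that("the fused trigger distribution carries information into role logits", {
  # hand-set weights that read only the soft block: flipping the trigger
  # distribution must flip the role decision while O stays fixed
  O <- matrix(0, 2, 4)
  trig <- tibble::tibble(type = "Reg", token_start = 1L, token_end = 1L)
  ent <- tibble::tibble(id = "T1", type = "P", token_start = 2L, token_end = 2L)
  pairs <- enumerate_candidates(trig, ent)
  nv <- 3  # toy trigger BIO vocab of 3 for this construction
  d <- 2 * (4 + nv)
  W <- matrix(0, d, 3)
  # soft block of the trigger span lives at columns 5..7 of the pooled vector;
  # route label 2 ("B-Reg") mass to role 2 (Cause)
  W[4 + 2, 2] <- 10
  W[4 + 3, 1] <- 10
  params <- list(W = W, b = matrix(0, 1, 3))
  soft_breg <- matrix(c(0.05, 0.9, 0.05, 1, 0, 0), 2, byrow = TRUE)
  soft_other <- matrix(c(0.05, 0.05, 0.9, 1, 0, 0), 2, byrow = TRUE)
  p1 <- role_classify(pairs, trig, ent, O, soft_breg, params)
  p2 <- role_classify(pairs, trig, ent, O, soft_other, params)
  expect_identical(which.max(p1[1, ]), 2L)
  expect_identical(which.max(p2[1, ]), 1L)
  # and with fusion disabled the distribution cannot move the logits
  p3 <- role_classify(pairs, trig, ent, O, soft_breg,
                      list(W = matrix(0, 2 * 4, 3), b = matrix(0, 1, 3)),
                      fusion = FALSE)
  p4 <- role_classify(pairs, trig, ent, O, soft_other,
                      list(W = matrix(0, 2 * 4, 3), b = matrix(0, 1, 3)),
                      fusion = FALSE)
  expect_equal(p3, p4)
})

test_that("assembled events reproduce a nested regulation-of-expression structure", {
  # two triggers (Pos_Reg 'activator', Exp 'expression'), two entities;
  # roles: (activator, TNF-alpha) = Cause, (activator, expression-event) = Theme,
  # (expression, IL-8) = Theme; everything else None
  trig <- tibble::tibble(type = c("Pos_Reg", "Expression"),
                         token_start = c(2L, 5L), token_end = c(2L, 5L),
                         id = c("T3", "T4"))
  ent <- tibble::tibble(id = c("T1", "T2"), type = "Protein",
                        token_start = c(1L, 4L), token_end = c(1L, 4L))
  pairs <- enumerate_candidates(trig, ent)
  role_probs <- matrix(0, nrow(pairs), 3)
  for (k in seq_len(nrow(pairs))) {
    key <- paste(pairs$trigger[k], pairs$candidate_kind[k], pairs$candidate[k])
    role_probs[k, ] <- switch(
      key,
      "1 entity 1" = c(0.05, 0.9, 0.05),   # Cause
      "1 trigger 2" = c(0.9, 0.05, 0.05),  # Theme (nested)
      "2 entity 2" = c(0.9, 0.05, 0.05),   # Theme
      c(0.05, 0.05, 0.9)                   # None
    )
  }
  evs <- assemble_events(pairs, role_probs, trig, ent,
                         event_ids = c("E1", "E2"))
  expect_length(evs, 2)
  e1 <- evs[[1]]
  fillers <- vapply(e1$args, `[[`, "", "filler_id")
  roles <- vapply(e1$args, `[[`, "", "role")
  expect_setequal(fillers, c("T1", "E2"))
  expect_identical(roles[fillers == "T1"], "Cause")
  expect_identical(roles[fillers == "E2"], "Theme")
  expect_identical(vapply(evs[[2]]$args, `[[`, "", "filler_id"), "T2")
})

test_that("all-None decisions still yield argument-less events per trigger", {
  trig <- tibble::tibble(type = c("A", "B"), token_start = c(1L, 3L),
                         token_end = c(1L, 3L), id = c("T1", "T2"))
  ent <- tibble::tibble(id = "T9", type = "P", token_start = 2L, token_end = 2L)
  pairs <- enumerate_candidates(trig, ent)
  probs <- matrix(rep(c(0.1, 0.1, 0.8), each = 1), nrow(pairs), 3, byrow = TRUE)
  evs <- assemble_events(pairs, probs, trig, ent)
  expect_length(evs, 2)
  expect_true(all(vapply(evs, function(e) length(e$args) == 0L, logical(1))))
})

test_that("mutual event links keep only the higher-probability direction", {
  trig <- tibble::tibble(type = c("R1", "R2"), token_start = c(1L, 2L),
                         token_end = c(1L, 2L), id = c("T1", "T2"))
  ent <- tibble::tibble(id = character(), type = character(),
                        token_start = integer(), token_end = integer())
  pairs <- enumerate_candidates(trig, ent)
  # both directions predicted Theme: probs 0.9 (1->2) and 0.6 (2->1)
  probs <- matrix(0, 2, 3)
  for (k in 1:2) {
    p <- if (pairs$trigger[k] == 1L) 0.9 else 0.6
    probs[k, ] <- c(p, (1 - p) / 2, (1 - p) / 2)
  }
  evs <- assemble_events(pairs, probs, trig, ent)
  a1 <- vapply(evs[[1]]$args, `[[`, "", "filler_id")
  a2 <- vapply(evs[[2]]$args, `[[`, "", "filler_id")
  expect_identical(a1, "E2")
  expect_length(a2, 0)
})
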