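test_that("generation is byte-deterministic under a fixed seed", {
  cfg <- generator_config(n_docs = 3, sentences_per_doc = 4, nesting_prob = 0.4, seed = 5)
  c1 <- generate_corpus(cfg)
  c2 <- generate_corpus(cfg)
  expect_identical(lapply(c1$docs, `[[`, "a2"), lapply(c2$docs, `[[`, "a2"))
  expect_identical(lapply(c1$docs, `[[`, "conllu"), lapply(c2$docs, `[[`, "conllu"))
  expect_identical(c1$log, c2$log)
})

test_that("nesting_prob = 0 yields entity-only argument fillers", {
  corp <- generate_corpus(generator_config(n_docs = 5, sentences_per_doc = 5,
                                           nesting_prob = 0, seed = 3))
  for (d in corp$docs) {
    for (ev in d$document$events) {
      for (a in ev$args) expect_true(startsWith(a$filler_id, "T"))
    }
  }
  expect_identical(sum(corp$log$nested_events), 0L)
})

test_that("generated corpora pass standoff validation and graph invariants", {
  corp <- small_corpus(n_docs = 5, sentences = 4, nesting = 0.6, seed = 13)
  for (d in corp$docs) {
    expect_silent(validate_document(d$document))
    sents <- read_conllu(lines = d$conllu)
    for (s in sents) {
      g <- build_sentence_graph(s$tokens, s$pos, s$arcs)
      expect_identical(nrow(g$edges), 2L * nrow(s$arcs) + nrow(s$tokens))
    }
  }
})

test_that("written files round trip through the directory readers", {
  corp <- small_corpus(n_docs = 2, sentences = 2, seed = 21)
  dir <- withr::local_tempdir()
  write_corpus(corp, dir)
  back <- read_corpus_dir(dir)
  expect_length(back, 2)
  for (k in seq_along(back)) {
    expect_identical(back[[k]]$document$text, corp$docs[[k]]$document$text)
    expect_identical(length(back[[k]]$document$events),
                     length(corp$docs[[k]]$document$events))
    expect_identical(length(back[[k]]$parses), length(corp$docs[[k]]$parses))
  }
})

test_that("fraction of nested root events converges to nesting_prob", {
  p <- 0.3
  corp <- generate_corpus(generator_config(n_docs = 40, sentences_per_doc = 25,
                                           nesting_prob = p, seed = 17))
  n <- sum(corp$log$root_events)
  expect_identical(n, 1000L)
  frac <- sum(corp$log$nested_root_events) / n
  # 4 binomial standard errors
  expect_lt(abs(frac - p), 4 * sqrt(p * (1 - p) / n))
})

test_that("gold roles follow the configured role rule deterministically", {
  corp <- small_corpus(n_docs = 4, sentences = 4, nesting = 0.7, seed = 9)
  rule <- corp$config$role_rule
  schema <- toy_corpus_schema()
  for (d in corp$docs) {
    sents <- prepare_sentences(d$document, d$parses, schema)
    for (s in sents) {
      for (k in seq_len(nrow(s$pairs))) {
        trig_type <- s$triggers$type[s$pairs$trigger[k]]
        cand_kind <- if (s$pairs$candidate_kind[k] == "entity") {
          s$entities$type[s$pairs$candidate[k]]
        } else {
          "event"
        }
        hit <- rule$role[rule$trigger_type == trig_type & rule$candidate == cand_kind]
        expected <- if (length(hit) == 0) "None" else hit[[1]]
        expect_identical(schema$role_labels[s$role_gold[k]], expected)
      }
    }
  }
})

test_that("filler sentences dilute trigger tokens and carry no events", {
  corp <- generate_corpus(generator_config(n_docs = 4, sentences_per_doc = 5,
                                           nesting_prob = 0, no_event_prob = 1,
                                           seed = 51))
  expect_identical(sum(corp$log$events), 0L)
  expect_true(sum(corp$log$entities) > 0)
  expect_identical(sum(corp$log$root_events), 0L)
  # partial filler probability raises the O fraction towards ~95%
  imb <- generate_corpus(generator_config(n_docs = 10, sentences_per_doc = 10,
                                          nesting_prob = 0, no_event_prob = 0.7,
                                          seed = 52))
  schema <- toy_corpus_schema()
  tags <- unlist(lapply(imb$docs, function(d) {
    unlist(lapply(prepare_sentences(d$document, d$parses, schema),
                  function(s) s$graph$trigger_bio))
  }))
  expect_gt(mean(tags == "O"), 0.9)
})

test_that("ambiguous trigger surfaces occur under both types, resolved by template", {
  corp <- generate_corpus(generator_config(n_docs = 40, sentences_per_doc = 5,
                                           nesting_prob = 0.5,
                                           ambiguous_triggers = TRUE, seed = 53))
  surf_type <- dplyr::bind_rows(lapply(corp$docs, function(d) {
    tibble::tibble(surface = vapply(d$document$triggers, `[[`, "", "surface"),
                   type = vapply(d$document$triggers, `[[`, "", "type"))
  }))
  amb <- surf_type[surf_type$surface %in% c("induction", "stimulation"), ]
  expect_gt(nrow(amb), 0)
  expect_setequal(unique(amb$type), c("Growth", "Pos_Reg"))
  # the default lexicon never emits these surfaces
  base <- generate_corpus(generator_config(n_docs = 10, sentences_per_doc = 5, seed = 53))
  base_surf <- unlist(lapply(base$docs, function(d) {
    vapply(d$document$triggers, `[[`, "", "surface")
  }))
  expect_false(any(c("induction", "stimulation") %in% base_surf))
})
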