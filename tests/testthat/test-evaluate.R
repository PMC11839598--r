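test_that("self-BLEU matches hand cases and the brute-force oracle", {
  expect_equal(self_bleu("the lesion is stable", "the lesion is stable"), 1)
  expect_equal(self_bleu("alpha beta gamma", "delta epsilon zeta"), 0)
  # smoothing floors zero precisions instead of zeroing the score
  expect_gt(self_bleu("alpha beta", c("alpha delta"), smooth = TRUE), 0)

  pairs <- list(
    c("stable 6 mm nodule in the right lower lobe of the lung today",
      "the 6 mm nodule in the right lower lobe remains stable today"),
    c("no new suspicious findings are seen on the current examination",
      "current examination shows no new suspicious findings"),
    c("a b c d e f g h i j k l", "a b c d x f g h i j k l"),
    c("one two three four five six seven", "one two three four"),
    c("alpha beta alpha beta alpha", "alpha beta"))
  refs_pool <- c("interval growth of the left adrenal nodule is seen",
                 "there is interval growth of the adrenal nodule")
  k <- 0
  for (p in pairs) {
    for (n_max in c(2L, 5L)) {
      k <- k + 1
      expect_equal(self_bleu(p[1], p[2], n_max = n_max),
                   oracle_bleu(p[1], p[2], n_max = n_max), tolerance = 1e-12)
      expect_equal(self_bleu(p[1], c(p[2], refs_pool), n_max = n_max),
                   oracle_bleu(p[1], c(p[2], refs_pool), n_max = n_max),
                   tolerance = 1e-12)
    }
  }
  expect_gte(k, 10)
  expect_error(self_bleu("x", character(0)), "reference")
  expect_error(self_bleu("", "y"), "non-empty")
})

test_that("self-BLEU never decreases as the reference pool grows", {
  cand <- "mild degenerative changes are seen throughout the spine"
  refs <- c("severe degenerative changes are noted in the spine",
            "mild changes are seen throughout the lumbar spine",
            "mild degenerative changes are seen throughout the spine area",
            "no degenerative changes")
  prev <- 0
  for (i in seq_along(refs)) {
    cur <- self_bleu(cand, refs[1:i])
    expect_gte(cur, prev - 1e-12)
    expect_equal(cur, oracle_bleu(cand, refs[1:i]), tolerance = 1e-12)
    prev <- cur
  }
})

test_that("semantic similarity has the expected fixed points", {
  expect_equal(as.numeric(semantic_similarity("liver lesion", "liver lesion")),
               1, tolerance = 1e-12)
  expect_equal(as.numeric(semantic_similarity("alpha beta", "gamma delta")),
               0, tolerance = 1e-12)
  # hand-computed sparse vectors via a custom embedder
  emb <- function(text) if (grepl("a", text)) c(1, 1, 0) else c(0, 1, 1)
  expect_equal(as.numeric(semantic_similarity("a", "b", emb)), 0.5)
  zero <- function(text) c(0, 0, 0)
  expect_warning(res <- semantic_similarity("x", "y", zero), "Zero-norm")
  expect_equal(as.numeric(res), 0)
})

test_that("diversity report aggregates per definition", {
  co <- make_corpus(list(c(0, 1)), words_per_impression = 30)
  # variants identical to sources -> all metrics 1
  v <- generate_variant_sets(co, co$report_id,
                             paraphrase_config(n_variants = 3, seed = 1))
  v$impression <- co$impression[match(v$source_report_id, co$report_id)]
  rep1 <- diversity_report(v, co)
  expect_equal(rep1$self_bleu_single, 1)
  expect_equal(rep1$self_bleu_multi, 1)
  expect_equal(rep1$cosine_similarity, 1, tolerance = 1e-12)
  # singleton sets: multi-reference component absent
  v1 <- v[v$variant_index == 1, ]
  expect_true(is.na(diversity_report(v1, co)$self_bleu_multi))
  expect_error(diversity_report(v[0, ], co), "empty")
})

test_that("rule-paraphrased long reports are more diverse vs source than pool", {
  co <- generate_corpus(generator_config(60, organ = "liver", seed = 41))
  w <- metaug:::count_words(co$impression)
  long_ids <- co$report_id[w >= 40][1:10]
  v <- generate_variant_sets(co, long_ids,
                             paraphrase_config(n_variants = 5, seed = 3))
  d <- diversity_report(v, co)
  # variants share substitution slots, so the pool overlaps itself more
  # than it overlaps the unsubstituted source
  expect_lt(d$self_bleu_single, d$self_bleu_multi)
  expect_gt(d$cosine_similarity, 0.7)
})

test_that("history truncation keeps the dated window and the target", {
  months <- c(0, 5, 11, 14, 26)
  co <- make_corpus(list(rep(0, 5)))
  co$date <- as.Date("2016-01-01") + round(months * 30.4375)
  # window 1 year at target month 26 -> months {14, 26}
  tr <- truncate_history(co, 4L, 1)
  expect_equal(tr$position, c(3L, 4L))
  # infinite window -> full prefix
  expect_equal(truncate_history(co, 3L, Inf)$position, 0:3)
  # window smaller than the gap -> singleton target
  expect_equal(truncate_history(co, 4L, 0.1)$position, 4L)
  expect_error(truncate_history(co, 9L, 1), "out of range")
  expect_error(truncate_history(co, 2L, -1), "positive")
  # monotonicity: larger windows give supersets
  for (wy in list(c(0.5, 1), c(1, 2), c(2, Inf))) {
    a <- truncate_history(co, 4L, wy[1])$position
    b <- truncate_history(co, 4L, wy[2])$position
    expect_true(all(a %in% b))
  }
})

test_that("windowed evaluation reads the target at the truncated end", {
  co <- generate_corpus(generator_config(8, seed = 3))
  co$split <- "test"
  enc <- encoder_config(kind = "hashed_ngram", dim = 64)
  agg <- aggregator_config(input_dim = 64, projected_dim = 8,
                           recurrent_hidden = 8, attention_heads = 2)
  m <- build_model(enc, agg, seed = 5)
  inf_preds <- evaluate_with_window(m, co, Inf)
  expect_equal(nrow(inf_preds), nrow(co))
  # Inf window equals the plain causal pass
  plain <- predict_corpus(m, co)
  expect_equal(inf_preds$probability, plain$probability, tolerance = 1e-12)
  # a tiny window reduces each prediction to the single-report context
  tiny <- evaluate_with_window(m, co, 0.001)
  for (p in split(co, co$patient_id)) {
    p <- p[order(p$position), ]
    for (i in seq_len(nrow(p))) {
      solo <- forward_patient(
        embed_corpus(p[i, ], enc), m$aggregator$params)$probabilities
      expect_equal(tiny$probability[tiny$report_id == p$report_id[i]], solo,
                   tolerance = 1e-12)
    }
  }
})

test_that("multi-seed aggregation matches an independent recomputation", {
  sweep <- structure(
    list(results = tibble::tibble(seed = 1:5,
                                  test_f1 = c(0.8, 0.82, 0.79, 0.85, 0.81),
                                  best_val_f1 = NA_real_),
         mean = mean(c(0.8, 0.82, 0.79, 0.85, 0.81)),
         sd = sd(c(0.8, 0.82, 0.79, 0.85, 0.81)),
         best = 0.85),
    class = "metaug_sweep")
  g <- glance(sweep)
  expect_equal(g$mean_f1, mean(tidy(sweep)$test_f1))
  expect_equal(g$sd_f1, sd(tidy(sweep)$test_f1))
  expect_equal(g$best_f1, max(tidy(sweep)$test_f1))
})
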