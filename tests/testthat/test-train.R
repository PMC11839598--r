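small_setup <- function(n = 30, cue = 1, seed = 19) {
  co <- generate_corpus(generator_config(n, organ = "liver",
                                         cue_strength = cue, seed = seed))
  co <- split_by_patient(co, c(train = 0.6, validation = 0.2, test = 0.2),
                         seed = seed)
  enc <- encoder_config(kind = "hashed_ngram", dim = 128)
  agg <- aggregator_config(input_dim = 128, projected_dim = 16,
                           recurrent_hidden = 16, attention_heads = 2)
  list(corpus = co, enc = enc, agg = agg,
       train = co[co$split == "train", ],
       val = co[co$split == "validation", ],
       test = co[co$split == "test", ])
}

test_that("binary F1 pools report positions and handles degenerate input", {
  expect_equal(binary_f1(c(0.9, 0.1, 0.8), c(1, 0, 1)), 1)
  # TP = 6, FP = 2, FN = 2 -> precision = recall = F1 = 0.75
  probs <- c(rep(0.9, 6), rep(0.9, 2), rep(0.1, 2), rep(0.1, 5))
  gold <- c(rep(1, 6), rep(0, 2), rep(1, 2), rep(0, 5))
  expect_equal(binary_f1(probs, gold), 0.75)
  # all-negative predictions on mixed gold
  expect_equal(binary_f1(c(0.1, 0.2), c(1, 0)), 0)
  # no positives anywhere -> 0 with a warning flag
  expect_warning(res <- binary_f1(c(0.1, 0.1), c(0, 0)), "F1 set to 0")
  expect_equal(as.numeric(res), 0)
  expect_true(attr(res, "undefined"))
})

test_that("budget-matched epochs equalize epochs x dataset size", {
  expect_equal(budget_matched_epochs(100, 500, 500), 10L)
  expect_equal(budget_matched_epochs(100, 1000, 100), 55L)
  expect_equal(budget_matched_epochs(10, 10, 100000), 1L)   # clamped
  expect_error(budget_matched_epochs(0, 10, 0), "denominator")
  expect_error(training_config(patience = 0), "patience")
})

test_that("training is seed-deterministic and tracks its best epoch", {
  s <- small_setup()
  cfg <- training_config(max_epochs = 5, patience = 5, seed = 3)
  fit1 <- train(build_model(s$enc, s$agg, seed = 3), s$train, s$val, cfg)
  fit2 <- train(build_model(s$enc, s$agg, seed = 3), s$train, s$val, cfg)
  expect_identical(tidy(fit1), tidy(fit2))
  expect_identical(fit1$model$aggregator$params, fit2$model$aggregator$params)
  h <- fit1$history
  expect_equal(h$best_validation_f1, max(h$epochs$val_f1))
  expect_equal(h$epochs$val_f1[h$best_epoch], h$best_validation_f1)
  g <- glance(fit1)
  expect_equal(g$best_epoch, h$best_epoch)
})

test_that("a separable corpus is learned to high validation F1", {
  s <- small_setup(n = 100, cue = 1, seed = 23)
  cfg <- training_config(max_epochs = 50, patience = 50, seed = 1)
  fit <- train(build_model(s$enc, s$agg, seed = 1), s$train, s$val, cfg)
  expect_gte(fit$history$best_validation_f1, 0.95)
})

test_that("training rejects leaking or empty splits", {
  s <- small_setup()
  m <- build_model(s$enc, s$agg, seed = 1)
  expect_error(train(m, s$train, s$train,
                     training_config(max_epochs = 1, patience = 1)),
               "share patients")
  expect_error(train(m, s$train[0, ], s$val,
                     training_config(max_epochs = 1, patience = 1)),
               "Empty")
})

test_that("continuation trains on augmented data without touching validation", {
  s <- small_setup(n = 24, seed = 29)
  cfg <- training_config(max_epochs = 3, patience = 3, seed = 2)
  fit <- train(build_model(s$enc, s$agg, seed = 2), s$train, s$val, cfg)
  # empty synthetic set: continuation is plain fine-tuning, allowed
  aug0 <- assemble_augmented_dataset(s$train, s$train[0, ])
  fit0 <- continue_on_augmented(fit, aug0, s$val, epochs = 2, cfg)
  expect_equal(nrow(tidy(fit0)), 2L)
  # real synthetic patients
  v <- generate_variant_sets(s$train, select_vanilla(s$train),
                             paraphrase_config(n_variants = 2, seed = 2))
  syn <- compose_corpus(s$train, v, seed = 2)
  aug <- assemble_augmented_dataset(s$train, syn)
  expect_true(all(!aug$combined$patient_id %in% s$val$patient_id))
  fit2 <- continue_on_augmented(fit, aug, s$val, epochs = 2, cfg)
  expect_equal(nrow(tidy(fit2)), 2L)
  # leak detection
  bad <- aug$combined
  bad$patient_id[1] <- s$val$patient_id[1]
  expect_error(continue_on_augmented(fit, bad, s$val, 2, cfg), "leaks")
  expect_error(continue_on_augmented(fit, aug, s$val, 0, cfg), "epochs")
})

test_that("PEFT regimes freeze the base encoder during optimization", {
  co <- make_corpus(list(c(0, 1), c(1, 0), c(0, 0), c(1, 1)),
                    words_per_impression = 10)
  val <- make_corpus(list(c(0, 1)), words_per_impression = 10)
  val$patient_id <- "V-P001"
  val$report_id <- sub("T-P001", "V-P001", val$report_id)
  enc <- encoder_config(kind = "tiny_transformer", dim = 8, layers = 1,
                        heads = 2, width = 8, vocab_hash_size = 64,
                        max_tokens = 16, seed = 2)
  agg <- aggregator_config(input_dim = 8, projected_dim = 4,
                           recurrent_hidden = 4, attention_heads = 2)
  cfg <- training_config(max_epochs = 2, patience = 2, seed = 6)
  for (regime in c("lora", "prefix")) {
    m <- build_model(enc, agg, regime = regime,
                     lora = lora_spec(rank = 2),
                     prefix = prefix_spec(prompt_length = 2), seed = 2)
    before <- m$encoder$params
    peft_before <- m$encoder$peft
    fit <- train(m, co, val, cfg)
    expect_identical(fit$model$encoder$params, before)      # frozen base
    expect_false(identical(fit$model$encoder$peft, peft_before))
  }
  # full fine-tuning does move the base
  m <- build_model(enc, agg, regime = "full", seed = 2)
  fit <- train(m, co, val, cfg)
  expect_false(identical(fit$model$encoder$params$Emb, m$encoder$params$Emb))
})

test_that("minority upsampling duplicates minority patients in the epoch", {
  co <- make_corpus(list(c(1, 1), c(0, 0), c(0, 0), c(0, 0)))
  ids <- metaug:::minority_upsample_ids(co)
  expect_equal(sum(ids == "T-P001"), 3L)  # 1 original + factor 2 replicas
  expect_equal(sum(ids == "T-P002"), 1L)
})

test_that("checkpoints reload deterministically", {
  s <- small_setup(n = 12, seed = 31)
  m <- build_model(s$enc, s$agg, seed = 4)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  p1 <- predict_corpus(m, s$test)
  p2 <- predict_corpus(m2, s$test)
  expect_equal(p1$probability, p2$probability, tolerance = 1e-12)
})
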