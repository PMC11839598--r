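length_fixture <- function() {
  counts <- c(5, 10, 15, 19, 20, 21, 40, 60, 80, 120)
  co <- make_corpus(list(rep(0, 10)))
  co$impression <- vapply(counts, function(n)
    paste(rep("word", n), collapse = " "), character(1))
  co
}

test_that("vanilla selection takes every training report and is idempotent", {
  expect_length(
    select_vanilla(make_corpus(list(0))[0, ])$selected_report_ids, 0)
  co <- make_corpus(rep(list(c(0, 1, 0)), 4))
  s1 <- select_vanilla(co)
  expect_setequal(s1$selected_report_ids, co$report_id)
  expect_identical(s1, select_vanilla(co))
})

test_that("length filter uses an inclusive 20-word threshold", {
  co <- length_fixture()
  sel <- select_by_length(co, 20)
  expect_length(sel$selected_report_ids, 6)
  w <- metaug:::count_words(co$impression)
  expect_setequal(sel$selected_report_ids, co$report_id[w >= 20])
  # boundary: 19 tokens out, 20 tokens in
  expect_false(co$report_id[4] %in% sel$selected_report_ids)
  expect_true(co$report_id[5] %in% sel$selected_report_ids)
  # empty impressions select nothing
  co$impression <- ""
  expect_length(select_by_length(co, 20)$selected_report_ids, 0)
  # exact partition with the below-threshold complement
  expect_equal(length(sel$selected_report_ids) + sel$diagnostics$n_below,
               nrow(length_fixture()))
})

test_that("KF-MF selection matches the brute-force fold oracle", {
  co <- make_corpus(rep(list(c(0, 1), c(1, 1, 0), c(0, 0)), 5))
  for (k in c(2L, 3L, 5L)) {
    cfg <- kfmf_config(k = k, epochs_per_fold = 1, seed = 42)
    sel <- select_by_kfmf(co, cfg, stub_confusion_trainer)
    oracle <- oracle_kfmf(co, k, 42, stub_confusion_trainer)
    expect_setequal(sel$selected_report_ids, oracle)
    # folds partition the patients
    folds <- sel$diagnostics$folds
    expect_setequal(names(folds), unique(co$patient_id))
    expect_equal(sort(unique(unname(folds))), seq_len(k))
  }
})

test_that("KF-MF degenerate trainers behave as specified", {
  co <- make_corpus(rep(list(c(0, 1, 1)), 6))
  oracle_trainer <- function(fit, epochs) {
    function(corpus) tibble::tibble(report_id = corpus$report_id,
                                    probability = as.numeric(corpus$label))
  }
  zero_trainer <- function(fit, epochs) {
    function(corpus) tibble::tibble(report_id = corpus$report_id,
                                    probability = 0)
  }
  cfg <- kfmf_config(k = 3, seed = 1)
  expect_length(select_by_kfmf(co, cfg, oracle_trainer)$selected_report_ids, 0)
  sel0 <- select_by_kfmf(co, cfg, zero_trainer)
  expect_setequal(sel0$selected_report_ids, co$report_id[co$label == 1L])
  expect_error(select_by_kfmf(co, kfmf_config(k = 7), oracle_trainer),
               "exceeds")
  expect_error(kfmf_config(k = 1), "k")
})

test_that("minority selection thresholds patients and sizes replication", {
  co <- make_corpus(list(c(0, 0, 1), c(0, 1), c(0, 0)))
  sel <- select_minority(co)
  # (0,0,1): fraction 1/3 -> out; (0,1): 1/2 -> in
  expect_setequal(sel$diagnostics$minority_patients, "T-P002")
  expect_setequal(sel$selected_report_ids,
                  co$report_id[co$patient_id == "T-P002"])

  # balanced corpus -> factor 0
  bal <- make_corpus(list(c(1, 1), c(0, 0)))
  expect_equal(select_minority(bal)$replication_factor, 0L)

  # 930 negatives / 70 positives -> round(930/70) - 1 = 12
  skew <- make_corpus(c(rep(list(rep(0, 30)), 31), rep(list(rep(1, 10)), 7)))
  expect_equal(sum(skew$label == 0L), 930L)
  expect_equal(sum(skew$label == 1L), 70L)
  expect_equal(select_minority(skew)$replication_factor, 12L)
})

test_that("composition implements maximum-use matching", {
  co <- make_corpus(list(c(0, 1, 1)))
  cfg <- paraphrase_config(n_variants = 3, seed = 2)

  # all sets empty -> no synthetic patients
  expect_equal(nrow(compose_synthetic_patients(co, co[0, ], seed = 1)), 0L)

  # l_i = (2, 2, 2): 2 synthetic patients, all 6 variants used exactly once
  v <- generate_variant_sets(co, co$report_id,
                             paraphrase_config(n_variants = 2, seed = 2))
  syn <- compose_synthetic_patients(co, v, seed = 1)
  expect_equal(dplyr::n_distinct(syn$patient_id), 2L)
  expect_setequal(syn$variant_id, v$report_id)
  expect_equal(anyDuplicated(syn$variant_id), 0L)

  # l_i = (2, 0, 3): 3 synthetic patients; position 1 copies the original
  v23 <- dplyr::bind_rows(
    generate_variant_sets(co, co$report_id[1],
                          paraphrase_config(n_variants = 2, seed = 2)),
    generate_variant_sets(co, co$report_id[3],
                          paraphrase_config(n_variants = 3, seed = 2)))
  syn2 <- compose_synthetic_patients(co, v23, seed = 1)
  expect_equal(dplyr::n_distinct(syn2$patient_id), 3L)
  mid <- syn2[syn2$position == 1L, ]
  expect_true(all(mid$impression == co$impression[2]))
  expect_true(all(mid$source_report_id == co$report_id[2]))
  used <- syn2$variant_id[!is.na(syn2$variant_id)]
  expect_setequal(unique(used), v23$report_id)  # all 5 variants appear
  # labels and dates preserved position-wise
  for (sp in split(syn2, syn2$patient_id)) {
    sp <- sp[order(sp$position), ]
    expect_equal(sp$label, co$label)
    expect_equal(sp$date, co$date)
  }
  # determinism
  expect_identical(syn2, compose_synthetic_patients(co, v23, seed = 1))
})

test_that("augmented assembly enforces provenance and counts", {
  co <- make_corpus(rep(list(c(0, 1)), 3))
  v <- generate_variant_sets(co, co$report_id,
                             paraphrase_config(n_variants = 2, seed = 3))
  syn <- compose_corpus(co, v, seed = 4)
  aug <- assemble_augmented_dataset(co, syn)
  expect_equal(dplyr::n_distinct(aug$combined$patient_id),
               dplyr::n_distinct(co$patient_id) +
                 dplyr::n_distinct(syn$patient_id))
  expect_true(all(aug$provenance_index$source_report_id %in% co$report_id))

  # no synthetic patients -> D_aug = D
  aug0 <- assemble_augmented_dataset(co, syn[0, ])
  expect_equal(nrow(aug0$combined), nrow(co))

  # foreign source -> integrity error
  bad <- syn
  bad$source_report_id[1] <- "ELSEWHERE"
  expect_error(assemble_augmented_dataset(co, bad), "outside the training")
})

test_that("targeted selections are subsets of vanilla and counts account", {
  co <- generate_corpus(generator_config(30, seed = 17))
  co$split <- "train"
  vanilla <- select_vanilla(co)
  length_sel <- select_by_length(co)
  minority <- select_minority(co)
  expect_true(all(length_sel$selected_report_ids %in%
                    vanilla$selected_report_ids))
  expect_true(all(minority$selected_report_ids %in%
                    vanilla$selected_report_ids))
  expect_equal(generated_sample_count(vanilla, 10),
               10L * nrow(co))
  expect_equal(generated_sample_count(length_sel, 10),
               10L * length(length_sel$selected_report_ids))
  expect_equal(generated_sample_count(minority, 10),
               10L * length(minority$selected_report_ids) +
                 minority$replication_factor *
                   length(minority$selected_report_ids))
})

test_that("minority replication reuses variants round-robin", {
  co <- make_corpus(list(c(1, 1), c(0, 0), c(0, 0), c(0, 0)))
  sel <- select_minority(co)
  expect_equal(sel$replication_factor, 2L)  # round(6/2) - 1
  v <- generate_variant_sets(co, sel$selected_report_ids,
                             paraphrase_config(n_variants = 2, seed = 5))
  reps <- replicate_minority_patients(co, sel, v)
  expect_equal(dplyr::n_distinct(reps$patient_id), 2L)
  expect_true(all(reps$source_report_id %in% co$report_id))
  # replica r uses variant ((r-1) mod l)+1 at each position
  first <- reps[reps$patient_id == "T-P001-rep01" & reps$position == 0L, ]
  expect_equal(first$variant_id,
               v$report_id[v$source_report_id == co$report_id[1]][1])
})
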