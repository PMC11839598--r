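#' End-to-end experiment configuration
#'
#' Describes one experiment: corpus source, patient-level split,
#' augmentation strategy, paraphrase engine, model architecture and
#' adaptation regime, training protocol, and evaluation windows.
#'
#' @param corpus A [generator_config()] or a path to a JSONL corpus.
#' @param split_fractions Named fractions `c(train=, validation=, test=)`.
#' @param split_seed Seed for the patient-level split.
#' @param train_fraction Fraction of training patients to keep (seeded,
#'   nested: smaller fractions are subsets of larger ones).
#' @param strategy `"none"`, `"vanilla"`, `"length"`, `"kfmf"`, or
#'   `"minority"`.
#' @param paraphrase A [paraphrase_config()].
#' @param min_words Length-filter threshold (default 20).
#' @param kfmf A [kfmf_config()] (used when `strategy = "kfmf"`).
#' @param encoder An [encoder_config()].
#' @param regime,lora,prefix Adaptation regime passed to [build_model()].
#' @param aggregator An [aggregator_config()].
#' @param training A [training_config()].
#' @param windows History windows (years) evaluated on the test split.
#' @param compose_seed Seed for synthetic-patient composition.
#' @param out_dir Optional output directory for the results bundle.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(corpus,
                              split_fractions = c(train = 0.7,
                                                  validation = 0.15,
                                                  test = 0.15),
                              split_seed = 1L, train_fraction = 1,
                              strategy = c("none", "vanilla", "length",
                                           "kfmf", "minority"),
                              paraphrase = paraphrase_config(),
                              min_words = 20L, kfmf = kfmf_config(),
                              encoder = encoder_config(),
                              regime = "frozen", lora = NULL, prefix = NULL,
                              aggregator = aggregator_config(encoder$dim),
                              training = training_config(),
                              windows = Inf, compose_seed = 1L,
                              out_dir = NULL) {
  strategy <- match.arg(strategy)
  if (is.character(corpus) && !file.exists(corpus)) {
    abort(sprintf("Corpus file `%s` does not exist.", corpus))
  }
  if (train_fraction <= 0 || train_fraction > 1) {
    abort("`train_fraction` must be in (0, 1].")
  }
  structure(
    list(corpus = corpus, split_fractions = split_fractions,
         split_seed = as.integer(split_seed),
         train_fraction = train_fraction, strategy = strategy,
         paraphrase = paraphrase, min_words = min_words, kfmf = kfmf,
         encoder = encoder, regime = regime, lora = lora, prefix = prefix,
         aggregator = aggregator, training = training, windows = windows,
         compose_seed = as.integer(compose_seed), out_dir = out_dir),
    class = "experiment_config"
  )
}

# Seeded, nested patient-level subsetting: patients ranked by a hash of
# (seed, id); a 20% subset is contained in the 50% subset for one seed.
subset_train_fraction <- function(train_corpus, fraction, seed) {
  if (fraction >= 1) return(train_corpus)
  ids <- sort(unique(train_corpus$patient_id))
  score <- vapply(ids, function(id) fnv1a32(paste0(seed, "|subset|", id)),
                  integer(1))
  keep <- ids[order(score, ids)][seq_len(ceiling(fraction * length(ids)))]
  train_corpus[train_corpus$patient_id %in% keep, ]
}

resolve_selection <- function(config, train_corpus, seed) {
  switch(config$strategy,
    vanilla = select_vanilla(train_corpus),
    length = select_by_length(train_corpus, config$min_words),
    kfmf = {
      kc <- config$kfmf
      kc$seed <- seed
      trainer <- make_patient_trainer(config$encoder, config$aggregator,
                                      config$training, regime = config$regime,
                                      lora = config$lora,
                                      prefix = config$prefix)
      select_by_kfmf(train_corpus, kc, trainer)
    },
    minority = select_minority(train_corpus),
    abort("No selection for strategy \"none\".")
  )
}

#' Run one end-to-end experiment
#'
#' Executes generate/load -> split -> subset -> (select -> paraphrase ->
#' compose) -> train -> continue -> evaluate for a single seed, and
#' optionally writes a results bundle (metrics CSVs, resolved-config
#' snapshot) to `config$out_dir`.
#'
#' Continuation epochs are the configured base for vanilla augmentation
#' and budget-matched (epochs x training patients equalized against
#' vanilla) for the targeted strategies.
#'
#' @param config An [experiment_config()].
#' @param seed Optional integer overriding every stage seed (training,
#'   paraphrasing, composition); the split and corpus stay fixed so
#'   multi-seed sweeps rerun the learning, not the data.
#' @return A results bundle: corpus and selection summaries, sample
#'   counts, fitted models with histories, test F1, and per-window
#'   prediction results.
#' @export
run_experiment <- function(config, seed = NULL) {
  seed <- if (is.null(seed)) config$training$seed else as.integer(seed)
  corpus <- if (is.character(config$corpus)) {
    read_corpus_jsonl(config$corpus)
  } else {
    generate_corpus(config$corpus)
  }
  if (all(is.na(corpus$split))) {
    corpus <- split_by_patient(corpus, config$split_fractions,
                               config$split_seed)
  }
  train_c <- subset_train_fraction(corpus[corpus$split == "train", ],
                                   config$train_fraction, config$split_seed)
  val_c <- corpus[corpus$split == "validation", ]
  test_c <- corpus[corpus$split == "test", ]

  tcfg <- config$training
  tcfg$seed <- seed
  model <- build_model(config$encoder, config$aggregator,
                       regime = config$regime, lora = config$lora,
                       prefix = config$prefix, seed = seed)
  fit <- train(model, train_c, val_c, tcfg)

  selection <- NULL
  variants <- NULL
  augmented <- NULL
  fit_final <- fit
  continuation_epochs <- 0L
  n_syn_patients <- 0L
  if (config$strategy != "none") {
    selection <- resolve_selection(config, train_c, seed)
    pcfg <- config$paraphrase
    pcfg$seed <- seed
    variants <- generate_variant_sets(train_c, selection, pcfg)
    synthetic <- if (config$strategy == "minority") {
      replicate_minority_patients(train_c, selection, variants)
    } else {
      compose_corpus(train_c, variants, seed = seed)
    }
    augmented <- assemble_augmented_dataset(train_c, synthetic)
    n_original <- dplyr::n_distinct(train_c$patient_id)
    n_syn_patients <- dplyr::n_distinct(synthetic$patient_id)
    n_syn_vanilla <- pcfg$n_variants * n_original
    continuation_epochs <- if (config$strategy == "vanilla") {
      tcfg$augmented_epochs_base
    } else {
      budget_matched_epochs(n_original, n_syn_vanilla, n_syn_patients,
                            base = tcfg$augmented_epochs_base)
    }
    fit_final <- continue_on_augmented(fit, augmented, val_c,
                                       continuation_epochs, tcfg)
  }

  window_results <- dplyr::bind_rows(lapply(config$windows, function(wy) {
    preds <- evaluate_with_window(fit_final$model, test_c, wy)
    tibble::tibble(
      window_years = wy,
      f1 = as.numeric(binary_f1(preds,
                                threshold = tcfg$decision_threshold)))
  }))
  test_preds <- evaluate_with_window(fit_final$model, test_c, Inf)
  test_f1 <- as.numeric(binary_f1(test_preds,
                                  threshold = tcfg$decision_threshold))

  bundle <- list(
    seed = seed,
    corpus_summary = corpus_summary(corpus),
    selection = selection,
    counts = list(
      n_train_patients = dplyr::n_distinct(train_c$patient_id),
      n_train_reports = nrow(train_c),
      n_synthetic_patients = n_syn_patients,
      generated_samples = if (is.null(selection)) 0L else
        generated_sample_count(selection, config$paraphrase$n_variants),
      continuation_epochs = continuation_epochs
    ),
    fit = fit,
    fit_final = fit_final,
    test_f1 = test_f1,
    window_results = window_results,
    predictions = test_preds,
    config = config
  )
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(tidy(bundle$fit_final$history),
                   file.path(out_dir, "history.csv"), row.names = FALSE)
  utils::write.csv(bundle$window_results,
                   file.path(out_dir, "results.csv"), row.names = FALSE)
  snapshot <- list(
    seed = bundle$seed, strategy = bundle$config$strategy,
    counts = bundle$counts, test_f1 = bundle$test_f1,
    split_fractions = as.list(bundle$config$split_fractions),
    train_fraction = bundle$config$train_fraction
  )
  yaml::write_yaml(snapshot, file.path(out_dir, "snapshot.yaml"))
  if (!is.null(bundle$selection)) {
    jsonlite::write_json(
      list(strategy = bundle$selection$strategy,
           selected_report_ids = bundle$selection$selected_report_ids,
           replication_factor = bundle$selection$replication_factor),
      file.path(out_dir, "selection.json"), auto_unbox = TRUE, null = "null")
  }
  invisible(out_dir)
}

#' Desk-scale directional augmentation benchmark
#'
#' The package's reference experiment: on one generated liver-like
#' corpus (fixed patient-level split), train per seed (i) the
#' no-augmentation baseline, (ii) the same model continued on
#' vanilla-augmented data, and (iii) the history-free single-report
#' baseline, then evaluate test F1 — for the augmented model also under
#' finite history windows.
#'
#' @param seeds Training seeds (default `1:5`).
#' @param n_train,n_validation,n_test Patient counts per split.
#' @param positive_rate,cue_strength,label_persistence Generator
#'   parameters (defaults 0.31, 0.7, 0.9).
#' @param n_variants Paraphrase variants per report (default 10).
#' @param windows Finite history windows (years) evaluated with the
#'   augmented model (default 1).
#' @param max_epochs,patience Base-training protocol for the benchmark
#'   (defaults 40 and 12).
#' @param corpus_seed Seed of the shared generated corpus.
#' @return A `metaug_benchmark` list: `results` (tibble of seed x arm x
#'   F1), `corpus_summary`, and the per-arm mean F1s in `summary`.
#' @export
da_benchmark <- function(seeds = 1:5, n_train = 200L, n_validation = 100L,
                         n_test = 150L, positive_rate = 0.31,
                         cue_strength = 0.7, label_persistence = 0.9,
                         n_variants = 10L, windows = 1,
                         max_epochs = 40L, patience = 12L,
                         corpus_seed = 7L) {
  n_total <- n_train + n_validation + n_test
  gcfg <- generator_config(n_total, organ = "liver",
                           positive_rate = positive_rate,
                           cue_strength = cue_strength,
                           label_persistence = label_persistence,
                           seed = corpus_seed)
  corpus <- generate_corpus(gcfg)
  corpus <- split_by_patient(
    corpus, c(train = n_train, validation = n_validation, test = n_test) /
      n_total, seed = corpus_seed)
  train_c <- corpus[corpus$split == "train", ]
  val_c <- corpus[corpus$split == "validation", ]
  test_c <- corpus[corpus$split == "test", ]

  enc <- encoder_config(kind = "hashed_ngram", dim = 256L)
  agg <- aggregator_config(input_dim = 256L, projected_dim = 32L,
                           recurrent_hidden = 32L, attention_heads = 2L)
  agg_single <- aggregator_config(input_dim = 256L, projected_dim = 32L,
                                  recurrent_hidden = 32L,
                                  attention_heads = 2L, single_report = TRUE)

  rows <- list()
  for (s in seeds) {
    tcfg <- training_config(max_epochs = max_epochs, patience = patience,
                            seed = s)
    model <- build_model(enc, agg, seed = s)
    fit <- train(model, train_c, val_c, tcfg)
    f1_noda <- as.numeric(binary_f1(predict_corpus(fit$model, test_c)))

    selection <- select_vanilla(train_c)
    pcfg <- paraphrase_config(n_variants = n_variants, seed = s)
    variants <- generate_variant_sets(train_c, selection, pcfg)
    synthetic <- compose_corpus(train_c, variants, seed = s)
    augmented <- assemble_augmented_dataset(train_c, synthetic)
    fit_da <- continue_on_augmented(fit, augmented, val_c,
                                    tcfg$augmented_epochs_base, tcfg)
    f1_da <- as.numeric(binary_f1(predict_corpus(fit_da$model, test_c)))

    model_sr <- build_model(enc, agg_single, seed = s)
    fit_sr <- train(model_sr, train_c, val_c, tcfg)
    f1_sr <- as.numeric(binary_f1(predict_corpus(fit_sr$model, test_c)))

    wrows <- lapply(windows, function(wy) {
      preds <- evaluate_with_window(fit_da$model, test_c, wy)
      tibble::tibble(seed = s, arm = sprintf("da_window_%gy", wy),
                     f1 = as.numeric(binary_f1(preds)))
    })
    rows[[length(rows) + 1L]] <- dplyr::bind_rows(
      tibble::tibble(seed = s,
                     arm = c("no_da", "vanilla_da", "single_report"),
                     f1 = c(f1_noda, f1_da, f1_sr)),
      dplyr::bind_rows(wrows))
  }
  results <- dplyr::bind_rows(rows)
  summary <- dplyr::summarise(dplyr::group_by(results, .data$arm),
                              mean_f1 = mean(.data$f1),
                              sd_f1 = if (length(seeds) > 1) sd(.data$f1) else 0,
                              best_f1 = max(.data$f1), .groups = "drop")
  structure(
    list(results = results, summary = summary,
         corpus_summary = corpus_summary(corpus),
         corpus = corpus, train_corpus = train_c),
    class = "metaug_benchmark"
  )
}

#' @export
print.metaug_benchmark <- function(x, ...) {
  cat("<metaug_benchmark>\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}

## --- checkpointing ----------------------------------------------------

encode_tree <- function(x) {
  if (is.matrix(x)) {
    list(`.kind` = "matrix", dim = dim(x), data = as.numeric(x))
  } else if (is.numeric(x)) {
    list(`.kind` = "numeric", data = as.numeric(x))
  } else if (is.character(x) || is.logical(x)) {
    list(`.kind` = "atomic", data = x)
  } else if (is.null(x)) {
    list(`.kind` = "null")
  } else if (is.list(x)) {
    list(`.kind` = "list", class = class(x),
         names = names(x) %||% character(0),
         items = lapply(x, encode_tree))
  } else {
    abort("Unsupported component in checkpoint.")
  }
}

decode_tree <- function(x) {
  kind <- x$`.kind`
  if (kind == "matrix") {
    matrix(unlist(x$data), x$dim[[1]], x$dim[[2]])
  } else if (kind == "numeric") {
    as.numeric(unlist(x$data))
  } else if (kind == "atomic") {
    unlist(x$data)
  } else if (kind == "null") {
    NULL
  } else {
    out <- lapply(x$items, decode_tree)
    if (length(x$names) == length(out)) names(out) <- unlist(x$names)
    cls <- unlist(x$class)
    if (!identical(cls, "list")) class(out) <- cls
    out
  }
}

#' Save a model checkpoint (JSON, full precision)
#'
#' @param model A `metaug_model`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  jsonlite::write_json(encode_tree(unclass(model)), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path File written by [save_model()].
#' @return The reconstructed `metaug_model`.
#' @export
load_model <- function(path) {
  model <- decode_tree(jsonlite::fromJSON(path, simplifyVector = FALSE))
  class(model) <- "metaug_model"
  model
}
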