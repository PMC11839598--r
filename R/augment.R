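new_selection <- function(strategy, ids, replication_factor = NA_integer_,
                          diagnostics = list()) {
  structure(
    list(
      strategy = strategy,
      selected_report_ids = unique(as.character(ids)),
      replication_factor = replication_factor,
      diagnostics = diagnostics
    ),
    class = "metaug_selection"
  )
}

#' @export
print.metaug_selection <- function(x, ...) {
  cat(sprintf("<metaug_selection> strategy=%s, %d reports selected",
              x$strategy, length(x$selected_report_ids)))
  if (!is.na(x$replication_factor)) {
    cat(sprintf(", replication_factor=%d", x$replication_factor))
  }
  cat("\n")
  invisible(x)
}

#' Vanilla selection: paraphrase every training report
#'
#' @param train_reports Corpus tibble restricted to the training split.
#' @return A `metaug_selection`.
#' @export
select_vanilla <- function(train_reports) {
  new_selection("vanilla", train_reports$report_id)
}

#' Length-filtered selection
#'
#' Selects the reports whose impression contains at least `min_words`
#' whitespace-delimited words (default threshold 20). Short impressions
#' are excluded because a paraphraser has too little material to produce
#' genuinely different rewrites of them.
#'
#' @param train_reports Corpus tibble restricted to the training split.
#' @param min_words Inclusive word-count threshold (default 20).
#' @return A `metaug_selection`.
#' @export
select_by_length <- function(train_reports, min_words = 20L) {
  min_words <- assert_count(min_words, "min_words", min = 1L)
  w <- count_words(train_reports$impression)
  new_selection("length_filter", train_reports$report_id[w >= min_words],
                diagnostics = list(min_words = min_words,
                                   n_below = sum(w < min_words)))
}

#' Configuration for k-fold misclassification filtering
#'
#' @param k Number of folds (default 5).
#' @param epochs_per_fold Training epochs for each fold model (default 20).
#' @param decision_threshold Probability cutoff for the predicted label
#'   (default 0.5).
#' @param seed Integer seed controlling the fold assignment.
#' @return A `kfmf_config` list.
#' @export
kfmf_config <- function(k = 5L, epochs_per_fold = 20L,
                        decision_threshold = 0.5, seed = 1L) {
  k <- assert_count(k, "k", min = 2L)
  if (decision_threshold <= 0 || decision_threshold >= 1) {
    abort("`decision_threshold` must be in (0, 1).")
  }
  structure(
    list(k = k,
         epochs_per_fold = assert_count(epochs_per_fold, "epochs_per_fold",
                                        min = 1L),
         decision_threshold = decision_threshold,
         seed = as.integer(seed)),
    class = "kfmf_config"
  )
}

# Seeded patient-level fold assignment; near-equal fold sizes via
# largest remainder. Returns a named integer vector patient_id -> fold.
kfmf_folds <- function(patient_ids, k, seed) {
  ids <- sort(unique(patient_ids))
  score <- vapply(ids, function(id) fnv1a32(paste0(seed, "|fold|", id)),
                  integer(1))
  ranked <- ids[order(score, ids)]
  sizes <- largest_remainder(length(ids), rep(1 / k, k))
  setNames(rep(seq_len(k), sizes), ranked)
}

#' K-fold misclassification-based selection (hard-example mining)
#'
#' Training patients are partitioned into `k` folds. For each fold a
#' fresh model is trained on the other folds for `epochs_per_fold`
#' epochs and applied to the held-out fold; a report is selected iff its
#' thresholded predicted label disagrees with the gold label. Every
#' training report is evaluated exactly once; the selection is the union
#' over folds. Folds are split at the patient level to avoid leakage
#' between the fold models' train and validation chunks.
#'
#' @param train_corpus Corpus tibble restricted to the training split.
#' @param config A [kfmf_config()].
#' @param trainer Training procedure: a function `(train_corpus, epochs)`
#'   returning a prediction function `(corpus) -> tibble(report_id,
#'   probability)`. Use [make_patient_trainer()] for the package's
#'   patient-level classifier, or inject a stub for testing.
#' @return A `metaug_selection` whose diagnostics record the fold
#'   assignment and per-fold misclassification counts.
#' @export
select_by_kfmf <- function(train_corpus, config = kfmf_config(), trainer) {
  ids <- unique(train_corpus$patient_id)
  if (config$k > length(ids)) {
    abort("`k` exceeds the number of training patients.")
  }
  folds <- kfmf_folds(ids, config$k, config$seed)
  selected <- character(0)
  per_fold <- integer(config$k)
  for (f in seq_len(config$k)) {
    held <- names(folds)[folds == f]
    fit_corpus <- train_corpus[!train_corpus$patient_id %in% held, ]
    eval_corpus <- train_corpus[train_corpus$patient_id %in% held, ]
    predict_fn <- trainer(fit_corpus, config$epochs_per_fold)
    preds <- predict_fn(eval_corpus)
    merged <- dplyr::inner_join(
      eval_corpus[, c("report_id", "label")], preds, by = "report_id")
    wrong <- merged$report_id[
      as.integer(merged$probability >= config$decision_threshold) !=
        merged$label]
    per_fold[f] <- length(wrong)
    selected <- c(selected, wrong)
  }
  new_selection("kfmf", selected,
                diagnostics = list(folds = folds,
                                   misclassified_per_fold = per_fold,
                                   config = config))
}

#' Minority-class selection with balancing replication
#'
#' Selects every report of each training patient whose positive-label
#' fraction is at least 0.5, and computes a patient replication factor
#' `max(0, round(n_neg / max(1, n_pos)) - 1)` from the report-level class
#' counts of the training split, so that originals plus replicas
#' approximately balance the positive and negative classes.
#'
#' @param train_corpus Corpus tibble restricted to the training split.
#' @return A `metaug_selection` with `replication_factor` set.
#' @export
select_minority <- function(train_corpus) {
  if (nrow(train_corpus) == 0L) {
    return(new_selection("minority", character(0), replication_factor = 0L))
  }
  per_patient <- dplyr::summarise(
    dplyr::group_by(train_corpus, .data$patient_id),
    pos_frac = mean(.data$label), .groups = "drop")
  minority_ids <- per_patient$patient_id[per_patient$pos_frac >= 0.5]
  sel <- train_corpus$report_id[train_corpus$patient_id %in% minority_ids]
  n_pos <- sum(train_corpus$label == 1L)
  n_neg <- sum(train_corpus$label == 0L)
  factor <- max(0L, as.integer(floor(n_neg / max(1L, n_pos) + 0.5)) - 1L)
  new_selection("minority", sel, replication_factor = factor,
                diagnostics = list(n_pos = n_pos, n_neg = n_neg,
                                   minority_patients = minority_ids))
}

#' Generated-sample accounting for an augmentation strategy
#'
#' The number of synthetically generated report samples attributed to a
#' selection: `n_variants` per selected report, plus — for the minority
#' strategy — one replicated sample per selected report per replication
#' round.
#'
#' @param selection A `metaug_selection`.
#' @param n_variants Paraphrase variants per selected report.
#' @return Integer count.
#' @export
generated_sample_count <- function(selection, n_variants) {
  n <- length(selection$selected_report_ids) * n_variants
  if (identical(selection$strategy, "minority") &&
      !is.na(selection$replication_factor)) {
    n <- n + selection$replication_factor * length(selection$selected_report_ids)
  }
  as.integer(n)
}

#' Compose synthetic patients from per-position variant sets
#'
#' Implements maximum-use random matching. With `l_i` variants available
#' at position `i`, `m = max_i l_i` synthetic patients are composed.
#' Position `i` of synthetic patient `j` holds the `j`-th element of a
#' seeded random permutation of variant set `i` when `j <= l_i`, a seeded
#' draw with replacement from set `i` when `1 <= l_i < j`, and a fresh
#' copy of the original report when `l_i = 0`. Every variant is therefore
#' used at least once, and `m = 0` yields no synthetic patients.
#' Randomness is keyed by `(seed, patient_id, position)`.
#'
#' @param patient_reports Corpus tibble holding one patient's reports.
#' @param variants Variant tibble (from [generate_variant_sets()])
#'   restricted to this patient; may be empty.
#' @param seed Integer seed.
#' @return A corpus tibble of synthetic patients with an extra
#'   `variant_id` column naming the originating variant (`NA` for copies
#'   of original reports).
#' @export
compose_synthetic_patients <- function(patient_reports, variants, seed = 1L) {
  patient_reports <- patient_reports[order(patient_reports$position), ]
  pid <- patient_reports$patient_id[1]
  if (!"variant_index" %in% names(variants)) {
    variants$variant_index <- seq_len(nrow(variants))
  }
  sets <- lapply(seq_len(nrow(patient_reports)), function(i) {
    v <- variants[variants$source_report_id ==
                    patient_reports$report_id[i], , drop = FALSE]
    v[order(v$variant_index), , drop = FALSE]
  })
  m <- if (length(sets) == 0L) 0L else max(vapply(sets, nrow, integer(1)))
  if (m == 0L) {
    out <- empty_corpus()
    out$variant_id <- character(0)
    return(out)
  }
  perms <- lapply(seq_along(sets), function(i) {
    li <- nrow(sets[[i]])
    if (li == 0L) integer(0) else {
      with_substream(seed, "compose", pid, i, expr = sample.int(li))
    }
  })
  out <- lapply(seq_len(m), function(j) {
    syn_pid <- sprintf("%s-syn%02d", pid, j)
    rows <- lapply(seq_along(sets), function(i) {
      src <- patient_reports[i, ]
      li <- nrow(sets[[i]])
      if (li == 0L) {
        r <- src
        r$source_report_id <- src$report_id
        r$variant_id <- NA_character_
      } else {
        pick <- if (j <= li) perms[[i]][j] else {
          with_substream(seed, "compose-draw", pid, i, j,
                         expr = sample.int(li, 1))
        }
        r <- sets[[i]][pick, , drop = FALSE]
        names(r$impression) <- NULL
        r$variant_id <- r$report_id
        r$variant_index <- NULL
      }
      r$patient_id <- syn_pid
      r$report_id <- sprintf("%s-r%02d", syn_pid, src$position)
      r$split <- src$split
      r
    })
    dplyr::bind_rows(rows)
  })
  dplyr::bind_rows(out)
}

#' Compose synthetic patients for a whole corpus
#'
#' Applies [compose_synthetic_patients()] to every patient owning at
#' least one variant.
#'
#' @param train_corpus Corpus tibble (training split).
#' @param variants Variant tibble from [generate_variant_sets()].
#' @param seed Integer seed.
#' @return Corpus tibble of all synthetic patients.
#' @export
compose_corpus <- function(train_corpus, variants, seed = 1L) {
  pids <- unique(variants$patient_id)
  out <- lapply(pids, function(pid) {
    compose_synthetic_patients(
      train_corpus[train_corpus$patient_id == pid, ],
      variants[variants$patient_id == pid, ],
      seed = seed
    )
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    res <- empty_corpus()
    res$variant_id <- character(0)
  }
  res
}

#' Replicate minority patients using paraphrase variants
#'
#' Builds `replication_factor` synthetic replicas of each selected
#' minority patient. Replica `r` fills each report position with variant
#' `((r - 1) mod l_i) + 1` of that position's set when variants exist,
#' falling back to a copy of the original text, so replicas reuse
#' distinct paraphrases round-robin.
#'
#' @param train_corpus Corpus tibble (training split).
#' @param selection A minority `metaug_selection`.
#' @param variants Variant tibble (possibly empty).
#' @return Corpus tibble of replica patients.
#' @export
replicate_minority_patients <- function(train_corpus, selection, variants) {
  stopifnot(identical(selection$strategy, "minority"))
  factor <- selection$replication_factor
  pids <- selection$diagnostics$minority_patients
  if (is.na(factor) || factor == 0L || length(pids) == 0L) {
    out <- empty_corpus()
    out$variant_id <- character(0)
    return(out)
  }
  out <- lapply(pids, function(pid) {
    p <- train_corpus[train_corpus$patient_id == pid, ]
    p <- p[order(p$position), ]
    dplyr::bind_rows(lapply(seq_len(factor), function(r) {
      syn_pid <- sprintf("%s-rep%02d", pid, r)
      rows <- lapply(seq_len(nrow(p)), function(i) {
        src <- p[i, ]
        v <- variants[variants$source_report_id == src$report_id, ,
                      drop = FALSE]
        li <- nrow(v)
        if (li > 0L) {
          vr <- v[order(v$variant_index), ][((r - 1L) %% li) + 1L, ]
          row <- vr
          row$variant_id <- vr$report_id
          row$variant_index <- NULL
        } else {
          row <- src
          row$source_report_id <- src$report_id
          row$variant_id <- NA_character_
        }
        row$patient_id <- syn_pid
        row$report_id <- sprintf("%s-r%02d", syn_pid, src$position)
        row$split <- src$split
        row
      })
      dplyr::bind_rows(rows)
    }))
  })
  dplyr::bind_rows(out)
}

#' Assemble the augmented dataset
#'
#' Combines the original training corpus with synthetic patients,
#' verifying that every synthetic report's source resolves to an
#' original training report. Validation and test data never enter the
#' augmented set.
#'
#' @param train_corpus Corpus tibble (training split only).
#' @param synthetic_patients Corpus tibble from [compose_corpus()]
#'   and/or [replicate_minority_patients()].
#' @return A `metaug_augmented` list with elements `original`,
#'   `synthetic`, `combined` (the training material), and
#'   `provenance_index` (tibble mapping every synthetic report to its
#'   source report).
#' @export
assemble_augmented_dataset <- function(train_corpus, synthetic_patients) {
  if (nrow(synthetic_patients) > 0L) {
    bad <- !synthetic_patients$source_report_id %in% train_corpus$report_id
    if (any(bad)) {
      abort("Synthetic reports sourced from outside the training split.")
    }
  }
  syn <- synthetic_patients
  syn$variant_id <- NULL
  syn$variant_index <- NULL
  combined <- dplyr::bind_rows(train_corpus, syn)
  structure(
    list(
      original = train_corpus,
      synthetic = synthetic_patients,
      combined = combined,
      provenance_index = tibble::tibble(
        synthetic_report_id = synthetic_patients$report_id,
        source_report_id = synthetic_patients$source_report_id
      )
    ),
    class = "metaug_augmented"
  )
}

#' @export
print.metaug_augmented <- function(x, ...) {
  cat(sprintf(
    "<metaug_augmented> %d original + %d synthetic patients (%d + %d reports)\n",
    dplyr::n_distinct(x$original$patient_id),
    dplyr::n_distinct(x$synthetic$patient_id),
    nrow(x$original), nrow(x$synthetic)))
  invisible(x)
}
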