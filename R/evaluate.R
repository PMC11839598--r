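ngram_counts <- function(tokens, n) {
  if (length(tokens) < n) return(integer(0))
  grams <- vapply(seq_len(length(tokens) - n + 1L), function(i)
    paste(tokens[i:(i + n - 1L)], collapse = "\u0001"), character(1))
  table(grams)
}

#' Self-BLEU of a candidate against reference texts
#'
#' BLEU with modified n-gram precision (candidate counts clipped by the
#' maximum reference count), uniform weights over n-gram orders 1 to
#' `n_max`, and the brevity penalty against the closest reference length
#' (ties resolved toward the shorter reference). Orders for which the
#' candidate has no n-grams (candidate shorter than `n`) are skipped, so
#' a candidate identical to its reference scores exactly 1. With
#' `smooth = FALSE` any zero clipped precision yields 0; with
#' `smooth = TRUE` zero precisions are floored at `1e-4`.
#'
#' Tokenization is lowercased with punctuation split off, fixed for
#' reproducibility. In single-reference mode the reference is the
#' original source; in multi-reference mode the references are the other
#' variants generated from the same source.
#'
#' @param candidate Non-empty text.
#' @param references Character vector of at least one reference text.
#' @param n_max Maximum n-gram order (default 5).
#' @param smooth Apply epsilon smoothing to zero precisions.
#' @return BLEU score in `[0, 1]`.
#' @export
self_bleu <- function(candidate, references, n_max = 5L, smooth = FALSE) {
  if (!is.character(candidate) || length(candidate) != 1L ||
      !nzchar(trimws(candidate))) {
    abort("`candidate` must be a non-empty string.")
  }
  if (length(references) < 1L) abort("At least one reference is required.")
  cand <- tokenize_text(candidate)
  refs <- lapply(references, tokenize_text)
  c_len <- length(cand)
  ref_lens <- lengths(refs)
  # closest reference length; ties toward the shorter reference
  r_len <- ref_lens[order(abs(ref_lens - c_len), ref_lens)][1]
  log_precisions <- numeric(0)
  for (n in seq_len(n_max)) {
    cc <- ngram_counts(cand, n)
    if (length(cc) == 0L) next  # candidate too short for this order
    total <- sum(cc)
    ref_counts <- lapply(refs, ngram_counts, n = n)
    clipped <- 0
    for (g in names(cc)) {
      max_ref <- 0
      for (rc in ref_counts) {
        cnt <- if (g %in% names(rc)) rc[[g]] else 0
        if (cnt > max_ref) max_ref <- cnt
      }
      clipped <- clipped + min(cc[[g]], max_ref)
    }
    p_n <- clipped / total
    if (p_n == 0) {
      if (!smooth) return(0)
      p_n <- 1e-4
    }
    log_precisions <- c(log_precisions, log(p_n))
  }
  if (length(log_precisions) == 0L) return(0)
  bp <- if (c_len >= r_len) 1 else exp(1 - r_len / c_len)
  bp * exp(mean(log_precisions))
}

#' Cosine semantic similarity between two texts
#'
#' The embedding backend is pluggable; the default is the deterministic
#' hashed n-gram encoder, so no pretrained checkpoint is needed.
#'
#' @param original,variant Texts to compare.
#' @param embedder Function mapping text to a fixed-dimension numeric
#'   vector; default hashed n-gram embedding of dimension 768.
#' @return Cosine similarity in `[-1, 1]`; 0 (with a warning) if either
#'   embedding has zero norm.
#' @export
semantic_similarity <- function(original, variant, embedder = NULL) {
  if (is.null(embedder)) {
    embedder <- function(text) embed_text_hashed(text, 768L)
  }
  a <- embedder(original)
  b <- embedder(variant)
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    warn("Zero-norm embedding; similarity set to 0.")
    return(structure(0, undefined = TRUE))
  }
  sum(a * b) / (na * nb)
}

#' Diversity and fidelity report for paraphrase variant sets
#'
#' Computes three aggregate metrics over all (source, variant) units:
#' mean single-reference self-BLEU (variant vs its source), mean
#' multi-reference self-BLEU (variant vs the other variants of the same
#' source; sets of size 1 are skipped), and mean cosine similarity
#' between source and variant. Lower self-BLEU means higher lexical
#' diversity.
#'
#' @param variants Variant tibble from [generate_variant_sets()].
#' @param sources Corpus tibble supplying the source impressions
#'   (matched by `source_report_id`).
#' @param n_max Maximum n-gram order (default 5).
#' @param embedder Optional embedding function for the cosine metric.
#' @return A one-row `metaug_diversity` tibble with columns
#'   `self_bleu_single`, `self_bleu_multi`, `cosine_similarity`, `n_max`,
#'   `n_sets`, `n_variants`.
#' @export
diversity_report <- function(variants, sources, n_max = 5L, embedder = NULL) {
  if (nrow(variants) == 0L) abort("All variant sets are empty.")
  src_text <- setNames(sources$impression, sources$report_id)
  sets <- split(variants, variants$source_report_id)
  singles <- c()
  multis <- c()
  cosines <- c()
  for (set_id in names(sets)) {
    s <- sets[[set_id]]
    source <- src_text[[set_id]]
    if (is.null(source)) {
      abort(sprintf("Source report %s not found in `sources`.", set_id))
    }
    for (i in seq_len(nrow(s))) {
      v <- s$impression[i]
      singles <- c(singles, self_bleu(v, source, n_max = n_max))
      cosines <- c(cosines, as.numeric(semantic_similarity(source, v,
                                                           embedder)))
      if (nrow(s) > 1L) {
        multis <- c(multis, self_bleu(v, s$impression[-i], n_max = n_max))
      }
    }
  }
  out <- tibble::tibble(
    self_bleu_single = mean(singles),
    self_bleu_multi = if (length(multis) > 0L) mean(multis) else NA_real_,
    cosine_similarity = mean(cosines),
    n_max = as.integer(n_max),
    n_sets = length(sets),
    n_variants = nrow(variants)
  )
  class(out) <- c("metaug_diversity", class(out))
  out
}

#' Truncate a patient's history to a time window
#'
#' Keeps exactly the reports at positions up to `target_position` whose
#' dates fall within `window_years` calendar years (365.25 days each)
#' before the target report's date; the target itself is always
#' retained. Applied at evaluation time only — training always sees full
#' timelines.
#'
#' @param patient_reports Corpus tibble for one patient.
#' @param target_position Position (0-based) of the report being
#'   evaluated.
#' @param window_years Positive number of years, or `Inf` for the full
#'   prefix.
#' @return The truncated patient tibble, chronological order preserved.
#' @export
truncate_history <- function(patient_reports, target_position, window_years) {
  p <- patient_reports[order(patient_reports$position), ]
  if (!target_position %in% p$position) {
    abort("`target_position` is out of range for this patient.")
  }
  if (!is.numeric(window_years) || window_years <= 0) {
    abort("`window_years` must be positive (possibly Inf).")
  }
  target_date <- p$date[p$position == target_position]
  keep <- p$position <= target_position &
    (is.infinite(window_years) |
       as.numeric(target_date - p$date) <= window_years * 365.25)
  p[keep, ]
}

#' Evaluate per-report predictions under a history window
#'
#' For each report of each patient, the timeline is truncated with
#' [truncate_history()] and the prediction for the target is read at the
#' truncated sequence's last position. With `window_years = Inf` this
#' reduces to a single causal pass per patient.
#'
#' @param model A `metaug_model`.
#' @param corpus Corpus tibble to evaluate.
#' @param window_years History window in years (default `Inf`).
#' @param embeddings Optional precomputed embedding matrix.
#' @return Prediction tibble as from [predict_corpus()], plus a
#'   `window_years` column.
#' @export
evaluate_with_window <- function(model, corpus, window_years = Inf,
                                 embeddings = NULL) {
  if (is.null(embeddings)) {
    embeddings <- embed_corpus(corpus, model$encoder$config,
                               model$encoder$params, model$encoder$peft)
  }
  if (is.infinite(window_years)) {
    out <- predict_corpus(model, corpus, embeddings = embeddings)
    out$window_years <- Inf
    return(out)
  }
  out <- lapply(split_patients(corpus), function(p) {
    probs <- vapply(p$position, function(tp) {
      tr <- truncate_history(p, tp, window_years)
      E <- embeddings[tr$report_id, , drop = FALSE]
      fw <- forward_patient(E, model$aggregator$params)
      fw$probabilities[nrow(tr)]
    }, numeric(1))
    tibble::tibble(patient_id = p$patient_id, report_id = p$report_id,
                   position = p$position, label = p$label,
                   probability = probs, window_years = window_years)
  })
  dplyr::bind_rows(out)
}

#' Multi-seed experiment sweep
#'
#' Reruns the full experiment pipeline once per seed on fixed splits and
#' aggregates the test F1 scores.
#'
#' @param config An [experiment_config()].
#' @param seeds Integer vector of seeds (default `1:5`).
#' @return A `metaug_sweep` list with `results` (per-seed tibble),
#'   `mean`, `sd`, `best`.
#' @export
evaluate_multi_seed <- function(config, seeds = 1:5) {
  if (length(seeds) < 1L) abort("At least one seed is required.")
  results <- lapply(seeds, function(s) {
    bundle <- tryCatch(
      run_experiment(config, seed = s),
      error = function(e) {
        abort(sprintf("Seed %d run failed: %s", s, conditionMessage(e)))
      })
    tibble::tibble(seed = s, test_f1 = bundle$test_f1,
                   best_val_f1 = bundle$fit$history$best_validation_f1)
  })
  results <- dplyr::bind_rows(results)
  structure(
    list(results = results, mean = mean(results$test_f1),
         sd = if (nrow(results) > 1L) sd(results$test_f1) else 0,
         best = max(results$test_f1)),
    class = "metaug_sweep"
  )
}

#' @export
print.metaug_sweep <- function(x, ...) {
  cat(sprintf("<metaug_sweep> %d seeds: mean F1 %.3f (sd %.3f), best %.3f\n",
              nrow(x$results), x$mean, x$sd, x$best))
  invisible(x)
}
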