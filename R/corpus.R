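#' Organ-specific cue-phrase banks
#'
#' The synthetic corpus carries a controllable, learnable label signal via
#' two disjoint phrase banks per organ: metastasis-affirming phrases placed
#' in positive-label impressions and benign/negating phrases placed in
#' negative-label impressions. The paraphrase engine treats every phrase in
#' either bank as immutable, so paraphrasing preserves the label signal by
#' construction.
#'
#' @param organ One of `"lung"`, `"liver"`, `"adrenal"`, or `"all"`.
#' @return A list with character vectors `positive` and `negative`; for
#'   `"all"`, the union over organs.
#' @export
cue_phrases <- function(organ = c("all", "lung", "liver", "adrenal")) {
  organ <- match.arg(organ)
  banks <- list(
    lung = list(
      positive = c(
        "new metastatic nodules in both lungs",
        "innumerable pulmonary metastases",
        "interval growth of metastatic lung nodules",
        "progression of pulmonary metastatic disease"
      ),
      negative = c(
        "no evidence of pulmonary metastatic disease",
        "lung nodules are stable and benign appearing",
        "no suspicious pulmonary nodules identified"
      )
    ),
    liver = list(
      positive = c(
        "new hepatic metastases",
        "multiple metastatic liver lesions",
        "interval increase in hepatic metastases",
        "progression of hepatic metastatic disease"
      ),
      negative = c(
        "no evidence of hepatic metastatic disease",
        "liver lesions are stable and benign appearing",
        "no suspicious hepatic lesions identified"
      )
    ),
    adrenal = list(
      positive = c(
        "new adrenal metastasis",
        "enlarging metastatic adrenal lesion",
        "interval growth of adrenal metastases",
        "progression of adrenal metastatic disease"
      ),
      negative = c(
        "no evidence of adrenal metastatic disease",
        "adrenal glands are unremarkable",
        "stable benign appearing adrenal adenoma"
      )
    )
  )
  if (organ == "all") {
    list(
      positive = unlist(lapply(banks, `[[`, "positive"), use.names = FALSE),
      negative = unlist(lapply(banks, `[[`, "negative"), use.names = FALSE)
    )
  } else {
    banks[[organ]]
  }
}

# Neutral sentence material shared across organs. Measurement slots keep
# digits in the text so digit-preservation by the paraphraser is exercised.
neutral_sentences <- function() {
  c(
    "Overall appearance is similar to the prior examination from last year .",
    "Mild degenerative changes are seen throughout the thoracic spine .",
    "There is a %d mm hypodense focus that is too small to characterize .",
    "Postsurgical changes are again noted in the upper abdomen .",
    "A %d mm calcified granuloma is unchanged from prior imaging .",
    "No acute osseous abnormality is identified on this examination .",
    "Scattered subcentimeter lymph nodes are seen without significant change .",
    "The visualized portions of the bowel appear grossly unremarkable .",
    "Trace free fluid is seen in the dependent pelvis .",
    "Atherosclerotic calcifications are noted in the abdominal aorta .",
    "The spleen and pancreas are within normal limits for age .",
    "A %d mm cyst in the left kidney is again demonstrated ."
  )
}

findings_sentences <- function(organ) {
  sprintf(c(
    "Dedicated %s subsection review was performed on thin slice images .",
    "The %s parenchyma demonstrates homogeneous attenuation elsewhere .",
    "Comparison with the prior %s protocol study was available ."
  ), organ)
}

#' Configuration for the synthetic corpus generator
#'
#' Defines the statistical structure of a generated longitudinal corpus:
#' per-organ report-level positive rate, timeline length distribution,
#' exam spacing, persistence of the metastasis label across consecutive
#' exams, and the strength of the lexical label signal.
#'
#' @param n_patients Number of patients to generate (>= 0).
#' @param organ `"lung"`, `"liver"` or `"adrenal"`; selects the cue bank
#'   and the default positive rate (0.16, 0.31, 0.07 respectively).
#' @param positive_rate Target report-level positive-label fraction.
#' @param mean_reports_per_patient Mean timeline length (default 9).
#' @param max_reports Maximum reports per patient (default 30).
#' @param reports_per_year Expected exam frequency (default 3/year).
#' @param label_persistence Probability that a positive label remains
#'   positive at the next exam (default 0.9).
#' @param cue_strength Probability that a report's impression carries an
#'   explicit cue sentence for its label (default 0.7).
#' @param length_distribution List with `mean_extra_sentences` and
#'   `max_extra_sentences`; impressions span roughly 8 to 120 words so
#'   both sides of the 20-word filter threshold are populated.
#' @param seed Integer seed; identical configs generate byte-identical
#'   corpora.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_patients,
                             organ = c("liver", "lung", "adrenal"),
                             positive_rate = NULL,
                             mean_reports_per_patient = 9,
                             max_reports = 30L,
                             reports_per_year = 3,
                             label_persistence = 0.9,
                             cue_strength = 0.7,
                             length_distribution = list(
                               mean_extra_sentences = 2.2,
                               max_extra_sentences = 9L
                             ),
                             seed = 1L) {
  organ <- match.arg(organ)
  n_patients <- assert_count(n_patients, "n_patients", min = 0L)
  if (is.null(positive_rate)) {
    positive_rate <- c(liver = 0.31, lung = 0.16, adrenal = 0.07)[[organ]]
  }
  assert_prob(positive_rate, "positive_rate")
  assert_prob(label_persistence, "label_persistence")
  assert_prob(cue_strength, "cue_strength")
  if (mean_reports_per_patient <= 0 || reports_per_year <= 0) {
    abort("`mean_reports_per_patient` and `reports_per_year` must be positive.")
  }
  structure(
    list(
      n_patients = n_patients, organ = organ, positive_rate = positive_rate,
      mean_reports_per_patient = mean_reports_per_patient,
      max_reports = assert_count(max_reports, "max_reports", min = 1L),
      reports_per_year = reports_per_year,
      label_persistence = label_persistence,
      cue_strength = cue_strength,
      length_distribution = length_distribution,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

# Two-state label chain: stationary report-level positive rate pi with
# persistence q requires P(0 -> 1) = pi * (1 - q) / (1 - pi); the first
# label is drawn at the stationary rate so every position is marginally
# Bernoulli(pi).
label_chain <- function(l, positive_rate, persistence) {
  pi0 <- positive_rate
  if (pi0 >= 1) return(rep(1L, l))
  t01 <- min(1, pi0 * (1 - persistence) / (1 - pi0))
  y <- integer(l)
  y[1] <- rbinom(1, 1, pi0)
  if (l > 1) {
    for (i in 2:l) {
      p <- if (y[i - 1] == 1L) persistence else t01
      y[i] <- rbinom(1, 1, p)
    }
  }
  y
}

one_impression <- function(label, organ, cue_strength, len_dist) {
  bank <- cue_phrases(organ)
  cued <- runif(1) < cue_strength
  lead <- if (cued && label == 1L) {
    sprintf("Findings are consistent with %s .", sample(bank$positive, 1))
  } else if (cued && label == 0L) {
    sprintf("%s .", sample(bank$negative, 1))
  } else {
    "Examination performed for oncologic surveillance as requested ."
  }
  n_extra <- min(rpois(1, len_dist$mean_extra_sentences),
                 len_dist$max_extra_sentences)
  extra <- character(0)
  if (n_extra > 0) {
    tmpl <- sample(neutral_sentences(), n_extra, replace = TRUE)
    extra <- vapply(tmpl, function(s) {
      if (grepl("%d", s, fixed = TRUE)) sprintf(s, sample(2:38, 1)) else s
    }, character(1), USE.NAMES = FALSE)
  }
  # Capitalized lead sentence first, then neutral filler.
  paste(c(lead, extra), collapse = " ")
}

#' Generate a synthetic longitudinal patient corpus
#'
#' Produces a tibble with one row per radiology report: ordered patient
#' timelines with non-decreasing dates, a two-state persistent metastasis
#' label process whose stationary report-level rate matches
#' `positive_rate`, and template-assembled impression text in which the
#' label is lexically signalled with probability `cue_strength`.
#' Identical configurations (including the seed) generate byte-identical
#' corpora.
#'
#' @param config A [generator_config()].
#' @return A tibble with columns `patient_id`, `report_id`, `position`,
#'   `date`, `impression`, `findings`, `label`, `organ`, `provenance`,
#'   `source_report_id`, `split`.
#' @export
generate_corpus <- function(config) {
  if (!inherits(config, "generator_config")) {
    abort("`config` must be a `generator_config`.")
  }
  if (config$n_patients == 0L) return(empty_corpus())
  rows <- lapply(seq_len(config$n_patients), function(i) {
    pid <- sprintf("%s-P%04d", toupper(substr(config$organ, 1, 2)), i)
    with_substream(config$seed, "patient", pid, expr = {
      l <- min(1L + rpois(1, config$mean_reports_per_patient - 1),
               config$max_reports)
      y <- label_chain(l, config$positive_rate, config$label_persistence)
      # first exam uniformly inside a 10-year window; i.i.d. exponential gaps
      d0 <- as.Date("2009-07-01") + floor(runif(1, 0, 3652))
      gaps <- if (l > 1) pmax(1, round(rexp(l - 1, config$reports_per_year / 365.25))) else numeric(0)
      dates <- d0 + c(0, cumsum(gaps))
      imp <- vapply(seq_len(l), function(j) {
        one_impression(y[j], config$organ, config$cue_strength,
                       config$length_distribution)
      }, character(1))
      fnd <- vapply(seq_len(l), function(j) {
        paste(c(sample(findings_sentences(config$organ), 2), imp[j]),
              collapse = " ")
      }, character(1))
      tibble::tibble(
        patient_id = pid,
        report_id = sprintf("%s-r%02d", pid, seq_len(l) - 1L),
        position = seq_len(l) - 1L,
        date = dates,
        impression = imp,
        findings = fnd,
        label = as.integer(y),
        organ = config$organ,
        provenance = "original",
        source_report_id = NA_character_,
        split = NA_character_
      )
    })
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "generator_config") <- config
  out
}

empty_corpus <- function() {
  tibble::tibble(
    patient_id = character(0), report_id = character(0),
    position = integer(0), date = as.Date(character(0)),
    impression = character(0), findings = character(0),
    label = integer(0), organ = character(0), provenance = character(0),
    source_report_id = character(0), split = character(0)
  )
}

#' Assign patients to train/validation/test splits
#'
#' Splitting is performed at the patient level so no report of one patient
#' can leak across splits. The assignment is a deterministic function of
#' the patient identifiers and the seed alone: patients are ranked by a
#' seeded hash of their id and apportioned by the largest-remainder rule
#' (remainder ties broken in train, validation, test order).
#'
#' @param corpus A corpus tibble.
#' @param fractions Named numeric vector `c(train=, validation=, test=)`
#'   summing to 1.
#' @param seed Integer seed.
#' @return The corpus with the `split` column filled in.
#' @export
split_by_patient <- function(corpus,
                             fractions = c(train = 0.7, validation = 0.15,
                                           test = 0.15),
                             seed = 1L) {
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    abort("`fractions` must be 3 non-negative values summing to 1.")
  }
  names(fractions) <- c("train", "validation", "test")
  ids <- sort(unique(corpus$patient_id))
  if (length(ids) == 0L) return(corpus)
  counts <- largest_remainder(length(ids), fractions)
  score <- vapply(ids, function(id) fnv1a32(paste0(seed, "|split|", id)),
                  integer(1))
  ranked <- ids[order(score, ids)]
  assignment <- rep(names(fractions), counts)
  lut <- setNames(assignment, ranked)
  corpus$split <- unname(lut[corpus$patient_id])
  corpus
}

#' Summarize a corpus
#'
#' @param corpus A corpus tibble.
#' @return One-row tibble with patient/report counts, the report-level
#'   positive rate, and quartiles of the words-per-impression
#'   distribution. For an empty corpus the rate and quantiles are `NA`.
#' @export
corpus_summary <- function(corpus) {
  n_rep <- nrow(corpus)
  if (n_rep == 0L) {
    return(tibble::tibble(
      n_patients = 0L, n_reports = 0L, n_positive = 0L,
      positive_rate = NA_real_, words_q25 = NA_real_,
      words_median = NA_real_, words_q75 = NA_real_
    ))
  }
  w <- count_words(corpus$impression)
  tibble::tibble(
    n_patients = dplyr::n_distinct(corpus$patient_id),
    n_reports = n_rep,
    n_positive = sum(corpus$label),
    positive_rate = sum(corpus$label) / n_rep,
    words_q25 = unname(stats::quantile(w, 0.25)),
    words_median = unname(stats::median(w)),
    words_q75 = unname(stats::quantile(w, 0.75))
  )
}

#' Write a corpus as JSONL (one patient per line)
#'
#' Each line is a JSON object with `patient_id`, `split`, and a `reports`
#' array carrying `report_id`, ISO-8601 `date`, `position`, `impression`,
#' `findings` (nullable), `label`, `organ`, `provenance`, and
#' `source_report_id` (nullable).
#'
#' @param corpus A corpus tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  split_map <- split(corpus, factor(corpus$patient_id,
                                    levels = unique(corpus$patient_id)))
  lines <- vapply(split_map, function(p) {
    p <- p[order(p$position), ]
    reports <- lapply(seq_len(nrow(p)), function(i) {
      r <- p[i, ]
      list(
        report_id = r$report_id, date = format(r$date, "%Y-%m-%d"),
        position = r$position, impression = r$impression,
        findings = if (is.na(r$findings)) NULL else r$findings,
        label = r$label, organ = r$organ, provenance = r$provenance,
        source_report_id = if (is.na(r$source_report_id)) NULL else r$source_report_id
      )
    })
    jsonlite::toJSON(list(
      patient_id = p$patient_id[1],
      split = if (is.na(p$split[1])) NULL else p$split[1],
      reports = reports
    ), auto_unbox = TRUE, null = "null")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a JSONL corpus
#'
#' Tolerates absent `findings`, `split`, and `source_report_id` fields.
#'
#' @param path JSONL file written by [write_corpus_jsonl()] or an
#'   external tool following the same schema.
#' @return A corpus tibble.
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(empty_corpus())
  rows <- lapply(lines, function(ln) {
    p <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    reports <- p$reports
    tibble::tibble(
      patient_id = p$patient_id,
      report_id = vapply(reports, `[[`, character(1), "report_id"),
      position = vapply(reports, function(r) as.integer(r$position), integer(1)),
      date = as.Date(vapply(reports, `[[`, character(1), "date")),
      impression = vapply(reports, `[[`, character(1), "impression"),
      findings = vapply(reports, function(r) r$findings %||% NA_character_,
                        character(1)),
      label = vapply(reports, function(r) as.integer(r$label), integer(1)),
      organ = vapply(reports, `[[`, character(1), "organ"),
      provenance = vapply(reports, function(r) r$provenance %||% "original",
                          character(1)),
      source_report_id = vapply(reports, function(r)
        r$source_report_id %||% NA_character_, character(1)),
      split = p$split %||% NA_character_
    )
  })
  dplyr::bind_rows(rows)
}
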