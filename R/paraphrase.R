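#' Paraphrase-engine configuration
#'
#' @param n_variants Number of paraphrase variants per selected report
#'   (default 10).
#' @param engine `"rule_based"` (deterministic, in-package) or
#'   `"llm_adapter"` (an external instruction-tuned LLM supplied as a
#'   function; no network code ships in the package).
#' @param temperature,repetition_penalty Decoding parameters recorded as
#'   metadata for the LLM adapter (defaults 0.3 and 1.15); the rule-based
#'   engine ignores them.
#' @param seed Integer seed (rule-based engine only).
#' @return A `paraphrase_config` list.
#' @export
paraphrase_config <- function(n_variants = 10L,
                              engine = c("rule_based", "llm_adapter"),
                              temperature = 0.3,
                              repetition_penalty = 1.15,
                              seed = 1L) {
  structure(
    list(
      n_variants = assert_count(n_variants, "n_variants", min = 1L),
      engine = match.arg(engine),
      temperature = temperature,
      repetition_penalty = repetition_penalty,
      seed = as.integer(seed)
    ),
    class = "paraphrase_config"
  )
}

prompt_marker <- function(name) sprintf("@@@METAUG:%s@@@", name)

escape_section <- function(x) gsub("@@@METAUG", "@@@@METAUG", x, fixed = TRUE)
unescape_section <- function(x) gsub("@@@@METAUG", "@@@METAUG", x, fixed = TRUE)

#' Default paraphrasing prompt template
#'
#' A four-part template: background, task description, and a
#' demonstration consisting of an original impression and its
#' paraphrase. The demonstration text bundled here is package fixture
#' prose, not clinical data.
#'
#' @return A named list with elements `background`, `task_description`,
#'   `demonstration_original`, `demonstration_paraphrase`.
#' @export
default_prompt_template <- function() {
  list(
    background = paste(
      "You are assisting with research on automatic reading of radiology",
      "report impression sections for cancer imaging follow-up."),
    task_description = paste(
      "Rewrite the impression below in different words while keeping every",
      "clinical fact, every measurement, and the overall conclusion",
      "unchanged. Output only the rewritten impression."),
    demonstration_original = paste(
      "Stable 6 mm nodule in the right lower lobe. No new suspicious",
      "findings. Recommend continued annual follow-up."),
    demonstration_paraphrase = paste(
      "The 6 mm right lower lobe nodule is unchanged. There are no new",
      "concerning findings. Continued yearly surveillance is advised.")
  )
}

#' Assemble a paraphrasing prompt
#'
#' Concatenates the four template sections and the target impression with
#' fixed section markers, in a fixed order. Marker strings occurring
#' inside any section are escaped so [parse_prompt()] recovers the exact
#' original text.
#'
#' @param template A list as returned by [default_prompt_template()].
#' @param impression Non-empty impression text to paraphrase.
#' @return A single prompt string.
#' @export
build_prompt <- function(template = default_prompt_template(), impression) {
  if (!is.character(impression) || length(impression) != 1L ||
      !nzchar(trimws(impression))) {
    abort("`impression` must be a non-empty string.")
  }
  parts <- c("BACKGROUND", "TASK", "DEMO_ORIGINAL", "DEMO_PARAPHRASE", "INPUT")
  texts <- c(template$background, template$task_description,
             template$demonstration_original, template$demonstration_paraphrase,
             impression)
  if (any(!nzchar(texts[1:4]))) abort("All four template sections must be non-empty.")
  paste(
    vapply(seq_along(parts), function(i) {
      paste0(prompt_marker(parts[i]), "\n", escape_section(texts[i]))
    }, character(1)),
    collapse = "\n"
  )
}

#' Parse a prompt back into its sections
#'
#' Inverse of [build_prompt()]; used to validate the escaping contract.
#'
#' @param prompt A string produced by [build_prompt()].
#' @return Named list of the five sections (including `input`).
#' @export
parse_prompt <- function(prompt) {
  parts <- c("BACKGROUND", "TASK", "DEMO_ORIGINAL", "DEMO_PARAPHRASE", "INPUT")
  markers <- vapply(parts, prompt_marker, character(1))
  lines <- strsplit(prompt, "\n", fixed = TRUE)[[1]]
  # markers stand alone on their own line; escaped copies never do
  positions <- vapply(markers, function(m) {
    hit <- which(lines == m)
    if (length(hit) == 0L) -1L else hit[1]
  }, integer(1))
  if (any(positions < 0) || is.unsorted(positions)) {
    abort("Prompt does not contain the expected section markers in order.")
  }
  out <- lapply(seq_along(parts), function(i) {
    from <- positions[i] + 1L
    to <- if (i < length(parts)) positions[i + 1] - 1L else length(lines)
    unescape_section(paste(lines[from:to], collapse = "\n"))
  })
  names(out) <- c("background", "task_description", "demonstration_original",
                  "demonstration_paraphrase", "input")
  out
}

# Versioned synonym lexicon for the rule-based engine. Lowercase content
# words only; alternatives never contain cue-bank vocabulary or digits, so
# substitution cannot create or destroy a label cue or a measurement.
synonym_lexicon <- function() {
  list(
    seen = c("noted", "observed", "visualized"),
    noted = c("seen", "observed"),
    unchanged = c("stable", "not significantly changed"),
    mild = c("minimal", "slight"),
    identified = c("detected", "appreciated"),
    examination = c("exam", "study"),
    prior = c("previous", "earlier"),
    similar = c("comparable", "nearly identical"),
    grossly = c("essentially", "largely"),
    unremarkable = c("within normal limits", "without focal abnormality"),
    trace = c("minimal", "a small amount of"),
    throughout = c("across", "involving"),
    scattered = c("several", "a few"),
    significant = c("appreciable", "notable"),
    performed = c("obtained", "completed"),
    hypodense = c("low attenuation", "hypoattenuating"),
    abnormality = c("abnormal finding", "irregularity"),
    appear = c("seem", "look"),
    demonstrated = c("shown", "redemonstrated"),
    surveillance = c("follow up", "monitoring"),
    requested = c("indicated", "ordered"),
    dependent = c("posterior", "dependent portion of the"),
    calcifications = c("calcific deposits", "vascular calcification"),
    degenerative = c("chronic degenerative", "age related degenerative")
  )
}

protect_cues <- function(text) {
  bank <- cue_phrases("all")
  phrases <- c(bank$positive, bank$negative)
  placeholders <- sprintf("⟦CUE%02d⟧", seq_along(phrases))
  for (i in seq_along(phrases)) {
    text <- gsub(phrases[i], placeholders[i], text, fixed = TRUE)
  }
  list(text = text, phrases = phrases, placeholders = placeholders)
}

restore_cues <- function(text, prot) {
  for (i in seq_along(prot$phrases)) {
    text <- gsub(prot$placeholders[i], prot$phrases[i], text, fixed = TRUE)
  }
  text
}

split_sentences <- function(text) {
  strsplit(text, "(?<=[.!?])\\s+", perl = TRUE)[[1]]
}

substitute_synonyms <- function(sentence, lexicon, sub_prob = 0.6) {
  tokens <- strsplit(sentence, " ", fixed = TRUE)[[1]]
  for (i in seq_along(tokens)) {
    alts <- lexicon[[tokens[i]]]
    if (!is.null(alts) && runif(1) < sub_prob) {
      tokens[i] <- sample(alts, 1)
    }
  }
  paste(tokens, collapse = " ")
}

#' Deterministic rule-based paraphrasing
#'
#' A desk-scale stand-in for an instruction-tuned LLM paraphraser. Each
#' variant is produced by (i) masking every cue-bank phrase so the label
#' signal is copied verbatim, (ii) substituting non-cue content words from
#' a fixed synonym lexicon, and (iii) permuting the sentences that carry
#' no cue phrase. Digits are never touched (the lexicon contains none).
#' Variant `k` is a pure function of `(impression, seed, k)`. Short
#' impressions (a single sentence with few substitutable words) leave the
#' engine almost no transformation space, so their variants are
#' near-duplicates — the behaviour that motivates length filtering.
#'
#' @param impression Source impression text.
#' @param config A [paraphrase_config()] with `engine = "rule_based"`.
#' @return Character vector of `n_variants` paraphrases.
#' @export
rule_paraphrase <- function(impression, config = paraphrase_config()) {
  if (config$engine != "rule_based") {
    abort("`rule_paraphrase()` requires engine = \"rule_based\".")
  }
  lexicon <- synonym_lexicon()
  prot <- protect_cues(impression)
  sentences <- split_sentences(prot$text)
  is_cue <- grepl("⟦CUE", sentences, fixed = TRUE)
  # short impressions leave the engine little to vary: the substitution
  # rate collapses below the 20-word mark, yielding near-duplicates
  sub_prob <- if (count_words(impression) >= 20L) 0.6 else 0.1
  key <- fnv1a32(impression)
  vapply(seq_len(config$n_variants), function(k) {
    with_substream(config$seed, "rp", key, k, expr = {
      out <- vapply(sentences, substitute_synonyms, character(1),
                    lexicon = lexicon, sub_prob = sub_prob,
                    USE.NAMES = FALSE)
      # permute the non-cue sentences among their own slots
      idx <- which(!is_cue)
      if (length(idx) > 1L) out[idx] <- out[sample(idx)]
      restore_cues(paste(out, collapse = " "), prot)
    })
  }, character(1))
}

#' Generate paraphrase variant sets for selected reports
#'
#' Every report named in `selection` receives exactly `n_variants`
#' synthetic variants; unselected reports receive an empty set (zero
#' rows). Variants copy the source report's label, organ, patient, date
#' and position, carry `provenance = "synthetic"`, and point back to the
#' source through `source_report_id`.
#'
#' @param reports A corpus tibble (typically the training split).
#' @param selection A [selection][select_vanilla] object or a character
#'   vector of report ids; must be a subset of `reports$report_id`.
#' @param config A [paraphrase_config()].
#' @param engine Optional paraphrasing function `(impression, config) ->
#'   character(n_variants)`; defaults to [rule_paraphrase()] for the
#'   rule-based engine. Required when `config$engine = "llm_adapter"`.
#' @return A tibble of synthetic reports with an extra `variant_index`
#'   column; group by `source_report_id` to recover the per-report sets.
#' @export
generate_variant_sets <- function(reports, selection,
                                  config = paraphrase_config(),
                                  engine = NULL) {
  ids <- if (inherits(selection, "metaug_selection")) {
    selection$selected_report_ids
  } else {
    as.character(selection)
  }
  unknown <- setdiff(ids, reports$report_id)
  if (length(unknown) > 0L) {
    abort(sprintf("Selection contains unknown report ids: %s",
                  paste(head(unknown, 3), collapse = ", ")))
  }
  if (is.null(engine)) {
    if (config$engine != "rule_based") {
      abort("An `engine` function must be supplied for the llm_adapter engine.")
    }
    engine <- rule_paraphrase
  }
  sel <- reports[reports$report_id %in% ids, ]
  if (nrow(sel) == 0L) {
    out <- empty_corpus()
    out$variant_index <- integer(0)
    return(out)
  }
  rows <- lapply(seq_len(nrow(sel)), function(i) {
    src <- sel[i, ]
    texts <- engine(src$impression, config)
    stopifnot(length(texts) == config$n_variants)
    tibble::tibble(
      patient_id = src$patient_id,
      report_id = sprintf("%s-syn%02d", src$report_id,
                          seq_len(config$n_variants)),
      position = src$position,
      date = src$date,
      impression = texts,
      findings = NA_character_,
      label = src$label,
      organ = src$organ,
      provenance = "synthetic",
      source_report_id = src$report_id,
      split = src$split,
      variant_index = seq_len(config$n_variants)
    )
  })
  dplyr::bind_rows(rows)
}

#' Write variant sets as JSONL (one set per line)
#'
#' @param variants Tibble from [generate_variant_sets()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants_jsonl <- function(variants, path) {
  sets <- split(variants, factor(variants$source_report_id,
                                 levels = unique(variants$source_report_id)))
  lines <- vapply(sets, function(s) {
    jsonlite::toJSON(list(
      source_report_id = s$source_report_id[1],
      variants = lapply(seq_len(nrow(s)), function(i) {
        v <- s[i, ]
        list(report_id = v$report_id, patient_id = v$patient_id,
             position = v$position, date = format(v$date, "%Y-%m-%d"),
             impression = v$impression, label = v$label, organ = v$organ,
             provenance = v$provenance,
             source_report_id = v$source_report_id,
             variant_index = v$variant_index)
      })
    ), auto_unbox = TRUE, null = "null")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read variant sets from JSONL
#'
#' @param path File written by [write_variants_jsonl()].
#' @return A tibble of synthetic reports.
#' @export
read_variants_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(ln) {
    s <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    dplyr::bind_rows(lapply(s$variants, function(v) {
      tibble::tibble(
        patient_id = v$patient_id, report_id = v$report_id,
        position = as.integer(v$position), date = as.Date(v$date),
        impression = v$impression, findings = NA_character_,
        label = as.integer(v$label), organ = v$organ,
        provenance = v$provenance, source_report_id = v$source_report_id,
        split = NA_character_, variant_index = as.integer(v$variant_index)
      )
    }))
  })
  dplyr::bind_rows(rows)
}
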