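#' Build a patient-level classification model
#'
#' Bundles an encoder (hashed n-gram or tiny transformer, optionally
#' adapted with LoRA or deep prefix-tuning) with the patient-level
#' aggregator head.
#'
#' @param encoder An [encoder_config()].
#' @param aggregator An [aggregator_config()]; its `input_dim` must match
#'   the encoder `dim`.
#' @param regime Adaptation regime for the tiny transformer: `"frozen"`,
#'   `"full"`, `"lora"`, or `"prefix"`. Ignored for the hashed encoder
#'   (which has nothing to train).
#' @param lora,prefix A [lora_spec()] / [prefix_spec()] when the
#'   corresponding regime is chosen.
#' @param seed Integer seed for all parameter initialization.
#' @return A `metaug_model` list.
#' @export
build_model <- function(encoder, aggregator,
                        regime = c("frozen", "full", "lora", "prefix"),
                        lora = NULL, prefix = NULL, seed = 1L) {
  regime <- match.arg(regime)
  if (aggregator$input_dim != encoder$dim) {
    abort("Aggregator `input_dim` must equal the encoder `dim`.")
  }
  enc_params <- NULL
  peft <- NULL
  if (encoder$kind == "tiny_transformer") {
    enc_params <- init_tiny_transformer(encoder)
    if (regime == "lora") {
      if (is.null(lora)) abort("regime = \"lora\" requires a `lora` spec.")
      peft <- attach_lora(enc_params, lora, seed = seed)
    } else if (regime == "prefix") {
      if (is.null(prefix)) abort("regime = \"prefix\" requires a `prefix` spec.")
      peft <- attach_prefix(enc_params, prefix, seed = seed)
    }
  } else {
    regime <- "frozen"
  }
  structure(
    list(encoder = list(config = encoder, params = enc_params, peft = peft,
                        regime = regime),
         aggregator = list(config = aggregator,
                           params = init_aggregator(aggregator))),
    class = "metaug_model"
  )
}

#' @export
print.metaug_model <- function(x, ...) {
  cat(sprintf("<metaug_model> encoder=%s (regime=%s), aggregator %s (d=%d -> %d)\n",
              x$encoder$config$kind, x$encoder$regime,
              if (x$aggregator$config$single_report) "single-report" else "LSTM+causal-attention",
              x$aggregator$config$input_dim, x$aggregator$config$projected_dim))
  invisible(x)
}

#' Training configuration
#'
#' @param max_epochs Epoch cap for base training (default 1000).
#' @param patience Early-stopping patience in epochs without validation
#'   F1 improvement (default 200; must be >= 1 and <= `max_epochs`).
#' @param augmented_epochs_base Continuation epochs on augmented data for
#'   the vanilla strategy at N = 10 (default 10).
#' @param learning_rate Adam step size (default 0.005).
#' @param schedule `"cosine"` (half-cosine decay over the epoch budget)
#'   or `"constant"`.
#' @param batch_size Patients per optimizer step (default 1).
#' @param minority_upsampling Duplicate minority-class patients in the
#'   training list to balance report-level classes (the no-augmentation
#'   baseline's imbalance handling).
#' @param decision_threshold Probability cutoff for the predicted label
#'   (default 0.5).
#' @param seed Integer seed; training is fully reproducible given it.
#' @return A `training_config` list.
#' @export
training_config <- function(max_epochs = 1000L, patience = 200L,
                            augmented_epochs_base = 10L,
                            learning_rate = 0.005,
                            schedule = c("cosine", "constant"),
                            batch_size = 1L, minority_upsampling = FALSE,
                            decision_threshold = 0.5, seed = 1L) {
  max_epochs <- assert_count(max_epochs, "max_epochs", 1L)
  patience <- assert_count(patience, "patience", 1L)
  if (patience > max_epochs) abort("`patience` must not exceed `max_epochs`.")
  if (decision_threshold <= 0 || decision_threshold >= 1) {
    abort("`decision_threshold` must be in (0, 1).")
  }
  structure(
    list(max_epochs = max_epochs, patience = patience,
         augmented_epochs_base = assert_count(augmented_epochs_base,
                                              "augmented_epochs_base", 1L),
         learning_rate = learning_rate, schedule = match.arg(schedule),
         batch_size = assert_count(batch_size, "batch_size", 1L),
         minority_upsampling = isTRUE(minority_upsampling),
         decision_threshold = decision_threshold, seed = as.integer(seed)),
    class = "training_config"
  )
}

## --- parameter-tree utilities ----------------------------------------

# elementwise walk over parallel parameter/gradient trees; grad == NULL
# leaves the parameter untouched (frozen)
tree_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.numeric(a)) return(a + b)
  out <- a
  for (nm in seq_along(a)) {
    v <- tree_add(a[[nm]], b[[nm]])
    if (!is.null(v)) out[[nm]] <- v  # never delete NULL placeholders
  }
  out
}

tree_scale <- function(a, s) {
  if (is.null(a)) return(NULL)
  if (is.numeric(a)) return(a * s)
  lapply(a, tree_scale, s = s)
}

tree_zeros <- function(a) tree_scale(a, 0)

# One Adam step over all numeric leaves present in `grad`.
adam_step <- function(theta, grad, state, lr, t,
                      b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  if (is.null(grad)) return(list(theta = theta, state = state))
  if (is.numeric(grad)) {
    if (is.null(state)) state <- list(m = grad * 0, v = grad * 0)
    state$m <- b1 * state$m + (1 - b1) * grad
    state$v <- b2 * state$v + (1 - b2) * grad^2
    mhat <- state$m / (1 - b1^t)
    vhat <- state$v / (1 - b2^t)
    theta <- theta - lr * mhat / (sqrt(vhat) + eps)
    return(list(theta = theta, state = state))
  }
  if (is.null(state)) state <- vector("list", length(grad))
  for (i in seq_along(grad)) {
    nm <- names(grad)[i]
    key <- if (!is.null(nm) && nzchar(nm)) nm else i
    if (is.null(grad[[i]])) next
    res <- adam_step(theta[[key]], grad[[i]], state[[i]], lr, t, b1, b2, eps)
    theta[[key]] <- res$theta
    state[[i]] <- res$state
  }
  list(theta = theta, state = state)
}

schedule_lr <- function(config, epoch, total_epochs) {
  if (config$schedule == "cosine") {
    config$learning_rate * 0.5 * (1 + cos(pi * (epoch - 1) / total_epochs))
  } else {
    config$learning_rate
  }
}

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Positive-class F1 score
#'
#' F1 of the positive class over all report positions pooled across
#' patients; a prediction is positive iff its probability is at least
#' `threshold`. When there are neither positive gold labels nor positive
#' predictions, F1 is defined as 0 and flagged with a warning.
#'
#' @param probabilities Numeric vector of predicted probabilities (or a
#'   prediction tibble with `probability` and `label` columns).
#' @param labels Binary gold labels (ignored when a tibble is given).
#' @param threshold Decision threshold (default 0.5).
#' @return F1 in `[0, 1]`; attribute `undefined` is `TRUE` in the
#'   degenerate no-positives case.
#' @export
binary_f1 <- function(probabilities, labels = NULL, threshold = 0.5) {
  if (is.data.frame(probabilities)) {
    labels <- probabilities$label
    probabilities <- probabilities$probability
  }
  pred <- as.integer(probabilities >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  if (tp + fp + fn == 0L) {
    warn("No positive gold labels and no positive predictions; F1 set to 0.")
    return(structure(0, undefined = TRUE))
  }
  if (tp == 0L) return(0)
  prec <- tp / (tp + fp)
  rec <- tp / (tp + fn)
  2 * prec * rec / (prec + rec)
}

minority_upsample_ids <- function(train_corpus) {
  per_patient <- dplyr::summarise(
    dplyr::group_by(train_corpus, .data$patient_id),
    pos_frac = mean(.data$label), .groups = "drop")
  minority <- per_patient$patient_id[per_patient$pos_frac >= 0.5]
  n_pos <- sum(train_corpus$label == 1L)
  n_neg <- sum(train_corpus$label == 0L)
  factor <- max(0L, as.integer(floor(n_neg / max(1L, n_pos) + 0.5)) - 1L)
  c(unique(train_corpus$patient_id), rep(minority, factor))
}

# core optimization loop shared by train() and continue_on_augmented()
run_training <- function(model, train_corpus, validation_corpus, config,
                         epochs, include_initial = FALSE) {
  if (nrow(train_corpus) == 0L) abort("Empty training set.")
  enc <- model$encoder
  encoder_trainable <- enc$regime %in% c("full", "lora", "prefix")
  ap <- model$aggregator$params
  ep <- enc$params
  pf <- enc$peft
  patients <- split_patients(train_corpus)
  patient_ids <- if (config$minority_upsampling) {
    minority_upsample_ids(train_corpus)
  } else {
    names(patients)
  }
  # frozen encoders: embed once up front
  train_emb <- val_emb <- NULL
  if (!encoder_trainable) {
    train_emb <- embed_corpus(train_corpus, enc$config, ep, pf)
    if (!is.null(validation_corpus)) {
      val_emb <- embed_corpus(validation_corpus, enc$config, ep, pf)
    }
  }
  texts <- NULL
  if (encoder_trainable) {
    texts <- setNames(
      vapply(seq_len(nrow(train_corpus)), function(i)
        report_text(train_corpus$impression[i], train_corpus$findings[i],
                    enc$config$input_mode), character(1)),
      train_corpus$report_id)
  }
  eval_val <- function(ap_now, ep_now, pf_now) {
    if (is.null(validation_corpus)) return(NA_real_)
    m <- model
    m$aggregator$params <- ap_now
    m$encoder$params <- ep_now
    m$encoder$peft <- pf_now
    preds <- predict_corpus(m, validation_corpus,
                            embeddings = if (encoder_trainable) NULL else val_emb)
    as.numeric(binary_f1(preds, threshold = config$decision_threshold))
  }
  history <- vector("list", epochs)
  best <- list(f1 = -Inf, epoch = 0L, ap = ap, ep = ep, pf = pf)
  if (include_initial && !is.null(validation_corpus)) {
    f0 <- eval_val(ap, ep, pf)
    best <- list(f1 = f0, epoch = 0L, ap = ap, ep = ep, pf = pf)
  }
  adam_state <- list(ap = NULL, ep = NULL, pf = NULL)
  step_count <- 0L
  for (epoch in seq_len(epochs)) {
    lr <- schedule_lr(config, epoch, epochs)
    order_ids <- with_substream(config$seed, "epoch-order", epoch,
                                expr = sample(patient_ids))
    loss_sum <- 0
    loss_n <- 0L
    batch_g <- NULL
    batch_n <- 0L
    flush <- function() {
      if (batch_n == 0L) return()
      step_count <<- step_count + 1L
      g <- tree_scale(batch_g, 1 / batch_n)
      res <- adam_step(ap, g$ap, adam_state$ap, lr, step_count)
      ap <<- res$theta; adam_state$ap <<- res$state
      if (!is.null(g$ep)) {
        res <- adam_step(ep, g$ep, adam_state$ep, lr, step_count)
        ep <<- res$theta; adam_state$ep <<- res$state
      }
      if (!is.null(g$pf)) {
        res <- adam_step(pf, g$pf, adam_state$pf, lr, step_count)
        pf <<- res$theta; adam_state$pf <<- res$state
      }
      batch_g <<- NULL; batch_n <<- 0L
    }
    for (pid in order_ids) {
      p <- patients[[pid]]
      enc_caches <- NULL
      if (encoder_trainable) {
        E <- matrix(0, nrow(p), enc$config$dim)
        enc_caches <- vector("list", nrow(p))
        for (i in seq_len(nrow(p))) {
          r <- encode_text_tiny(texts[[p$report_id[i]]], ep, pf,
                                keep_cache = TRUE)
          E[i, ] <- r$embedding
          enc_caches[[i]] <- r$cache
        }
      } else {
        E <- train_emb[p$report_id, , drop = FALSE]
      }
      fw <- forward_patient(E, ap, keep_cache = TRUE)
      y <- p$label
      loss <- bce_loss(fw$probabilities, y)
      if (!is.finite(loss)) {
        abort(sprintf("Non-finite training loss at epoch %d.", epoch))
      }
      loss_sum <- loss_sum + loss
      loss_n <- loss_n + 1L
      dlogits <- (fw$probabilities - y) / length(y)
      g_agg <- backward_patient(dlogits, ap, fw$cache)
      dP <- g_agg$dP
      g_agg$dP <- NULL
      g_agg$Wp <- t(E) %*% dP
      g <- list(ap = g_agg, ep = NULL, pf = NULL)
      if (encoder_trainable) {
        dE <- dP %*% t(ap$Wp)
        g_ep <- NULL
        g_pf <- NULL
        for (i in seq_len(nrow(p))) {
          bt <- backward_text_tiny(dE[i, ], ep, enc_caches[[i]], pf)
          if (enc$regime == "full") {
            g_ep <- tree_add(g_ep, bt$base)
          } else {
            g_pf <- tree_add(g_pf, list(layers = bt$peft))
          }
        }
        g$ep <- g_ep
        if (!is.null(g_pf)) {
          g$pf <- list(kind = NULL, spec = NULL, layers = g_pf$layers)
        }
      }
      batch_g <- tree_add(batch_g, g)
      batch_n <- batch_n + 1L
      if (batch_n >= config$batch_size) flush()
    }
    flush()
    val_f1 <- eval_val(ap, ep, pf)
    history[[epoch]] <- tibble::tibble(epoch = epoch,
                                       train_loss = loss_sum / loss_n,
                                       val_f1 = val_f1)
    improved <- if (is.na(val_f1)) TRUE else val_f1 > best$f1
    if (improved) {
      best <- list(f1 = if (is.na(val_f1)) NA_real_ else val_f1,
                   epoch = epoch, ap = ap, ep = ep, pf = pf)
    }
    if (!is.na(val_f1) && (epoch - best$epoch) >= config$patience) break
  }
  hist_tbl <- dplyr::bind_rows(history)
  model$aggregator$params <- best$ap
  model$encoder$params <- best$ep
  model$encoder$peft <- best$pf
  history_obj <- structure(
    list(epochs = hist_tbl, best_epoch = best$epoch,
         best_validation_f1 = if (is.infinite(best$f1)) NA_real_ else best$f1),
    class = "metaug_history"
  )
  structure(list(model = model, history = history_obj), class = "metaug_fit")
}

#' Train the classifier on original data
#'
#' Minimizes mean binary cross-entropy over all report positions with
#' Adam updates and the configured learning-rate schedule, evaluates
#' validation F1 after every epoch, stops early after `patience` epochs
#' without improvement, and returns the parameters of the
#' best-validation-F1 epoch. Fully reproducible given the config seed.
#'
#' @param model A `metaug_model` from [build_model()].
#' @param train_corpus,validation_corpus Corpus tibbles (patient-level
#'   disjoint). `validation_corpus = NULL` disables early stopping and
#'   model selection (the final epoch is returned) — used for fixed-epoch
#'   fold models.
#' @param config A [training_config()].
#' @return A `metaug_fit` list with elements `model` and `history`.
#' @export
train <- function(model, train_corpus, validation_corpus,
                  config = training_config()) {
  if (!is.null(validation_corpus)) {
    if (nrow(validation_corpus) == 0L) abort("Empty validation set.")
    overlap <- intersect(train_corpus$patient_id,
                         validation_corpus$patient_id)
    if (length(overlap) > 0L) {
      abort("Train and validation sets share patients.")
    }
  }
  run_training(model, train_corpus, validation_corpus, config,
               epochs = config$max_epochs)
}

#' Continue training on an augmented dataset
#'
#' Resumes optimization from a model trained on the original data, now
#' on the combined original + synthetic training material, for exactly
#' `epochs` epochs. The best checkpoint is again chosen by validation
#' F1, with the starting model included as a candidate. Validation data
#' is never augmented.
#'
#' @param fit A `metaug_fit` from [train()] (or a bare `metaug_model`).
#' @param augmented A `metaug_augmented` from
#'   [assemble_augmented_dataset()] (or a corpus tibble).
#' @param validation_corpus Validation split tibble.
#' @param epochs Number of continuation epochs (>= 1); use
#'   [budget_matched_epochs()] for targeted strategies.
#' @param config A [training_config()].
#' @return A `metaug_fit`.
#' @export
continue_on_augmented <- function(fit, augmented, validation_corpus,
                                  epochs, config = training_config()) {
  epochs <- assert_count(epochs, "epochs", min = 1L)
  model <- if (inherits(fit, "metaug_fit")) fit$model else fit
  corpus <- if (inherits(augmented, "metaug_augmented")) {
    augmented$combined
  } else {
    augmented
  }
  if (any(corpus$patient_id %in% validation_corpus$patient_id)) {
    abort("Augmented training data leaks into the validation set.")
  }
  cfg <- config
  cfg$patience <- epochs  # continuation runs all epochs
  run_training(model, corpus, validation_corpus, cfg, epochs = epochs,
               include_initial = TRUE)
}

#' Budget-matched continuation epochs for targeted augmentation
#'
#' Equalizes `epochs x dataset size` (dataset size in training patients)
#' between a targeted strategy and vanilla augmentation:
#' `round(base * (n_original + n_syn_vanilla) / (n_original +
#' n_syn_targeted))`, floored at 1.
#'
#' @param n_original Original training patients.
#' @param n_syn_vanilla Synthetic patients a vanilla run would add.
#' @param n_syn_targeted Synthetic patients the targeted run adds.
#' @param base Vanilla continuation epochs (default 10).
#' @return Integer epoch count.
#' @export
budget_matched_epochs <- function(n_original, n_syn_vanilla, n_syn_targeted,
                                  base = 10L) {
  n_original <- assert_count(n_original, "n_original")
  n_syn_vanilla <- assert_count(n_syn_vanilla, "n_syn_vanilla")
  n_syn_targeted <- assert_count(n_syn_targeted, "n_syn_targeted")
  if (n_original + n_syn_targeted == 0L) {
    abort("Zero denominator: no original or targeted-synthetic patients.")
  }
  max(1L, as.integer(floor(
    base * (n_original + n_syn_vanilla) / (n_original + n_syn_targeted) + 0.5
  )))
}

#' Patient-level trainer factory for k-fold misclassification mining
#'
#' Returns a trainer with the signature [select_by_kfmf()] expects: it
#' trains a fresh copy of the configured model on a fold's training
#' patients for a fixed number of epochs (no early stopping) and returns
#' a prediction function.
#'
#' @param encoder An [encoder_config()].
#' @param aggregator An [aggregator_config()].
#' @param config A [training_config()] (its `max_epochs`/`patience` are
#'   overridden by the per-fold epoch count).
#' @param regime,lora,prefix Passed to [build_model()].
#' @return `function(fit_corpus, epochs) -> function(corpus) ->
#'   tibble(report_id, probability)`.
#' @export
make_patient_trainer <- function(encoder, aggregator,
                                 config = training_config(),
                                 regime = "frozen", lora = NULL,
                                 prefix = NULL) {
  force(encoder); force(aggregator); force(config)
  function(fit_corpus, epochs) {
    model <- build_model(encoder, aggregator, regime = regime, lora = lora,
                         prefix = prefix, seed = config$seed)
    cfg <- config
    cfg$max_epochs <- as.integer(epochs)
    cfg$patience <- as.integer(epochs)
    fit <- run_training(model, fit_corpus, validation_corpus = NULL, cfg,
                        epochs = as.integer(epochs))
    function(corpus) {
      preds <- predict_corpus(fit$model, corpus)
      preds[, c("report_id", "probability")]
    }
  }
}

#' @export
print.metaug_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("<metaug_fit> %d epochs, best epoch %d (validation F1 %.3f)\n",
              nrow(h$epochs), h$best_epoch,
              h$best_validation_f1 %||% NA_real_))
  invisible(x)
}
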