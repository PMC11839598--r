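#' Patient-level aggregator configuration
#'
#' The aggregator turns a patient's chronological report embeddings into
#' one metastasis probability per report: linear down-projection,
#' one-directional LSTM, causal multi-head attention over the LSTM
#' outputs, and a per-position linear head with logistic squashing. With
#' `single_report = TRUE` the recurrent and attention stages are removed
#' and the head reads the projected embedding directly — the
#' history-free baseline architecture.
#'
#' @param input_dim Embedding dimension `d` coming from the encoder.
#' @param projected_dim Down-projection width (default 128).
#' @param recurrent_hidden LSTM hidden size (default 128).
#' @param attention_heads Number of attention heads (default 4); must
#'   divide `recurrent_hidden`.
#' @param single_report Use the history-free single-report architecture.
#' @param seed Integer seed for initialization.
#' @return An `aggregator_config` list.
#' @export
aggregator_config <- function(input_dim, projected_dim = 128L,
                              recurrent_hidden = 128L, attention_heads = 4L,
                              single_report = FALSE, seed = 1L) {
  input_dim <- assert_count(input_dim, "input_dim", 1L)
  projected_dim <- assert_count(projected_dim, "projected_dim", 1L)
  recurrent_hidden <- assert_count(recurrent_hidden, "recurrent_hidden", 1L)
  attention_heads <- assert_count(attention_heads, "attention_heads", 1L)
  if (projected_dim > input_dim) {
    abort("`projected_dim` must not exceed `input_dim`.")
  }
  if (recurrent_hidden %% attention_heads != 0L) {
    abort("`attention_heads` must divide `recurrent_hidden`.")
  }
  structure(
    list(input_dim = input_dim, projected_dim = projected_dim,
         recurrent_hidden = recurrent_hidden,
         attention_heads = attention_heads,
         single_report = isTRUE(single_report), seed = as.integer(seed)),
    class = "aggregator_config"
  )
}

#' Initialize aggregator parameters
#'
#' @param config An [aggregator_config()].
#' @return Parameter list of class `metaug_aggregator`.
#' @export
init_aggregator <- function(config) {
  d <- config$input_dim
  p <- config$projected_dim
  h <- config$recurrent_hidden
  with_substream(config$seed, "agg-init", expr = {
    if (config$single_report) {
      params <- list(config = config,
                     Wp = rand_mat(d, p, 0.08), bp = numeric(p),
                     wout = rnorm(p, 0, 0.08), bout = 0)
    } else {
      params <- list(config = config,
                     Wp = rand_mat(d, p, 0.08), bp = numeric(p),
                     Wx = rand_mat(p, 4L * h, 0.08),
                     Wh = rand_mat(h, 4L * h, 0.08), bl = numeric(4L * h),
                     Wq = rand_mat(h, h, 0.08), Wk = rand_mat(h, h, 0.08),
                     Wv = rand_mat(h, h, 0.08), Wo = rand_mat(h, h, 0.08),
                     wout = rnorm(h, 0, 0.08), bout = 0)
    }
    structure(params, class = "metaug_aggregator")
  })
}

#' Causal attention mask
#'
#' @param l Sequence length (>= 1).
#' @return An `l x l` logical matrix: entry `(j, i)` is `TRUE` iff
#'   position `j` may attend to position `i` (`i <= j`).
#' @export
causal_mask <- function(l) {
  l <- assert_count(l, "l", min = 1L)
  outer(seq_len(l), seq_len(l), `>=`)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Forward pass for one patient
#'
#' Computes metastasis probabilities for all report positions in one
#' pass. Causality is guaranteed structurally: the LSTM runs forward in
#' time and the attention scores are masked so position `j` attends only
#' to positions `i <= j`.
#'
#' @param E Numeric matrix (`l x d`) of report embeddings in
#'   chronological order.
#' @param params Parameters from [init_aggregator()].
#' @param keep_cache Keep activations for the backward pass.
#' @return List with `probabilities` (length `l`, in `[0, 1]`), `logits`,
#'   and optionally `cache`.
#' @export
forward_patient <- function(E, params, keep_cache = FALSE) {
  cfg <- params$config
  if (!is.matrix(E) || nrow(E) < 1L) abort("`E` must be a non-empty matrix.")
  if (ncol(E) != cfg$input_dim) abort("Embedding dimension mismatch.")
  l <- nrow(E)
  P <- sweep(E %*% params$Wp, 2, params$bp, "+")
  if (cfg$single_report) {
    logits <- as.numeric(P %*% params$wout + params$bout)
    return(list(probabilities = sigmoid(logits), logits = logits,
                cache = if (keep_cache) list(P = P) else NULL))
  }
  h <- cfg$recurrent_hidden
  nh <- cfg$attention_heads
  dk <- h %/% nh
  # one-directional LSTM, gate order i, f, g, o
  Hs <- matrix(0, l, h)
  Cs <- matrix(0, l, h)
  gates <- matrix(0, l, 4L * h)
  hprev <- numeric(h)
  cprev <- numeric(h)
  for (t in seq_len(l)) {
    a <- as.numeric(P[t, ] %*% params$Wx + hprev %*% params$Wh + params$bl)
    i_g <- sigmoid(a[1:h])
    f_g <- sigmoid(a[(h + 1):(2 * h)])
    g_g <- tanh(a[(2 * h + 1):(3 * h)])
    o_g <- sigmoid(a[(3 * h + 1):(4 * h)])
    cprev <- f_g * cprev + i_g * g_g
    hprev <- o_g * tanh(cprev)
    gates[t, ] <- c(i_g, f_g, g_g, o_g)
    Cs[t, ] <- cprev
    Hs[t, ] <- hprev
  }
  Q <- Hs %*% params$Wq
  K <- Hs %*% params$Wk
  V <- Hs %*% params$Wv
  mask <- causal_mask(l)
  O <- matrix(0, l, h)
  A_heads <- vector("list", nh)
  for (hd in seq_len(nh)) {
    cols <- ((hd - 1L) * dk + 1L):(hd * dk)
    S <- (Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE])) / sqrt(dk)
    S[!mask] <- -Inf
    A <- row_softmax(S)
    A_heads[[hd]] <- A
    O[, cols] <- A %*% V[, cols, drop = FALSE]
  }
  U <- O %*% params$Wo
  logits <- as.numeric(U %*% params$wout + params$bout)
  probs <- sigmoid(logits)
  cache <- if (keep_cache) {
    list(E = E, P = P, Hs = Hs, Cs = Cs, gates = gates, Q = Q, K = K, V = V,
         A_heads = A_heads, O = O, U = U)
  } else NULL
  list(probabilities = probs, logits = logits, cache = cache)
}

# Backward pass for one patient. `dlogits` is dLoss/dlogit per position.
# Returns a gradient list with the same shapes as `params` (minus config).
backward_patient <- function(dlogits, params, cache) {
  cfg <- params$config
  l <- length(dlogits)
  if (cfg$single_report) {
    P <- cache$P
    dwout <- as.numeric(t(P) %*% dlogits)
    dbout <- sum(dlogits)
    dP <- outer(dlogits, params$wout)
    return(list(bp = colSums(dP), wout = dwout, bout = dbout, dP = dP))
  }
  h <- cfg$recurrent_hidden
  nh <- cfg$attention_heads
  dk <- h %/% nh
  dwout <- as.numeric(t(cache$U) %*% dlogits)
  dbout <- sum(dlogits)
  dU <- outer(dlogits, params$wout)
  dWo <- t(cache$O) %*% dU
  dO <- dU %*% t(params$Wo)
  dQ <- matrix(0, l, h)
  dK <- matrix(0, l, h)
  dV <- matrix(0, l, h)
  for (hd in seq_len(nh)) {
    cols <- ((hd - 1L) * dk + 1L):(hd * dk)
    A <- cache$A_heads[[hd]]
    dOh <- dO[, cols, drop = FALSE]
    dA <- dOh %*% t(cache$V[, cols, drop = FALSE])
    dV[, cols] <- dV[, cols, drop = FALSE] + t(A) %*% dOh
    dS <- A * (dA - rowSums(dA * A))  # masked entries have A = 0
    dQ[, cols] <- dQ[, cols, drop = FALSE] +
      dS %*% cache$K[, cols, drop = FALSE] / sqrt(dk)
    dK[, cols] <- dK[, cols, drop = FALSE] +
      t(dS) %*% cache$Q[, cols, drop = FALSE] / sqrt(dk)
  }
  dWq <- t(cache$Hs) %*% dQ
  dWk <- t(cache$Hs) %*% dK
  dWv <- t(cache$Hs) %*% dV
  dH <- dQ %*% t(params$Wq) + dK %*% t(params$Wk) + dV %*% t(params$Wv)
  # LSTM backward through time
  dWx <- matrix(0, cfg$projected_dim, 4L * h)
  dWh <- matrix(0, h, 4L * h)
  dbl <- numeric(4L * h)
  dP <- matrix(0, l, cfg$projected_dim)
  dh_next <- numeric(h)
  dc_next <- numeric(h)
  for (t in rev(seq_len(l))) {
    i_g <- cache$gates[t, 1:h]
    f_g <- cache$gates[t, (h + 1):(2 * h)]
    g_g <- cache$gates[t, (2 * h + 1):(3 * h)]
    o_g <- cache$gates[t, (3 * h + 1):(4 * h)]
    c_t <- cache$Cs[t, ]
    c_prev <- if (t > 1L) cache$Cs[t - 1L, ] else numeric(h)
    tc <- tanh(c_t)
    dh <- dH[t, ] + dh_next
    do_g <- dh * tc
    dc <- dc_next + dh * o_g * (1 - tc^2)
    di <- dc * g_g
    df <- dc * c_prev
    dg <- dc * i_g
    dc_next <- dc * f_g
    da <- c(di * i_g * (1 - i_g), df * f_g * (1 - f_g),
            dg * (1 - g_g^2), do_g * o_g * (1 - o_g))
    dWx <- dWx + outer(cache$P[t, ], da)
    dWh <- dWh + outer(if (t > 1L) cache$Hs[t - 1L, ] else numeric(h), da)
    dbl <- dbl + da
    dP[t, ] <- da %*% t(params$Wx)
    dh_next <- as.numeric(da %*% t(params$Wh))
  }
  list(bp = colSums(dP), Wx = dWx, Wh = dWh, bl = dbl,
       Wq = dWq, Wk = dWk, Wv = dWv, Wo = dWo,
       wout = dwout, bout = dbout, dP = dP)
}

#' Predict per-report probabilities for a corpus
#'
#' Runs the aggregator over each patient's chronological reports.
#'
#' @param model A `metaug_model` from [build_model()].
#' @param corpus Corpus tibble.
#' @param embeddings Optional precomputed embedding matrix (rownames =
#'   report ids); computed on the fly otherwise.
#' @return Tibble with `patient_id`, `report_id`, `position`, `label`,
#'   `probability`.
#' @export
predict_corpus <- function(model, corpus, embeddings = NULL) {
  if (is.null(embeddings)) {
    embeddings <- embed_corpus(corpus, model$encoder$config,
                               model$encoder$params, model$encoder$peft)
  }
  out <- lapply(split_patients(corpus), function(p) {
    E <- embeddings[p$report_id, , drop = FALSE]
    fw <- forward_patient(E, model$aggregator$params)
    tibble::tibble(patient_id = p$patient_id, report_id = p$report_id,
                   position = p$position, label = p$label,
                   probability = fw$probabilities)
  })
  dplyr::bind_rows(out)
}

# ordered per-patient report list
split_patients <- function(corpus) {
  corpus <- corpus[order(corpus$patient_id, corpus$position), ]
  split(corpus, factor(corpus$patient_id, levels = unique(corpus$patient_id)))
}
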