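#' Text-encoder configuration
#'
#' Three encoder kinds share one embedding contract (report text to a
#' fixed `dim`-vector): a trainable-free hashed n-gram encoder, a small
#' in-repo transformer that carries the parameter-efficient fine-tuning
#' contracts, and an external adapter slot for plugging in a pretrained
#' model without changing downstream code.
#'
#' @param kind `"hashed_ngram"`, `"tiny_transformer"`, or
#'   `"external_adapter"`.
#' @param dim Output embedding dimension `d` (default 768, the hidden
#'   size of a BERT-base class encoder).
#' @param layers Transformer blocks (tiny transformer, default 2).
#' @param heads Attention heads (default 4); must divide `width`.
#' @param width Per-layer transformer width (default 64).
#' @param vocab_hash_size Hashing-trick vocabulary size.
#' @param max_tokens Head-truncation length for the tiny transformer.
#' @param input_mode `"impression_only"` or `"findings_plus_impression"`
#'   (findings text concatenated before the impression with a separator
#'   marker).
#' @param seed Integer seed for parameter initialization.
#' @return An `encoder_config` list.
#' @export
encoder_config <- function(kind = c("hashed_ngram", "tiny_transformer",
                                    "external_adapter"),
                           dim = 768L, layers = 2L, heads = 4L, width = 64L,
                           vocab_hash_size = 4096L, max_tokens = 64L,
                           input_mode = c("impression_only",
                                          "findings_plus_impression"),
                           seed = 1L) {
  kind <- match.arg(kind)
  dim <- assert_count(dim, "dim", min = 1L)
  width <- assert_count(width, "width", min = 1L)
  heads <- assert_count(heads, "heads", min = 1L)
  if (kind == "tiny_transformer" && width %% heads != 0L) {
    abort("`heads` must divide `width`.")
  }
  structure(
    list(kind = kind, dim = dim, layers = assert_count(layers, "layers", 1L),
         heads = heads, width = width,
         vocab_hash_size = assert_count(vocab_hash_size, "vocab_hash_size", 2L),
         max_tokens = assert_count(max_tokens, "max_tokens", 1L),
         input_mode = match.arg(input_mode), seed = as.integer(seed)),
    class = "encoder_config"
  )
}

# memoized token hash (the generator vocabulary is small)
.hash_memo <- new.env(parent = emptyenv())
token_hash <- function(token) {
  h <- .hash_memo[[token]]
  if (is.null(h)) {
    h <- fnv1a32(token)
    assign(token, h, envir = .hash_memo)
  }
  h
}

report_text <- function(impression, findings, input_mode) {
  if (input_mode == "findings_plus_impression" && !is.na(findings) &&
      nzchar(findings)) {
    paste(findings, "[SEP]", impression)
  } else {
    impression
  }
}

#' Hashed n-gram embedding
#'
#' Lowercased tokens plus adjacent bigrams are hashed into `dim` buckets
#' (hashing trick, FNV-1a); bucket counts are L2-normalized. The encoder
#' has no trainable parameters and is fully deterministic, which makes it
#' the default embedding backend for tests and desk-scale experiments.
#'
#' @param report One corpus row (or any list with `impression` and
#'   optional `findings`).
#' @param config An `encoder_config` with `kind = "hashed_ngram"`.
#' @return Numeric vector of length `config$dim`.
#' @export
embed_hashed <- function(report, config) {
  stopifnot(config$kind == "hashed_ngram")
  txt <- report_text(report$impression, report$findings %||% NA_character_,
                     config$input_mode)
  embed_text_hashed(txt, config$dim)
}

embed_text_hashed <- function(text, dim) {
  tokens <- tokenize_text(text)
  v <- numeric(dim)
  if (length(tokens) == 0L) return(v)
  grams <- tokens
  if (length(tokens) > 1L) {
    grams <- c(grams, paste(tokens[-length(tokens)], tokens[-1], sep = "_"))
  }
  for (g in grams) {
    b <- (token_hash(g) %% dim) + 1L
    v[b] <- v[b] + 1
  }
  nrm <- sqrt(sum(v^2))
  if (nrm > 0) v <- v / nrm
  v
}

#' Embed every report of a corpus
#'
#' @param corpus Corpus tibble.
#' @param config An `encoder_config`.
#' @param params,peft Tiny-transformer parameters and optional PEFT state
#'   (ignored for the hashed encoder).
#' @return Numeric matrix, one row per report, rownames = `report_id`.
#' @export
embed_corpus <- function(corpus, config, params = NULL, peft = NULL) {
  n <- nrow(corpus)
  E <- matrix(0, n, config$dim)
  for (i in seq_len(n)) {
    txt <- report_text(corpus$impression[i], corpus$findings[i],
                       config$input_mode)
    E[i, ] <- if (config$kind == "hashed_ngram") {
      embed_text_hashed(txt, config$dim)
    } else {
      encode_text_tiny(txt, params, peft)$embedding
    }
  }
  rownames(E) <- corpus$report_id
  E
}

## --- tiny transformer ------------------------------------------------

rand_mat <- function(nr, nc, scale = 0.08) {
  matrix(rnorm(nr * nc, 0, scale), nr, nc)
}

#' Initialize the tiny transformer encoder
#'
#' Token-hash embedding table, learned positions, `layers` blocks of
#' multi-head self-attention and a ReLU feed-forward (both with residual
#' connections; no normalization layers at this depth), mean pooling, and
#' a linear map to the output dimension.
#'
#' @param config An `encoder_config` with `kind = "tiny_transformer"`.
#' @return A parameter list (`params`).
#' @export
init_tiny_transformer <- function(config) {
  stopifnot(config$kind == "tiny_transformer")
  w <- config$width
  ff <- 2L * w
  with_substream(config$seed, "tt-init", expr = {
    layers <- lapply(seq_len(config$layers), function(l) {
      list(Wq = rand_mat(w, w), Wk = rand_mat(w, w), Wv = rand_mat(w, w),
           Wo = rand_mat(w, w),
           W1 = rand_mat(w, ff), b1 = numeric(ff),
           W2 = rand_mat(ff, w), b2 = numeric(w))
    })
    structure(
      list(config = config,
           Emb = rand_mat(config$vocab_hash_size, w),
           Pos = rand_mat(config$max_tokens, w),
           layers = layers,
           Wout = rand_mat(w, config$dim), bout = numeric(config$dim)),
      class = "tiny_transformer"
    )
  })
}

tokens_to_ids <- function(text, config) {
  tokens <- tokenize_text(text)
  if (length(tokens) == 0L) tokens <- "[empty]"
  tokens <- tokens[seq_len(min(length(tokens), config$max_tokens))]
  vapply(tokens, function(t)
    (token_hash(t) %% config$vocab_hash_size) + 1L, integer(1),
    USE.NAMES = FALSE)
}

row_softmax <- function(S) {
  m <- apply(S, 1, max)
  E <- exp(S - m)
  E / rowSums(E)
}

# effective projection including a LoRA update for one target of one layer
lora_eff <- function(W, peft, layer, target) {
  if (is.null(peft) || peft$kind != "lora" ||
      !target %in% peft$spec$target_projections) {
    return(W)
  }
  st <- peft$layers[[layer]][[target]]
  W + peft$spec$scaling * (st$A %*% st$B)
}

#' Tiny-transformer forward pass for one text
#'
#' @param text Input text (already findings-concatenated if desired).
#' @param params Parameters from [init_tiny_transformer()].
#' @param peft Optional PEFT state from [attach_lora()] or
#'   [attach_prefix()].
#' @param keep_cache Keep intermediate activations for the backward pass.
#' @return List with `embedding` (length-`dim` vector) and, when
#'   requested, `cache`.
#' @export
encode_text_tiny <- function(text, params, peft = NULL, keep_cache = FALSE) {
  cfg <- params$config
  ids <- tokens_to_ids(text, cfg)
  Tn <- length(ids)
  w <- cfg$width
  nh <- cfg$heads
  dk <- w %/% nh
  m <- if (!is.null(peft) && peft$kind == "prefix") peft$spec$prompt_length else 0L
  X <- params$Emb[ids, , drop = FALSE] + params$Pos[seq_len(Tn), , drop = FALSE]
  cache <- list(ids = ids, X0 = X, layers = vector("list", cfg$layers))
  for (l in seq_len(cfg$layers)) {
    L <- params$layers[[l]]
    Wq <- lora_eff(L$Wq, peft, l, "query")
    Wv <- lora_eff(L$Wv, peft, l, "value")
    Q <- X %*% Wq
    K <- X %*% L$Wk
    V <- X %*% Wv
    if (m > 0L) {
      Kf <- rbind(peft$layers[[l]]$Pk, K)
      Vf <- rbind(peft$layers[[l]]$Pv, V)
    } else {
      Kf <- K; Vf <- V
    }
    O <- matrix(0, Tn, w)
    A_heads <- vector("list", nh)
    for (h in seq_len(nh)) {
      cols <- ((h - 1L) * dk + 1L):(h * dk)
      S <- (Q[, cols, drop = FALSE] %*% t(Kf[, cols, drop = FALSE])) / sqrt(dk)
      A <- row_softmax(S)
      A_heads[[h]] <- A
      O[, cols] <- A %*% Vf[, cols, drop = FALSE]
    }
    attn_out <- O %*% L$Wo
    X1 <- X + attn_out
    pre <- sweep(X1 %*% L$W1, 2, L$b1, "+")
    Hrelu <- pmax(pre, 0)
    ffo <- sweep(Hrelu %*% L$W2, 2, L$b2, "+")
    X2 <- X1 + ffo
    if (keep_cache) {
      cache$layers[[l]] <- list(Xin = X, Q = Q, K = K, V = V, Kf = Kf, Vf = Vf,
                                A_heads = A_heads, O = O, X1 = X1, pre = pre,
                                Hrelu = Hrelu, Wq_eff = Wq, Wv_eff = Wv)
    }
    X <- X2
  }
  pooled <- colMeans(X)
  emb <- as.numeric(pooled %*% params$Wout + params$bout)
  if (!is.finite(sum(emb))) abort("Non-finite encoder output.")
  cache$Xfinal <- X
  cache$pooled <- pooled
  list(embedding = emb,
       cache = if (keep_cache) cache else NULL)
}

# Backward pass through the tiny transformer for one text.
# `demb` is the gradient of the loss w.r.t. the output embedding.
# Returns gradients for base params, and for LoRA/prefix states if attached.
backward_text_tiny <- function(demb, params, cache, peft = NULL) {
  cfg <- params$config
  w <- cfg$width
  nh <- cfg$heads
  dk <- w %/% nh
  Tn <- length(cache$ids)
  m <- if (!is.null(peft) && peft$kind == "prefix") peft$spec$prompt_length else 0L
  g <- list(
    Emb = NULL, Pos = NULL,
    Wout = outer(cache$pooled, demb),
    bout = demb,
    layers = vector("list", cfg$layers)
  )
  gp <- if (!is.null(peft)) {
    lapply(seq_len(cfg$layers), function(l) {
      if (peft$kind == "lora") {
        lapply(peft$layers[[l]], function(st)
          list(A = st$A * 0, B = st$B * 0))
      } else {
        list(Pk = peft$layers[[l]]$Pk * 0, Pv = peft$layers[[l]]$Pv * 0)
      }
    })
  } else NULL
  dpooled <- as.numeric(params$Wout %*% demb)
  dX <- matrix(rep(dpooled / Tn, each = Tn), Tn, w)
  for (l in rev(seq_len(cfg$layers))) {
    L <- params$layers[[l]]
    cc <- cache$layers[[l]]
    # feed-forward block (X2 = X1 + relu(X1 W1 + b1) W2 + b2)
    dffo <- dX
    dW2 <- t(cc$Hrelu) %*% dffo
    db2 <- colSums(dffo)
    dH <- dffo %*% t(L$W2)
    dpre <- dH * (cc$pre > 0)
    dW1 <- t(cc$X1) %*% dpre
    db1 <- colSums(dpre)
    dX1 <- dX + dpre %*% t(L$W1)
    # attention block (X1 = Xin + (concat_h A_h Vf_h) Wo)
    dattn <- dX1
    dWo <- t(cc$O) %*% dattn
    dO <- dattn %*% t(L$Wo)
    dQ <- matrix(0, Tn, w)
    dKf <- matrix(0, m + Tn, w)
    dVf <- matrix(0, m + Tn, w)
    for (h in seq_len(nh)) {
      cols <- ((h - 1L) * dk + 1L):(h * dk)
      A <- cc$A_heads[[h]]
      dOh <- dO[, cols, drop = FALSE]
      Vh <- cc$Vf[, cols, drop = FALSE]
      dA <- dOh %*% t(Vh)
      dVf[, cols] <- dVf[, cols, drop = FALSE] + t(A) %*% dOh
      dS <- A * (dA - rowSums(dA * A))
      dQ[, cols] <- dQ[, cols, drop = FALSE] +
        dS %*% cc$Kf[, cols, drop = FALSE] / sqrt(dk)
      dKf[, cols] <- dKf[, cols, drop = FALSE] +
        t(dS) %*% cc$Q[, cols, drop = FALSE] / sqrt(dk)
    }
    tok <- (m + 1L):(m + Tn)
    dK <- dKf[tok, , drop = FALSE]
    dV <- dVf[tok, , drop = FALSE]
    if (m > 0L) {
      gp[[l]]$Pk <- dKf[seq_len(m), , drop = FALSE]
      gp[[l]]$Pv <- dVf[seq_len(m), , drop = FALSE]
    }
    dXin <- dX1 +
      dQ %*% t(cc$Wq_eff) + dK %*% t(L$Wk) + dV %*% t(cc$Wv_eff)
    gl <- list(
      Wq = t(cc$Xin) %*% dQ, Wk = t(cc$Xin) %*% dK, Wv = t(cc$Xin) %*% dV,
      Wo = dWo, W1 = dW1, b1 = db1, W2 = dW2, b2 = db2
    )
    if (!is.null(peft) && peft$kind == "lora") {
      s <- peft$spec$scaling
      if ("query" %in% peft$spec$target_projections) {
        st <- peft$layers[[l]]$query
        gp[[l]]$query$A <- s * (t(cc$Xin) %*% dQ) %*% t(st$B)
        gp[[l]]$query$B <- s * t(cc$Xin %*% st$A) %*% dQ
      }
      if ("value" %in% peft$spec$target_projections) {
        st <- peft$layers[[l]]$value
        gp[[l]]$value$A <- s * (t(cc$Xin) %*% dV) %*% t(st$B)
        gp[[l]]$value$B <- s * t(cc$Xin %*% st$A) %*% dV
      }
    }
    g$layers[[l]] <- gl
    dX <- dXin
  }
  # embedding / positional gradients (duplicate ids accumulate)
  dEmb <- matrix(0, nrow(params$Emb), w)
  for (t in seq_len(Tn)) {
    dEmb[cache$ids[t], ] <- dEmb[cache$ids[t], ] + dX[t, ]
  }
  dPos <- matrix(0, nrow(params$Pos), w)
  dPos[seq_len(Tn), ] <- dX
  g$Emb <- dEmb
  g$Pos <- dPos
  list(base = g, peft = gp)
}

## --- PEFT: LoRA ------------------------------------------------------

#' LoRA specification
#'
#' @param rank Low-rank update rank `r` (>= 1).
#' @param scaling Multiplier applied to the low-rank update.
#' @param target_projections Subset of `c("query", "value")`.
#' @return A `lora_spec` list.
#' @export
lora_spec <- function(rank, scaling = 1,
                      target_projections = c("query", "value")) {
  rank <- assert_count(rank, "rank", min = 1L)
  target_projections <- match.arg(target_projections,
                                  c("query", "value"), several.ok = TRUE)
  structure(list(rank = rank, scaling = scaling,
                 target_projections = target_projections),
            class = "lora_spec")
}

#' Attach LoRA adapters to the tiny transformer
#'
#' For each targeted projection `W` (query and/or value, per layer) a
#' low-rank additive update `scaling * A B` is created with `A` randomly
#' initialized and `B` zero-initialized, so the adapted encoder is
#' bit-identical to the base encoder at attachment time. Base weights are
#' frozen: only `A` and `B` receive gradient updates.
#'
#' @param params Tiny-transformer parameters.
#' @param spec A [lora_spec()].
#' @param seed Integer seed for the `A` initialization.
#' @return A `peft_state` list of kind `"lora"`.
#' @export
attach_lora <- function(params, spec, seed = 1L) {
  w <- params$config$width
  if (spec$rank > w) abort("LoRA rank exceeds the layer width.")
  layers <- with_substream(seed, "lora-init", expr = {
    lapply(seq_len(params$config$layers), function(l) {
      st <- list()
      for (tg in spec$target_projections) {
        st[[tg]] <- list(A = rand_mat(w, spec$rank, 0.05),
                         B = matrix(0, spec$rank, w))
      }
      st
    })
  })
  structure(list(kind = "lora", spec = spec, layers = layers),
            class = "peft_state")
}

#' Merge LoRA updates into the base weights
#'
#' Produces parameters with `W' = W + scaling * A B` for every targeted
#' projection; the merged encoder reproduces the adapted encoder's
#' outputs. Merging twice is a state error.
#'
#' @param params Tiny-transformer parameters (unmerged).
#' @param peft A LoRA `peft_state`.
#' @return Merged parameters.
#' @export
merge_lora <- function(params, peft) {
  stopifnot(peft$kind == "lora")
  if (isTRUE(attr(params, "lora_merged"))) {
    abort("LoRA updates have already been merged into these parameters.")
  }
  for (l in seq_len(params$config$layers)) {
    for (tg in peft$spec$target_projections) {
      st <- peft$layers[[l]][[tg]]
      slot <- if (tg == "query") "Wq" else "Wv"
      params$layers[[l]][[slot]] <- params$layers[[l]][[slot]] +
        peft$spec$scaling * (st$A %*% st$B)
    }
  }
  attr(params, "lora_merged") <- TRUE
  params
}

## --- PEFT: deep prefix-tuning ----------------------------------------

#' Deep prefix-tuning specification
#'
#' @param prompt_length Number of trainable key/value prompt tokens
#'   prepended in every attention layer (>= 1).
#' @param init_token_ids Optional vocabulary ids whose embeddings
#'   initialize the prompt (recycled to `prompt_length`); otherwise small
#'   random initialization.
#' @return A `prefix_spec` list.
#' @export
prefix_spec <- function(prompt_length, init_token_ids = NULL) {
  structure(list(prompt_length = assert_count(prompt_length, "prompt_length", 1L),
                 init_token_ids = init_token_ids),
            class = "prefix_spec")
}

#' Attach deep prefix-tuning state
#'
#' Every attention layer receives `prompt_length` trainable key and value
#' rows (P-tuning v2 style); the base weights are frozen. Trainable value
#' count is `layers * prompt_length * 2 * width`.
#'
#' @param params Tiny-transformer parameters.
#' @param spec A [prefix_spec()].
#' @param seed Integer seed.
#' @return A `peft_state` list of kind `"prefix"`.
#' @export
attach_prefix <- function(params, spec, seed = 1L) {
  w <- params$config$width
  mlen <- spec$prompt_length
  init_rows <- function() {
    if (!is.null(spec$init_token_ids)) {
      ids <- rep_len(spec$init_token_ids, mlen)
      params$Emb[ids, , drop = FALSE]
    } else {
      rand_mat(mlen, w, 0.05)
    }
  }
  layers <- with_substream(seed, "prefix-init", expr = {
    lapply(seq_len(params$config$layers), function(l) {
      list(Pk = init_rows(), Pv = init_rows())
    })
  })
  structure(list(kind = "prefix", spec = spec, layers = layers),
            class = "peft_state")
}

#' Count trainable parameters of a PEFT state
#'
#' @param params Tiny-transformer parameters.
#' @param peft A `peft_state`.
#' @return Integer count of trainable values.
#' @export
peft_trainable_count <- function(params, peft) {
  w <- params$config$width
  L <- params$config$layers
  if (peft$kind == "lora") {
    length(peft$spec$target_projections) * L * peft$spec$rank * (w + w)
  } else {
    L * peft$spec$prompt_length * 2L * w
  }
}

#' Count all base parameters of the tiny transformer
#'
#' @param params Tiny-transformer parameters.
#' @return Integer count.
#' @export
encoder_parameter_count <- function(params) {
  n <- length(params$Emb) + length(params$Pos) +
    length(params$Wout) + length(params$bout)
  for (L in params$layers) n <- n + sum(vapply(L, length, integer(1)))
  as.integer(n)
}
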