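test_that("hashed embedding is deterministic and input-mode aware", {
  cfg <- encoder_config(kind = "hashed_ngram", dim = 64)
  r1 <- list(impression = "stable 6 mm nodule", findings = NA_character_)
  expect_identical(embed_hashed(r1, cfg), embed_hashed(r1, cfg))

  cfg2 <- encoder_config(kind = "hashed_ngram", dim = 64,
                         input_mode = "findings_plus_impression")
  expect_identical(embed_hashed(r1, cfg2), embed_hashed(r1, cfg))
  r2 <- list(impression = "stable 6 mm nodule", findings = "liver subsection")
  expect_false(identical(embed_hashed(r2, cfg2), embed_hashed(r2, cfg)))
})

test_that("hashed embedding matches hand-computed bucket pattern", {
  d <- 32L
  v <- metaug:::embed_text_hashed("left adrenal nodule", d)
  grams <- c("left", "adrenal", "nodule", "left_adrenal", "adrenal_nodule")
  expected <- numeric(d)
  for (g in grams) {
    b <- (oracle_fnv1a(g) %% d) + 1L
    expected[b] <- expected[b] + 1
  }
  expected <- expected / sqrt(sum(expected^2))
  expect_equal(v, expected, tolerance = 1e-12)
  expect_equal(sqrt(sum(v^2)), 1, tolerance = 1e-12)
})

tiny_cfg <- function(...) {
  encoder_config(kind = "tiny_transformer", dim = 12, layers = 2, heads = 2,
                 width = 16, vocab_hash_size = 128, max_tokens = 12,
                 seed = 4, ...)
}

test_that("tiny transformer is deterministic, position-aware, and truncates", {
  ep <- init_tiny_transformer(tiny_cfg())
  t1 <- "no suspicious hepatic lesions identified today"
  expect_identical(encode_text_tiny(t1, ep)$embedding,
                   encode_text_tiny(t1, ep)$embedding)
  # swapping two different tokens changes the embedding
  t2 <- "suspicious no hepatic lesions identified today"
  expect_false(identical(encode_text_tiny(t1, ep)$embedding,
                         encode_text_tiny(t2, ep)$embedding))
  # texts identical in the first max_tokens tokens encode identically
  base <- paste(rep("alpha beta gamma delta", 3), collapse = " ")
  expect_identical(
    encode_text_tiny(paste(base, "tail one"), ep)$embedding,
    encode_text_tiny(paste(base, "different ending"), ep)$embedding)
})

test_that("analytic gradients match finite differences (all regimes)", {
  ep <- init_tiny_transformer(tiny_cfg())
  txt <- "stable 6 mm nodule in the right lower lobe"
  tgt <- withr::with_seed(1, rnorm(12))
  loss <- function(params, peft = NULL) {
    e <- encode_text_tiny(txt, params, peft)$embedding
    sum((e - tgt)^2) / 2
  }
  fd <- function(get, set, analytic, params, peft = NULL, n_probe = 25) {
    eps <- 1e-6
    idx <- withr::with_seed(2, sample(length(analytic),
                                      min(n_probe, length(analytic))))
    worst <- 0
    for (i in idx) {
      p1 <- set(params, peft, i, eps)
      p0 <- set(params, peft, i, -eps)
      num <- (loss(p1$params, p1$peft) - loss(p0$params, p0$peft)) / (2 * eps)
      worst <- max(worst, abs(num - analytic[i]))
    }
    worst
  }
  r <- encode_text_tiny(txt, ep, keep_cache = TRUE)
  bw <- metaug:::backward_text_tiny(r$embedding - tgt, ep, r$cache)
  # base parameters (full fine-tuning path)
  for (nm in c("Emb", "Pos", "Wout", "bout")) {
    worst <- fd(NULL, function(p, pf, i, e) {
      p[[nm]][i] <- p[[nm]][i] + e; list(params = p, peft = pf)
    }, bw$base[[nm]], ep)
    expect_lt(worst, 1e-6)
  }
  for (nm in c("Wq", "Wk", "Wv", "Wo", "W1", "W2")) {
    worst <- fd(NULL, function(p, pf, i, e) {
      p$layers[[2]][[nm]][i] <- p$layers[[2]][[nm]][i] + e
      list(params = p, peft = pf)
    }, bw$base$layers[[2]][[nm]], ep)
    expect_lt(worst, 1e-6)
  }
  # LoRA path (B randomized so gradients flow through both factors)
  pl <- attach_lora(ep, lora_spec(rank = 2, scaling = 0.5), seed = 7)
  pl$layers <- withr::with_seed(3, lapply(pl$layers, function(L) {
    lapply(L, function(st) { st$B[] <- rnorm(length(st$B), 0, 0.1); st })
  }))
  r <- encode_text_tiny(txt, ep, pl, keep_cache = TRUE)
  bw <- metaug:::backward_text_tiny(r$embedding - tgt, ep, r$cache, pl)
  for (tg in c("query", "value")) for (mm in c("A", "B")) {
    worst <- fd(NULL, function(p, pf, i, e) {
      pf$layers[[1]][[tg]][[mm]][i] <- pf$layers[[1]][[tg]][[mm]][i] + e
      list(params = p, peft = pf)
    }, bw$peft[[1]][[tg]][[mm]], ep, pl)
    expect_lt(worst, 1e-6)
  }
  # prefix path
  pp <- attach_prefix(ep, prefix_spec(prompt_length = 3), seed = 5)
  r <- encode_text_tiny(txt, ep, pp, keep_cache = TRUE)
  bw <- metaug:::backward_text_tiny(r$embedding - tgt, ep, r$cache, pp)
  for (mm in c("Pk", "Pv")) {
    worst <- fd(NULL, function(p, pf, i, e) {
      pf$layers[[2]][[mm]][i] <- pf$layers[[2]][[mm]][i] + e
      list(params = p, peft = pf)
    }, bw$peft[[2]][[mm]], ep, pp)
    expect_lt(worst, 1e-6)
  }
})

test_that("LoRA attaches as an exact identity and merges equivalently", {
  ep <- init_tiny_transformer(tiny_cfg())
  texts <- generate_corpus(generator_config(10, seed = 12))$impression
  for (seed in 1:5) {
    pl <- attach_lora(ep, lora_spec(rank = 4), seed = seed)
    expect_identical(encode_text_tiny(texts[1], ep)$embedding,
                     encode_text_tiny(texts[1], ep, pl)$embedding)
  }
  # merge at init is exact
  pl <- attach_lora(ep, lora_spec(rank = 4), seed = 1)
  merged0 <- merge_lora(ep, pl)
  expect_equal(merged0$layers, ep$layers)
  # randomized B: merged output equals adapted output within 1e-5
  pl$layers <- withr::with_seed(11, lapply(pl$layers, function(L) {
    lapply(L, function(st) { st$B[] <- rnorm(length(st$B), 0, 0.2); st })
  }))
  merged <- merge_lora(ep, pl)
  for (txt in texts) {
    a <- encode_text_tiny(txt, ep, pl)$embedding
    b <- encode_text_tiny(txt, merged)$embedding
    expect_lt(max(abs(a - b)) / max(1, max(abs(a))), 1e-5)
  }
  expect_error(merge_lora(merged, pl), "already been merged")
  expect_error(attach_lora(ep, lora_spec(rank = 99)), "rank exceeds")
})

test_that("PEFT trainable counts match the closed-form formulas", {
  cfg <- encoder_config(kind = "tiny_transformer", dim = 16, layers = 2,
                        heads = 2, width = 64, vocab_hash_size = 256,
                        seed = 1)
  ep <- init_tiny_transformer(cfg)
  # LoRA: targets x layers x r x (in + out) = 2 * 2 * 4 * 128 = 2048
  pl <- attach_lora(ep, lora_spec(rank = 4), seed = 1)
  expect_equal(peft_trainable_count(ep, pl), 2048L)
  # and equals the number of values in the A/B factors themselves
  expect_equal(sum(vapply(pl$layers, function(L)
    sum(vapply(L, function(st) length(st$A) + length(st$B), integer(1))),
    integer(1))), 2048L)
  # prefix: layers * prompt_length * 2 * width = 2 * 8 * 2 * 64
  pp <- attach_prefix(ep, prefix_spec(prompt_length = 8), seed = 1)
  expect_equal(peft_trainable_count(ep, pp), 2048L)
})

test_that("PEFT trainable fraction stays under 5% at default size", {
  cfg <- encoder_config(kind = "tiny_transformer")
  ep <- init_tiny_transformer(cfg)
  total <- encoder_parameter_count(ep)
  pl <- attach_lora(ep, lora_spec(rank = 4), seed = 1)
  pp <- attach_prefix(ep, prefix_spec(prompt_length = 8), seed = 1)
  expect_lt(peft_trainable_count(ep, pl) / total, 0.05)
  expect_lt(peft_trainable_count(ep, pp) / total, 0.05)
})

test_that("zero-value prefixes only renormalize attention", {
  # With prefix value rows set to zero, each attention output over real
  # tokens equals the no-prefix output scaled by the probability mass the
  # softmax assigns to real tokens — verified against a brute-force
  # attention computation.
  cfg <- tiny_cfg()
  cfg$layers <- 1L
  ep <- init_tiny_transformer(cfg)
  pp <- attach_prefix(ep, prefix_spec(prompt_length = 2), seed = 3)
  pp$layers[[1]]$Pv[] <- 0
  txt <- "adrenal glands are unremarkable"
  ids <- metaug:::tokens_to_ids(txt, cfg)
  X <- ep$Emb[ids, , drop = FALSE] + ep$Pos[seq_along(ids), , drop = FALSE]
  w <- cfg$width; nh <- cfg$heads; dk <- w / nh
  L <- ep$layers[[1]]
  Q <- X %*% L$Wq; K <- X %*% L$Wk; V <- X %*% L$Wv
  Kf <- rbind(pp$layers[[1]]$Pk, K)
  r <- encode_text_tiny(txt, ep, pp, keep_cache = TRUE)
  r0 <- encode_text_tiny(txt, ep, keep_cache = TRUE)
  for (h in seq_len(nh)) {
    cols <- ((h - 1) * dk + 1):(h * dk)
    for (j in seq_along(ids)) {
      # brute force: softmax over prefix + real keys, zero prefix values
      scores <- as.numeric(Q[j, cols] %*% t(Kf[, cols])) / sqrt(dk)
      probs <- exp(scores - max(scores)); probs <- probs / sum(probs)
      real_mass <- probs[-(1:2)]
      expected <- as.numeric(real_mass %*% V[, cols])
      got <- (r$cache$layers[[1]]$A_heads[[h]] %*%
                r$cache$layers[[1]]$Vf[, cols])[j, ]
      expect_equal(as.numeric(got), expected, tolerance = 1e-10)
      # equals the no-prefix output rescaled by the real-token mass
      base <- (r0$cache$layers[[1]]$A_heads[[h]] %*%
                 r0$cache$layers[[1]]$Vf[, cols])[j, ]
      expect_equal(as.numeric(got), as.numeric(base) * sum(real_mass),
                   tolerance = 1e-10)
    }
  }
})
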