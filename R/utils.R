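#' @importFrom rlang abort warn .data
#' @importFrom stats rnorm runif rpois rexp rbinom sd setNames
#' @importFrom utils head tail
NULL

# FNV-1a 32-bit hash over UTF-8 bytes, folded into [0, 2^31 - 1].
# Used to derive substream seeds from (seed, key...) so that every random
# decision is a pure function of the user-visible seed and a stable key,
# independent of call order.
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(enc2utf8(x)))
  h <- 2166136261
  for (b in bytes) {
    # xor touches only the low byte (b < 256)
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, b)
    # 32-bit modular multiply by the FNV prime 16777619; 16-bit split
    # keeps every intermediate product exactly representable in doubles
    h <- ((h %/% 65536 * 16777619) %% 65536 * 65536 +
            h %% 65536 * 16777619) %% 4294967296
  }
  as.integer(h %% 2147483647)
}

# Deterministic substream seed from a base seed and arbitrary key parts.
derive_seed <- function(seed, ...) {
  key <- paste(c(format(seed), vapply(list(...), format, character(1))),
               collapse = "")
  fnv1a32(key)
}

# Run `expr` under a derived seed without disturbing the caller's RNG.
with_substream <- function(seed, ..., expr) {
  withr::with_seed(derive_seed(seed, ...), expr)
}

# Whitespace tokenization after trimming; the word-count rule used by the
# length filter ("minimum of 20 words" = at least 20 whitespace tokens).
count_words <- function(x) {
  x <- trimws(x)
  ifelse(nchar(x) == 0L, 0L,
         lengths(strsplit(x, "\\s+")))
}

# BLEU / embedding tokenization: lowercase, punctuation split off as
# separate tokens, whitespace collapsed. Fixed for reproducibility.
tokenize_text <- function(x) {
  x <- tolower(x)
  x <- gsub("([[:punct:]])", " \\1 ", x)
  x <- trimws(gsub("\\s+", " ", x))
  if (nchar(x) == 0L) return(character(0))
  strsplit(x, " ", fixed = TRUE)[[1]]
}

# Largest-remainder apportionment of `n` units over `fractions`.
# Ties in remainders are broken by position order (first gets the unit).
largest_remainder <- function(n, fractions) {
  quota <- n * fractions
  base <- floor(quota)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(-(quota - base), seq_along(fractions))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single probability in [0, 1].", name))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}
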