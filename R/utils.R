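# Internal helpers shared across stages.

# Deterministic child seeds: one parent seed fans out to per-task streams
# without correlated overlap. Kept below 2^31-1.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483647L)
}

# Evaluate `expr` under a local RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Sample skewness (biased, moment definition); used only for ICA sign fixing.
skewness <- function(x) {
  x <- x - mean(x)
  s <- sqrt(mean(x^2))
  if (s == 0) return(0)
  mean(x^3) / s^3
}

# Row-wise z-scoring of a matrix; zero-variance rows become all-zero and are
# reported in the "constant_rows" attribute.
zscore_rows <- function(m, tol = 1e-12) {
  mu <- rowMeans(m)
  centred <- m - mu
  s <- sqrt(rowSums(centred^2) / (ncol(m) - 1))
  const <- which(s < tol)
  s[s < tol] <- 1
  out <- centred / s
  out[const, ] <- 0
  attr(out, "constant_rows") <- const
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
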