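# Independent reference implementations used as oracles. These stay naive
# (double loops, direct transcription of the defining formulas) on purpose.

# Correlation integral by naive enumeration of all unordered pairs.
naive_correlation_integral <- function(vectors, r) {
  n <- nrow(vectors)
  hits <- 0L
  tot <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt(sum((vectors[i, ] - vectors[j, ])^2))
      if (d < r) hits <- hits + 1L     # strict: H(0) = 0
      tot <- tot + 1L
    }
  }
  hits / tot
}

# Higuchi mean curve length by direct transcription of the definitions.
naive_higuchi_L <- function(y, kmax) {
  N <- length(y)
  vapply(seq_len(kmax), function(k) {
    Lm <- vapply(seq_len(k), function(m) {
      n <- (N - m) %/% k
      s <- sum(abs(y[m + (1:n) * k] - y[m + ((1:n) - 1) * k]))
      (1 / k) * ((N - 1) / (n * k)) * s
    }, numeric(1))
    sum(Lm) / k
  }, numeric(1))
}

# Exact fGn autocovariance at lag k for Hurst H (unit-variance increments).
fgn_autocov <- function(k, H) {
  0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
}

# An EEG-like test signal: unit-variance fBm plus a little white noise.
surrogate_epoch <- function(N = 1500, H = 0.6, noise = 0.02, seed = 1) {
  b <- gen_fbm(N, H, seed = seed)
  b <- (b - mean(b)) / sd(b)
  withr::with_seed(seed + 10000L, b + noise * rnorm(N))
}
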