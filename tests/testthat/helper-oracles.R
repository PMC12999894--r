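# Brute-force oracles, written directly from the defining formulas and
# independent of the package's implementations.

# Naive O(N^2) ApEn/SampEn with Chebyshev distance and absolute radius r.
# Returns the template-match counts alongside the entropies so tests can
# assert count-level equivalence.
naiveApEnSampEn <- function(x, m, r) {
  N <- length(x)
  nm <- N - m + 1
  nm1 <- N - m
  emb <- function(len, i) x[i:(i + len - 1)]
  cheb <- function(a, b) max(abs(a - b))
  cm <- integer(nm)
  for (i in seq_len(nm)) {
    for (j in seq_len(nm)) {
      if (cheb(emb(m, i), emb(m, j)) <= r) cm[i] <- cm[i] + 1L
    }
  }
  cm1 <- integer(nm1)
  for (i in seq_len(nm1)) {
    for (j in seq_len(nm1)) {
      if (cheb(emb(m + 1, i), emb(m + 1, j)) <= r) cm1[i] <- cm1[i] + 1L
    }
  }
  A <- 0L
  B <- 0L
  for (i in seq_len(nm1 - 1)) {
    for (j in (i + 1):nm1) {
      if (cheb(emb(m, i), emb(m, j)) <= r) B <- B + 1L
      if (cheb(emb(m + 1, i), emb(m + 1, j)) <= r) A <- A + 1L
    }
  }
  list(apen = mean(log(cm / nm)) - mean(log(cm1 / nm1)),
       cm = cm, cm1 = cm1, A = A, B = B,
       sampen = if (A > 0 && B > 0) -log(A / B) else NA_real_)
}

# plain periodogram band power (independent of the package's Welch code)
fftBandPower <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- Mod(fft(x))^2 / n^2
  f <- (seq_len(n) - 1) * fs / n
  half <- f <= fs / 2
  2 * sum(p[half & f >= lo & f <= hi])
}

# locations of the largest well-separated spectral peaks, in Hz
fftPeaks <- function(x, fs, npeaks) {
  n <- length(x)
  p <- Mod(fft(x))^2
  half <- seq_len(floor(n / 2))
  f <- (half - 1) * fs / n
  ord <- order(p[half], decreasing = TRUE)
  peaks <- c()
  for (i in ord) {
    if (all(abs(f[i] - peaks) > 2)) peaks <- c(peaks, f[i])
    if (length(peaks) == npeaks) break
  }
  sort(peaks)
}
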