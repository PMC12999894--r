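#' @include AllClasses.R
NULL

#' Entropy and fractal feature parameters
#'
#' Defaults follow common EEG practice: embedding dimension `m = 2` and
#' tolerance `r` = 0.2 (as a fraction of the signal SD) for approximate and
#' sample entropy; Tsallis order `q = 2` with a 64-bin amplitude histogram;
#' Higuchi maximum delay `kmax = 10`.
#'
#' @param m embedding dimension.
#' @param r tolerance, fraction of the signal standard deviation.
#' @param q Tsallis order (q > 0, q != 1).
#' @param n_bins histogram bins for the Tsallis probability estimate.
#' @param kmax Higuchi maximum delay.
#' @return a validated list of class `EntropyParams`.
#' @export
entropyParams <- function(m = 2L, r = 0.2, q = 2, n_bins = 64L, kmax = 10L) {
  if (m < 1) stop("config error: m must be >= 1")
  if (r <= 0) stop("config error: r must be > 0")
  if (q <= 0 || q == 1) stop("config error: q must be > 0 and != 1")
  if (n_bins < 2) stop("config error: n_bins must be >= 2")
  if (kmax < 2) stop("config error: kmax must be >= 2")
  structure(list(m = as.integer(m), r = r, q = q,
                 n_bins = as.integer(n_bins), kmax = as.integer(kmax)),
            class = "EntropyParams")
}

FEATURE_ORDER <- c("psd", "skew", "kurt", "de", "apen", "sampen",
                   "tsallis", "hfd")

# undefined-feature sentinel: value 0 plus a classed warning so callers can
# count occurrences
sentinel0 <- function(what) {
  warning(warningCondition(
    paste0("undefined ", what, "; returning sentinel 0"),
    class = "vmdEEG_sentinel"))
  0
}

#' Welch power spectral density estimate
#'
#' Hann window, segment length `min(256, length(x))`, 50% overlap, density
#' scaling (power per Hz); one-sided spectrum.
#'
#' @param x numeric vector.
#' @param fs sampling rate, Hz.
#' @param nperseg segment length.
#' @return list with `freq` (Hz) and `psd` (power/Hz).
#' @export
welchPSD <- function(x, fs, nperseg = min(256L, length(x))) {
  n <- length(x)
  nperseg <- min(nperseg, n)
  step <- max(1L, floor(nperseg / 2))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  win <- 0.5 * (1 - cos(2 * pi * seq_len(nperseg) / nperseg))  # periodic Hann
  U <- sum(win^2)
  nf <- floor(nperseg / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    X <- fft(win * seg)[seq_len(nf)]
    p <- (Mod(X)^2) / (fs * U)
    # one-sided: double everything except DC (and Nyquist when nperseg even)
    dbl <- rep(2, nf)
    dbl[1] <- 1
    if (nperseg %% 2 == 0) dbl[nf] <- 1
    acc <- acc + p * dbl
  }
  list(freq = (seq_len(nf) - 1L) * fs / nperseg, psd = acc / length(starts))
}

#' Mean power spectral density in the 0.5-45 Hz band
#'
#' Mean over frequency bins of the Welch estimate restricted to the EEG
#' band of interest.
#'
#' @param x numeric vector, length >= 64.
#' @param fs sampling rate, Hz.
#' @param band length-2 band limits, Hz.
#' @return mean PSD in power per Hz (microvolt^2/Hz for microvolt input).
#' @export
meanPSD <- function(x, fs, band = c(0.5, 45)) {
  if (length(x) < 64) stop("meanPSD requires at least 64 samples")
  w <- welchPSD(x, fs)
  keep <- w$freq >= band[1] & w$freq <= band[2]
  if (!any(keep)) return(0)
  mean(w$psd[keep])
}

#' Sample skewness and kurtosis
#'
#' Standardized third and fourth central moments. Kurtosis is the Pearson
#' (non-excess) form: a normal distribution gives 3.
#'
#' @param x numeric vector, length >= 3.
#' @return dimensionless scalar; sentinel 0 (with warning) for
#'   zero-variance input.
#' @export
sampleSkewness <- function(x) {
  if (length(x) < 3) stop("skewness requires at least 3 samples")
  if (var(x) == 0) return(sentinel0("skewness of constant signal"))
  e1071::skewness(x, type = 1)
}

#' @rdname sampleSkewness
#' @export
sampleKurtosis <- function(x) {
  if (length(x) < 3) stop("kurtosis requires at least 3 samples")
  if (var(x) == 0) return(sentinel0("kurtosis of constant signal"))
  e1071::kurtosis(x, type = 1) + 3
}

#' Differential entropy (Gaussian closed form)
#'
#' `H = 0.5 * ln(2 * pi * e * var(x))` in nats, with the unbiased sample
#' variance. Exact for Gaussian signals; used as a band-power-like feature
#' for near-Gaussian EEG modes.
#'
#' @param x numeric vector, length >= 2.
#' @return entropy in nats; sentinel 0 for zero variance.
#' @export
diffEntropy <- function(x) {
  if (length(x) < 2) stop("differential entropy requires >= 2 samples")
  v <- var(x)
  if (v <= 0) return(sentinel0("differential entropy of constant signal"))
  0.5 * log(2 * pi * exp(1) * v)
}

#' Approximate entropy
#'
#' `ApEn(m, r, N) = Phi_m(r) - Phi_{m+1}(r)` with
#' `Phi_m = mean_i log(C_i^m)`, where `C_i^m` is the fraction of m-length
#' templates within Chebyshev distance `r*sd(x)` of template i
#' (self-match included). A constant signal gives 0 by construction.
#'
#' @param x numeric vector, length >= m + 2.
#' @param p an [entropyParams()].
#' @return dimensionless regularity statistic.
#' @export
approxEntropy <- function(x, p = entropyParams()) {
  if (length(x) < p$m + 2) stop("approxEntropy requires length >= m + 2")
  r <- p$r * sd(x)
  .apen_sampen(as.numeric(x), p$m, r)$apen
}

#' Sample entropy
#'
#' `SampEn = -ln(A / B)` where `B` counts template pairs (i != j) matching
#' at length m within radius `r*sd(x)` and `A` the same at length m + 1;
#' self-matches are excluded. Undefined (`A = 0` or `B = 0`) inputs yield
#' sentinel 0 with a warning.
#'
#' @inheritParams approxEntropy
#' @return dimensionless regularity statistic.
#' @export
sampleEntropy <- function(x, p = entropyParams()) {
  if (length(x) < p$m + 2) stop("sampleEntropy requires length >= m + 2")
  r <- p$r * sd(x)
  cnt <- .apen_sampen(as.numeric(x), p$m, r)
  if (cnt$B == 0 || cnt$A == 0)
    return(sentinel0("sample entropy (no template matches)"))
  -log(cnt$A / cnt$B)
}

#' Tsallis entropy of the amplitude histogram
#'
#' `S_q = (1 - sum(p_i^q)) / (q - 1)` with `p_i` from an equal-width
#' amplitude histogram over `[min(x), max(x)]`. A constant signal occupies
#' one bin and gives 0.
#'
#' @inheritParams approxEntropy
#' @return dimensionless complexity measure.
#' @export
tsallisEntropy <- function(x, p = entropyParams()) {
  if (length(x) < p$n_bins)
    stop("tsallisEntropy requires length >= n_bins")
  if (min(x) == max(x)) return(0)
  breaks <- seq(min(x), max(x), length.out = p$n_bins + 1L)
  cnt <- tabulate(.bincode(x, breaks, include.lowest = TRUE),
                  nbins = p$n_bins)
  pr <- cnt / sum(cnt)
  (1 - sum(pr^p$q)) / (p$q - 1)
}

#' Higuchi fractal dimension
#'
#' Standard Higuchi construction: mean normalized curve length `L(k)` over
#' delays `k = 1..kmax`, and the fractal dimension is minus the slope of
#' the least-squares fit of `log L(k)` on `log k`. A smooth line gives ~1,
#' white noise ~2.
#'
#' @inheritParams approxEntropy
#' @return dimensionless fractal dimension estimate.
#' @export
higuchiFD <- function(x, p = entropyParams()) {
  N <- length(x)
  kmax <- p$kmax
  if (N < 10 * kmax) stop("higuchiFD requires length >= 10 * kmax")
  Lk <- vapply(seq_len(kmax), function(k) {
    La <- vapply(seq_len(k), function(a) {
      idx <- seq(a, N, by = k)
      ni <- length(idx) - 1L
      if (ni < 1L) return(NA_real_)
      sum(abs(diff(x[idx]))) * (N - 1) / (ni * k) / k
    }, 0)
    mean(La, na.rm = TRUE)
  }, 0)
  if (any(Lk <= 0)) return(sentinel0("Higuchi FD of degenerate signal"))
  -unname(coef(lm(log(Lk) ~ log(seq_len(kmax))))[2])
}

#' Extract the eight-feature battery from decomposed modes
#'
#' Computes, for every channel and every IMF, the fixed feature battery
#' (mean PSD, skewness, kurtosis, differential entropy, approximate
#' entropy, sample entropy, Tsallis entropy, Higuchi fractal dimension) in
#' deterministic channel-major order. Names follow
#' `CH{label}_IMF{k}_{feature}`.
#'
#' @param vmdList named list of [VMDResult-class], one per channel (as
#'   returned by [decomposeSegment()]); all entries must share `K`.
#' @param fs sampling rate, Hz.
#' @param p an [entropyParams()].
#' @return named numeric vector of length `n_channels * K * 8`, with
#'   attribute `n_sentinel` counting undefined-feature sentinels.
#' @export
extractFeatures <- function(vmdList, fs, p = entropyParams()) {
  Ks <- vapply(vmdList, nModes, 0L)
  if (length(unique(Ks)) != 1L)
    stop("all channels must share the same number of modes")
  K <- Ks[1]
  channels <- names(vmdList)
  if (is.null(channels)) channels <- paste0("ch", seq_along(vmdList))
  nSent <- 0L
  vals <- withCallingHandlers(
    unlist(lapply(seq_along(vmdList), function(ci) {
      m <- modes(vmdList[[ci]])
      unlist(lapply(seq_len(K), function(k) {
        imf <- m[k, ]
        # ApEn and SampEn share one template-matching pass
        cnt <- .apen_sampen(as.numeric(imf), p$m, p$r * sd(imf))
        sampen <- if (cnt$B == 0 || cnt$A == 0)
          sentinel0("sample entropy (no template matches)")
        else -log(cnt$A / cnt$B)
        c(psd = meanPSD(imf, fs),
          skew = sampleSkewness(imf),
          kurt = sampleKurtosis(imf),
          de = diffEntropy(imf),
          apen = cnt$apen,
          sampen = sampen,
          tsallis = tsallisEntropy(imf, p),
          hfd = higuchiFD(imf, p))
      }))
    })),
    vmdEEG_sentinel = function(w) {
      nSent <<- nSent + 1L
      invokeRestart("muffleWarning")
    })
  names(vals) <- as.vector(outer(FEATURE_ORDER,
    as.vector(outer(seq_len(K), channels,
                    function(k, ch) paste0("CH", ch, "_IMF", k))),
    function(f, pre) paste0(pre, "_", f)))
  if (nSent > 0)
    warning(warningCondition(
      paste0(nSent, " undefined feature value(s) replaced by sentinel 0"),
      class = "vmdEEG_sentinel_summary"))
  attr(vals, "n_sentinel") <- nSent
  vals
}

#' F1 score from sensitivity and precision
#'
#' Harmonic mean `2 * PR * SE / (PR + SE)`; inputs and output share the
#' same scale (e.g. percent).
#'
#' @param se sensitivity (recall).
#' @param pr precision.
#' @return F1 on the input scale.
#' @examples
#' f1Score(99.52, 98.58)
#' @export
f1Score <- function(se, pr) {
  if (se + pr == 0) return(0)
  2 * se * pr / (se + pr)
}
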