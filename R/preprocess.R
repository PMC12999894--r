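#' @include AllClasses.R
NULL

#' Preprocessing configuration
#'
#' Defaults follow standard resting-state EEG practice: 0.5-45 Hz
#' zero-phase Butterworth band-pass (order 4, applied forward-backward),
#' 50 Hz IIR notch with quality factor 30, common average reference, and
#' non-overlapping 8-second windows.
#'
#' @param hp_cutoff high-pass cutoff, Hz.
#' @param lp_cutoff low-pass cutoff, Hz.
#' @param notch_freq powerline frequency, Hz.
#' @param window_seconds segmentation window, s.
#' @param filter_order Butterworth order (per pass).
#' @param notch_quality notch Q factor.
#' @return a validated list of class `PreprocessConfig`.
#' @export
preprocessConfig <- function(hp_cutoff = 0.5, lp_cutoff = 45,
                             notch_freq = 50, window_seconds = 8,
                             filter_order = 4, notch_quality = 30) {
  cfg <- list(hp_cutoff = hp_cutoff, lp_cutoff = lp_cutoff,
              notch_freq = notch_freq, window_seconds = window_seconds,
              filter_order = filter_order, notch_quality = notch_quality)
  if (!(hp_cutoff > 0 && hp_cutoff < lp_cutoff))
    stop("config error: need 0 < hp_cutoff < lp_cutoff")
  if (window_seconds <= 0) stop("config error: window_seconds must be > 0")
  if (notch_quality <= 0) stop("config error: notch_quality must be > 0")
  structure(cfg, class = "PreprocessConfig")
}

checkNyquist <- function(cfg, fs) {
  if (cfg$lp_cutoff >= fs / 2)
    stop("config error: lp_cutoff (", cfg$lp_cutoff,
         " Hz) must be below fs/2 (", fs / 2, " Hz)")
  if (cfg$notch_freq >= fs / 2)
    stop("config error: notch_freq must be below fs/2")
  invisible(TRUE)
}

# forward-backward IIR filtering with odd-reflection padding and
# steady-state initial conditions (so constants map to their steady-state
# response exactly and edge transients are suppressed)
zeroPhaseFilter <- function(b, a, x) {
  n <- length(x)
  stepInit <- function(sig) {
    yss <- sig[1] * sum(b) / sum(a)
    as.numeric(signal::filter(b, a, sig,
                              init.x = rep(sig[1], length(b) - 1),
                              init.y = rep(yss, length(a) - 1)))
  }
  pad <- min(n - 1, 30 * (max(length(a), length(b)) - 1))
  pre <- 2 * x[1] - x[(pad + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - pad)]
  fwd <- stepInit(c(pre, x, post))
  bwd <- rev(stepInit(rev(fwd)))
  bwd[(pad + 1):(pad + n)]
}

applyPerChannel <- function(rec, fun) {
  x <- signalData(rec)
  out <- t(apply(x, 1, fun))
  Recording(out, fs = samplingRate(rec), channels = channelLabels(rec),
            subjectId = subjectId(rec), label = classLabel(rec))
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies the configured Butterworth band-pass per channel,
#' forward-backward (zero phase) with odd-reflection padding and
#' steady-state initial conditions. The DC component is removed entirely
#' (the high-pass has a zero at DC).
#'
#' @param rec a [Recording-class].
#' @param cfg a [preprocessConfig()].
#' @return filtered [Recording-class] of identical shape.
#' @export
bandpassFilter <- function(rec, cfg = preprocessConfig()) {
  fs <- samplingRate(rec)
  checkNyquist(cfg, fs)
  bf <- signal::butter(cfg$filter_order,
                       c(cfg$hp_cutoff, cfg$lp_cutoff) / (fs / 2),
                       type = "pass")
  applyPerChannel(rec, function(ch) zeroPhaseFilter(bf$b, bf$a, ch))
}

#' Zero-phase IIR notch filter
#'
#' Second-order (biquad) notch at `notch_freq` with quality factor
#' `notch_quality`, applied forward-backward. Suppresses powerline
#' interference while leaving bands more than a few Hz away essentially
#' untouched.
#'
#' @inheritParams bandpassFilter
#' @return filtered [Recording-class].
#' @export
notchFilter <- function(rec, cfg = preprocessConfig()) {
  fs <- samplingRate(rec)
  if (cfg$notch_freq >= fs / 2)
    stop("config error: notch_freq must be below fs/2")
  w0 <- 2 * pi * cfg$notch_freq / fs
  alpha <- sin(w0) / (2 * cfg$notch_quality)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  applyPerChannel(rec, function(ch) zeroPhaseFilter(b, a, ch))
}

#' Common average reference
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' the channel mean of the output is zero at every sample.
#'
#' @param rec a [Recording-class] with at least two channels.
#' @return re-referenced [Recording-class].
#' @export
commonAverageReference <- function(rec) {
  x <- signalData(rec)
  if (nrow(x) < 2)
    stop("common average reference requires at least 2 channels")
  out <- sweep(x, 2, colMeans(x))
  Recording(out, fs = samplingRate(rec), channels = channelLabels(rec),
            subjectId = subjectId(rec), label = classLabel(rec))
}

#' Segment a recording into non-overlapping windows
#'
#' Cuts the recording into `floor(n_samples / window_samples)` contiguous
#' non-overlapping windows in temporal order; a trailing partial window is
#' discarded, never zero-padded.
#'
#' @inheritParams bandpassFilter
#' @return a [SegmentedRecording-class].
#' @export
segmentRecording <- function(rec, cfg = preprocessConfig()) {
  ws <- round(cfg$window_seconds * samplingRate(rec))
  x <- signalData(rec)
  if (ncol(x) < ws)
    stop("recording shorter than one window (", ncol(x), " < ", ws,
         " samples)")
  n <- floor(ncol(x) / ws)
  segs <- lapply(seq_len(n), function(i) x[, ((i - 1) * ws + 1):(i * ws),
                                           drop = FALSE])
  new("SegmentedRecording", subjectId = subjectId(rec),
      label = classLabel(rec), fs = samplingRate(rec),
      channels = channelLabels(rec), segments = segs,
      windowSeconds = cfg$window_seconds)
}

#' Full preprocessing chain
#'
#' Band-pass, notch, common average reference, then segmentation, in that
#' fixed order.
#'
#' @inheritParams bandpassFilter
#' @return a [SegmentedRecording-class].
#' @export
preprocessRecording <- function(rec, cfg = preprocessConfig()) {
  rec |>
    bandpassFilter(cfg) |>
    notchFilter(cfg) |>
    commonAverageReference() |>
    segmentRecording(cfg)
}
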