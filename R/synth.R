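#' @include AllClasses.R io.R
NULL

SYNTH_BANDS <- list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13),
                    beta = c(13, 30))

#' Synthetic EEG generator configuration
#'
#' Two-class multichannel EEG with the statistical structure the pipeline
#' assumes: per channel a sum of amplitude-modulated narrowband
#' oscillations in the delta/theta/alpha/beta bands (random-walk phase)
#' plus 1/f-shaped background noise. The patient class (SCH) scales
#' delta/theta band power up, beta power down, and reduces oscillatory
#' phase noise, on the channels of the affected lobes.
#'
#' @param n_subjects_per_class subjects per class.
#' @param segments_per_subject 8-s windows generated per subject (7
#'   matches a 1-minute recording at the default window).
#' @param fs sampling rate, Hz (fs/2 must exceed 45 Hz).
#' @param montage `"mhrc16"`, `"repod19"`, or a character vector of
#'   channel labels.
#' @param window_seconds window length, s.
#' @param delta_theta_power_ratio SCH/control low-band power multiplier.
#' @param high_band_attenuation SCH beta power multiplier.
#' @param regularity_boost SCH phase-noise reduction factor (< 1 makes
#'   patient oscillations more regular).
#' @param affected_lobes lobes carrying the class contrast.
#' @param noise_exponent 1/f spectral exponent of the background noise.
#' @param noise_rms background noise RMS, microvolts.
#' @param seed RNG seed.
#' @return a list of class `SynthConfig`.
#' @export
synthConfig <- function(n_subjects_per_class = 10L,
                        segments_per_subject = 7L, fs = 128,
                        montage = "mhrc16", window_seconds = 8,
                        delta_theta_power_ratio = 2.0,
                        high_band_attenuation = 0.5,
                        regularity_boost = 0.5,
                        affected_lobes = LOBES,
                        noise_exponent = 1.0, noise_rms = 10,
                        seed = 1L) {
  channels <- if (length(montage) == 1 && montage %in% c("mhrc16", "repod19"))
    montageChannels(montage) else normalizeChannelLabels(montage)
  if (n_subjects_per_class < 1 || segments_per_subject < 1)
    stop("config error: counts must be positive")
  if (fs / 2 <= 45)
    stop("config error: fs too low for the beta band (need fs/2 > 45 Hz)")
  if (delta_theta_power_ratio <= 0 || high_band_attenuation <= 0 ||
      regularity_boost <= 0)
    stop("config error: effect multipliers must be > 0")
  structure(list(n_subjects_per_class = as.integer(n_subjects_per_class),
                 segments_per_subject = as.integer(segments_per_subject),
                 fs = fs, channels = channels,
                 window_seconds = window_seconds,
                 delta_theta_power_ratio = delta_theta_power_ratio,
                 high_band_attenuation = high_band_attenuation,
                 regularity_boost = regularity_boost,
                 affected_lobes = match.arg(affected_lobes, LOBES,
                                            several.ok = TRUE),
                 noise_exponent = noise_exponent, noise_rms = noise_rms,
                 seed = as.integer(seed)),
            class = "SynthConfig")
}

# 1/f^beta noise via spectral shaping of white Gaussian noise
onefNoise <- function(n, fs, exponent, rms) {
  w <- rnorm(n)
  W <- fft(w)
  f <- c(1e-6, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)                     # two-sided frequency axis
  shape <- pmax(f, 0.1)^(-exponent / 2)
  x <- Re(fft(W * shape, inverse = TRUE)) / n
  x <- x - mean(x)
  x * rms / sd(x)
}

# amplitude-modulated narrowband oscillation with random-walk phase
bandOscillation <- function(n, fs, band, rmsAmp, phaseSd) {
  fc <- runif(1, band[1] + 0.1 * diff(band), band[2] - 0.1 * diff(band))
  t <- seq_len(n) / fs
  phase <- 2 * pi * fc * t + cumsum(rnorm(n, 0, phaseSd))
  env <- 1 + 0.4 * sin(2 * pi * runif(1, 0.05, 0.2) * t +
                       runif(1, 0, 2 * pi))
  x <- env * sin(phase)
  x * rmsAmp / sd(x)
}

#' Generate synthetic two-class EEG recordings
#'
#' Deterministic given `cfg$seed`. Subjects are labeled
#' `SCH01..` / `CON01..`; each recording is exactly
#' `segments_per_subject * window_seconds` seconds long.
#'
#' @param cfg a [synthConfig()].
#' @return list of [Recording-class] objects (SCH subjects first).
#' @examples
#' recs <- generateRecordings(synthConfig(n_subjects_per_class = 1,
#'                                        segments_per_subject = 1))
#' recs[[1]]
#' @export
generateRecordings <- function(cfg = synthConfig()) {
  set.seed(cfg$seed)
  nwin <- round(cfg$window_seconds * cfg$fs)
  n <- cfg$segments_per_subject * nwin
  baseAmp <- c(delta = 20, theta = 15, alpha = 25, beta = 10)
  basePhaseSd <- 0.15
  ampJitterSd <- 0.08
  affected <- lobeChannelsOf(cfg$channels, cfg$affected_lobes)
  out <- list()
  for (class in c("SCH", "CONTROL")) {
    for (s in seq_len(cfg$n_subjects_per_class)) {
      data <- matrix(0, length(cfg$channels), n)
      for (ci in seq_along(cfg$channels)) {
        hit <- class == "SCH" && cfg$channels[ci] %in% affected
        amp <- baseAmp
        phSd <- basePhaseSd
        if (hit) {
          amp[c("delta", "theta")] <- amp[c("delta", "theta")] *
            sqrt(cfg$delta_theta_power_ratio)
          amp["beta"] <- amp["beta"] * sqrt(cfg$high_band_attenuation)
          phSd <- phSd * cfg$regularity_boost
        }
        # oscillation parameters are redrawn per window: windows (and
        # hence subjects) of a class are exchangeable, so a null
        # contrast is genuinely indistinguishable (no subject-identity
        # fingerprints for segment-level CV to exploit)
        for (w in seq_len(cfg$segments_per_subject)) {
          x <- numeric(nwin)
          winAmp <- amp * exp(rnorm(4, 0, ampJitterSd))
          for (b in names(SYNTH_BANDS))
            x <- x + bandOscillation(nwin, cfg$fs, SYNTH_BANDS[[b]],
                                     winAmp[b], phSd)
          data[ci, ((w - 1) * nwin + 1):(w * nwin)] <-
            x + onefNoise(nwin, cfg$fs, cfg$noise_exponent, cfg$noise_rms)
        }
      }
      id <- sprintf("%s%02d", if (class == "SCH") "SCH" else "CON", s)
      out[[id]] <- Recording(data, fs = cfg$fs, channels = cfg$channels,
                             subjectId = id, label = class)
    }
  }
  out
}

lobeChannelsOf <- function(channels, lobes) {
  unlist(lapply(lobes, function(l)
    lobeChannels(channels, l, defaultMontage())))
}

#' Write recordings as a fixture directory
#'
#' One file per recording (EDF or CSV) plus a JSON manifest
#' (`manifest.json`: subject ids, labels, sampling rate, montage, format)
#' consumable by [readFixture()].
#'
#' @param recordings non-empty list of [Recording-class] objects.
#' @param dir output directory (created if needed).
#' @param format `"csv"` or `"edf"`.
#' @param physRange EDF physical range, microvolts.
#' @return path of the manifest file, invisibly.
#' @export
writeFixture <- function(recordings, dir, format = c("csv", "edf"),
                         physRange = c(-1000, 1000)) {
  format <- match.arg(format)
  if (!length(recordings)) stop("empty recording list")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(recordings, function(rec) {
    fn <- paste0(subjectId(rec), ".", if (format == "edf") "edf" else "csv")
    if (format == "edf") writeEDF(rec, file.path(dir, fn), physRange)
    else writeMatrixEEG(rec, file.path(dir, fn))
    list(file = fn, subject_id = subjectId(rec), label = classLabel(rec),
         fs = samplingRate(rec), channels = as.list(channelLabels(rec)))
  })
  manifest <- list(format = format, recordings = unname(entries))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fixture directory written by [writeFixture()]
#'
#' @param dir fixture directory containing `manifest.json`.
#' @return list of [Recording-class] objects.
#' @export
readFixture <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("missing artifact: ", mf)
  manifest <- jsonlite::read_json(mf, simplifyVector = FALSE)
  lapply(manifest$recordings, function(e) {
    path <- file.path(dir, e$file)
    if (manifest$format == "edf")
      readEDF(path, subjectId = e$subject_id, label = e$label)
    else
      readMatrixEEG(path, fs = e$fs,
                    channels = unlist(e$channels),
                    subjectId = e$subject_id, label = e$label)
  })
}
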