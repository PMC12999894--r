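test_that("band-pass removes slow drift and DC while passing mid-band content", {
  fs <- 250
  t <- seq_len(60 * fs) / fs
  cfg <- preprocessConfig()

  # analytic single-pass response of the default Butterworth design
  bf <- signal::butter(cfg$filter_order,
                       c(cfg$hp_cutoff, cfg$lp_cutoff) / (fs / 2), "pass")
  H <- function(fhz) {
    z <- exp(-1i * 2 * pi * fhz / fs * (seq_along(bf$b) - 1))
    abs(sum(bf$b * z) / sum(bf$a * z))
  }
  expect_gt(-20 * log10(H(0.05)), 26)

  drift <- Recording(matrix(sin(2 * pi * 0.05 * t), 1), fs, "Cz")
  out <- bandpassFilter(drift, cfg)
  expect_lt(sqrt(mean(signalData(out)^2)) /
              sqrt(mean(signalData(drift)^2)), 0.05)

  tone <- Recording(matrix(sin(2 * pi * 10 * t), 1), fs, "Cz")
  amp <- max(abs(signalData(bandpassFilter(tone, cfg))[1, 2000:13000]))
  expect_lt(abs(amp - 1), 0.05)

  const <- Recording(matrix(1, 2, 5000) * 10, fs, c("C3", "C4"))
  expect_lt(max(abs(signalData(bandpassFilter(const, cfg)))), 1e-4)

  expect_error(bandpassFilter(Recording(matrix(0, 1, 100), 80, "Cz"),
                              preprocessConfig(lp_cutoff = 45)),
               "config error")
})

test_that("notch suppresses 50 Hz while leaving neighbors intact", {
  fs <- 250
  t <- seq_len(20 * fs) / fs
  x <- sin(2 * pi * 50 * t) + sin(2 * pi * 10 * t)
  rec <- Recording(matrix(x, 1), fs, "Cz")
  out <- signalData(notchFilter(rec))[1, ]
  binPower <- function(sig, fhz) {
    p <- Mod(fft(sig))^2
    p[round(fhz * length(sig) / fs) + 1]
  }
  expect_lt(binPower(out, 50) / binPower(x, 50), 0.01)
  expect_lt(abs(sqrt(binPower(out, 10) / binPower(x, 10)) - 1), 0.05)

  set.seed(1)
  wn <- rnorm(20 * fs)
  wrec <- Recording(matrix(wn, 1), fs, "Cz")
  wout <- signalData(notchFilter(wrec))[1, ]
  pw <- function(sig, lo, hi) fftBandPower(sig, fs, lo, hi)
  keepIn <- pw(wn, 0.5, 44) + pw(wn, 56, 120)
  keepOut <- pw(wout, 0.5, 44) + pw(wout, 56, 120)
  expect_lt(abs(keepOut / keepIn - 1), 0.1)

  zero <- Recording(matrix(0, 1, 1000), fs, "Cz")
  expect_equal(max(abs(signalData(notchFilter(zero)))), 0)
})

test_that("common average reference zeroes the channel mean at every sample", {
  fs <- 100
  same <- Recording(matrix(rep(sin(seq_len(500) / 10), 3), 3, 500,
                           byrow = TRUE), fs, c("C3", "C4", "Cz"))
  expect_lt(max(abs(signalData(commonAverageReference(same)))), 1e-12)

  set.seed(2)
  rnd <- Recording(matrix(rnorm(4 * 300), 4), fs,
                   c("C3", "C4", "F3", "F4"))
  out <- commonAverageReference(rnd)
  expect_lt(max(abs(colMeans(signalData(out)))), 1e-10)

  ab <- Recording(rbind(1:10, seq(2, 20, 2)), fs, c("C3", "C4"))
  ref <- commonAverageReference(ab)
  a <- 1:10; b <- seq(2, 20, 2)
  expect_equal(signalData(ref)[1, ], (a - b) / 2)
  expect_equal(signalData(ref)[2, ], (b - a) / 2)

  expect_error(commonAverageReference(Recording(matrix(1:5, 1), fs, "Cz")),
               "at least 2 channels")
})

test_that("segmentation produces floor(n/window) contiguous windows", {
  # 60 s at 128 Hz with 8-s windows: 7 segments of 1024 samples
  rec <- Recording(matrix(seq_len(7680), 1), 128, "Cz")
  seg <- segmentRecording(rec)
  expect_equal(nSegments(seg), 7)
  expect_equal(ncol(segments(seg)[[1]]), 1024)
  expect_equal(segments(seg)[[2]][1, 1], 1025)  # contiguous, in order

  # 15-minute session at 250 Hz: 112 segments of 2000 samples
  rec2 <- Recording(matrix(0, 1, 15 * 60 * 250), 250, "Cz")
  seg2 <- segmentRecording(rec2)
  expect_equal(nSegments(seg2), 112)
  expect_equal(ncol(segments(seg2)[[1]]), 2000)

  rec3 <- Recording(matrix(0, 2, 1024), 128, c("C3", "C4"))
  expect_equal(nSegments(segmentRecording(rec3)), 1)
  expect_error(segmentRecording(Recording(matrix(0, 1, 1000), 128, "Cz")),
               "shorter than one window")
})

test_that("segmentation preserves sample counts up to the discarded remainder", {
  set.seed(3)
  for (n in sample(1100:9000, 5)) {
    rec <- Recording(matrix(rnorm(n), 1), 128, "Cz")
    seg <- segmentRecording(rec)
    ws <- 1024
    expect_true(nSegments(seg) * ws <= n)
    expect_true(n < (nSegments(seg) + 1) * ws)
    expect_equal(segments(seg)[[1]][1, ], signalData(rec)[1, 1:ws])
  }
})

test_that("the filter chain is idempotent on stationary in-band signals", {
  fs <- 128
  t <- seq_len(40 * fs) / fs
  x <- 20 * sin(2 * pi * 4 * t) + 30 * sin(2 * pi * 10 * t + 1) +
    10 * sin(2 * pi * 24 * t + 2)
  rec <- Recording(rbind(x, rev(x)), fs, c("C3", "C4"))
  chain <- function(r)
    commonAverageReference(notchFilter(bandpassFilter(r)))
  once <- chain(rec)
  twice <- chain(once)
  relRMS <- sqrt(mean((signalData(twice) - signalData(once))^2)) /
    sqrt(mean(signalData(once)^2))
  expect_lt(relRMS, 0.01)
})

test_that("preprocess configuration is validated", {
  expect_error(preprocessConfig(hp_cutoff = 50, lp_cutoff = 45),
               "config error")
  expect_error(preprocessConfig(window_seconds = 0), "config error")
})
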