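twoTone <- function(fs = 200, secs = 8, f1 = 5, f2 = 40) {
  t <- seq_len(fs * secs) / fs
  sin(2 * pi * f1 * t) + sin(2 * pi * f2 * t)
}

test_that("two well-separated tones are recovered at their FFT-peak frequencies", {
  fs <- 200
  x <- twoTone(fs)
  oracle <- fftPeaks(x, fs, 2)      # independent peak-location oracle
  res <- vmdDecompose(x, fs, vmdConfig(K = 2, alpha = 2000))
  expect_equal(nModes(res), 2)
  expect_lt(max(abs(centerFreqs(res) - oracle)), 0.5)

  # band-limitation: >= 90% of each mode's energy near its center
  for (k in 1:2) {
    m <- modes(res)[k, ]
    inband <- fftBandPower(m, fs, centerFreqs(res)[k] - 3,
                           centerFreqs(res)[k] + 3)
    expect_gt(inband / fftBandPower(m, fs, 0, fs / 2), 0.9)
  }
})

test_that("a single pure tone yields one faithful mode", {
  fs <- 200
  t <- seq_len(fs * 8) / fs
  x <- sin(2 * pi * 13 * t)
  res <- vmdDecompose(x, fs, vmdConfig(K = 1))
  expect_lt(abs(centerFreqs(res) - 13), 0.5)
  expect_gt(cor(modes(res)[1, ], x), 0.99)
  interior <- seq(0.1 * length(x), 0.9 * length(x))  # away from edges
  expect_gt(cor(modes(res)[1, interior], x[interior]), 0.999)
})

test_that("the zero signal decomposes to zero modes immediately", {
  res <- vmdDecompose(numeric(1000), 100, vmdConfig(K = 4))
  expect_equal(max(abs(modes(res))), 0)
  expect_lte(res@nIter, 2)
  expect_true(converged(res))
})

test_that("decomposition is deterministic and offset-invariant beyond mode 1", {
  set.seed(4)
  fs <- 128
  x <- signalData(generateRecordings(synthConfig(
    n_subjects_per_class = 1, segments_per_subject = 1, seed = 9))[[1]])[1, ]
  x <- x[1:1024]
  r1 <- vmdDecompose(x, fs)
  r2 <- vmdDecompose(x, fs)
  expect_identical(modes(r1), modes(r2))
  expect_identical(centerFreqs(r1), centerFreqs(r2))

  r3 <- vmdDecompose(x + 57.3, fs)
  rmsDiff <- sqrt(rowMeans((modes(r1)[2:10, ] - modes(r3)[2:10, ])^2))
  expect_lt(max(rmsDiff), 1e-6)
})

test_that("with tau = 0 the reconstruction is close and residual energy shrinks", {
  rec <- generateRecordings(synthConfig(n_subjects_per_class = 1,
                                        segments_per_subject = 1,
                                        seed = 5))[[1]]
  x <- signalData(bandpassFilter(rec))[1, ]
  res <- vmdDecompose(x, 128)
  expect_gt(cor(colSums(modes(res)), x), 0.95)
  re <- res@residualEnergy[1:10]
  expect_true(all(diff(re) < 0))
  # invariants of the result object
  expect_false(is.unsorted(centerFreqs(res)))
  expect_true(all(centerFreqs(res) >= 0 & centerFreqs(res) <= 64))
  expect_true(all(is.finite(res@residual)))
})

test_that("decomposeSegment preserves channel order and reports failing channels", {
  seg <- rbind(twoTone(100, 4), sin(2 * pi * 7 * seq_len(400) / 100))
  out <- decomposeSegment(seg, 100, vmdConfig(K = 3),
                          channels = c("F3", "O1"))
  expect_named(out, c("F3", "O1"))
  expect_equal(vapply(out, nModes, 0L), c(F3 = 3L, O1 = 3L))

  one <- decomposeSegment(seg[1, , drop = FALSE], 100, vmdConfig(K = 2))
  expect_length(one, 1)

  segBad <- seg
  segBad[2, 5] <- NaN
  expect_error(decomposeSegment(segBad, 100, vmdConfig(K = 2),
                                channels = c("F3", "O1")), "O1")
})

test_that("invalid inputs and configurations are rejected", {
  expect_error(vmdDecompose(c(1, Inf, 3), 100), "non-finite")
  expect_error(vmdDecompose(rnorm(10), 100, vmdConfig(K = 8)), "K")
  expect_error(vmdConfig(K = 0), "config error")
  expect_error(vmdConfig(alpha = -1), "config error")
  expect_error(vmdConfig(tol = 0), "config error")
})

test_that("random initialization is reproducible under its seed", {
  x <- twoTone(100, 4)
  a <- vmdDecompose(x, 100, vmdConfig(K = 3, init = "random", seed = 42))
  b <- vmdDecompose(x, 100, vmdConfig(K = 3, init = "random", seed = 42))
  expect_identical(modes(a), modes(b))
})
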