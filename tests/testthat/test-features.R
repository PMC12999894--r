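test_that("ApEn/SampEn equal the naive O(N^2) oracle on assorted inputs", {
  # periodic sequence: exact brute-force agreement
  x <- rep(c(1, 2), 50)
  p <- entropyParams(m = 2, r = 0.2)
  o <- naiveApEnSampEn(x, 2, 0.2 * sd(x))
  expect_lt(abs(approxEntropy(x, p) - o$apen), 1e-12)
  expect_lt(abs(sampleEntropy(x, p) - o$sampen), 1e-12)

  set.seed(11)
  for (i in 1:8) {
    n <- sample(60:200, 1)
    m <- sample(1:3, 1)
    rf <- sample(c(0.1, 0.2, 0.5), 1)
    y <- rnorm(n)
    cnt <- vmdEEG:::.apen_sampen(y, m, rf * sd(y))
    ora <- naiveApEnSampEn(y, m, rf * sd(y))
    expect_identical(c(cnt$A, cnt$B), as.numeric(c(ora$A, ora$B)))
    expect_equal(cnt$apen, ora$apen, tolerance = 1e-10)
  }
})

test_that("regularity ordering: white noise is less regular than a sine", {
  set.seed(21)
  n <- 1000
  t <- seq_len(n) / 100
  sine <- sin(2 * pi * 5 * t)
  noise <- rnorm(n, sd = sd(sine))
  expect_gt(approxEntropy(noise), approxEntropy(sine))
  # over 20 seeded trials, mean SampEn(noise) > mean SampEn(sine)
  se <- vapply(1:20, function(s) {
    set.seed(s)
    w <- rnorm(400, sd = sd(sine))
    c(sampleEntropy(w), sampleEntropy(sine[1:400]))
  }, numeric(2))
  expect_gt(mean(se[1, ]), mean(se[2, ]))
})

test_that("sample entropy is invariant under sign flip and offset", {
  set.seed(5)
  x <- rnorm(300)
  expect_equal(sampleEntropy(x), sampleEntropy(-x), tolerance = 1e-12)
  expect_equal(sampleEntropy(x), sampleEntropy(x + 17.5),
               tolerance = 1e-12)
})

test_that("constant signals yield the forced zero entropies", {
  x <- rep(3.2, 100)
  expect_equal(approxEntropy(x), 0)
  expect_equal(sampleEntropy(x), 0)
  expect_equal(tsallisEntropy(x), 0)
  expect_warning(v <- diffEntropy(x), class = "vmdEEG_sentinel")
  expect_equal(v, 0)
})

test_that("differential entropy matches the Gaussian closed form", {
  set.seed(6)
  x <- rnorm(5000)
  x <- (x - mean(x)) / sd(x)           # unit sample variance
  expect_equal(diffEntropy(x), 0.5 * log(2 * pi * exp(1)),
               tolerance = 1e-12)
  y <- x * sqrt(exp(2) / (2 * pi * exp(1)))  # variance chosen so H = 1
  expect_equal(diffEntropy(y), 1.0, tolerance = 1e-10)
  # scaling by c adds ln|c|
  expect_equal(diffEntropy(3 * x) - diffEntropy(x), log(3),
               tolerance = 1e-10)
})

test_that("Tsallis entropy matches closed forms and the Shannon limit", {
  # uniform occupancy of B bins at q = 2 gives 1 - 1/B
  x <- c(0, 1, 2, 3)
  expect_equal(tsallisEntropy(x, entropyParams(n_bins = 4)), 1 - 1 / 4,
               tolerance = 1e-12)
  set.seed(7)
  z <- rnorm(2000)
  p <- entropyParams(n_bins = 32)
  # Shannon entropy computed directly from the identical histogram
  breaks <- seq(min(z), max(z), length.out = 33)
  pr <- tabulate(.bincode(z, breaks, include.lowest = TRUE), 32)
  pr <- pr[pr > 0] / length(z)
  shannon <- -sum(pr * log(pr))
  near1 <- entropyParams(q = 1.0001, n_bins = 32)
  expect_equal(tsallisEntropy(z, near1), shannon, tolerance = 1e-3)
})

test_that("Higuchi fractal dimension hits its limiting cases", {
  expect_lt(abs(higuchiFD(as.numeric(1:1000)) - 1), 0.05)
  set.seed(8)
  w <- rnorm(5000)
  expect_lt(abs(higuchiFD(w) - 2), 0.15)
  # affine invariance of the log-log slope
  expect_equal(higuchiFD(w), higuchiFD(2 * w + 7), tolerance = 1e-9)
  expect_error(higuchiFD(rnorm(50)), "length")
})

test_that("skewness and kurtosis are the standardized central moments", {
  expect_equal(sampleSkewness(c(-1, 0, 1)), 0)
  set.seed(9)
  g <- rnorm(1e5)
  expect_lt(abs(sampleKurtosis(g) - 3), 0.1)
  e <- rexp(1e5)
  expect_lt(abs(sampleSkewness(e) - 2), 0.1)
  expect_warning(k <- sampleKurtosis(rep(1, 10)),
                 class = "vmdEEG_sentinel")
  expect_equal(k, 0)
})

test_that("mean PSD obeys Parseval and quadratic amplitude scaling", {
  fs <- 128
  t <- seq_len(8 * fs) / fs
  x <- sin(2 * pi * 10 * t)
  w <- welchPSD(x, fs)
  df <- w$freq[2] - w$freq[1]
  expect_lt(abs(sum(w$psd) * df - 0.5) / 0.5, 0.05)  # sine power = 1/2
  expect_equal(meanPSD(numeric(1024), fs), 0)
  expect_equal(meanPSD(2 * x, fs) / meanPSD(x, fs), 4, tolerance = 1e-9)
  expect_error(meanPSD(rnorm(10), fs), "64")
})

test_that("extractFeatures emits the deterministic channel-major layout", {
  seg <- rbind(sin(2 * pi * 6 * seq_len(640) / 80) + rnorm(640, sd = .1),
               rnorm(640))
  dec <- decomposeSegment(seg, 80, vmdConfig(K = 3),
                          channels = c("F3", "O1"))
  fv <- extractFeatures(dec, 80)
  expect_length(fv, 2 * 3 * 8)
  expect_equal(names(fv)[1:8],
               paste0("CHF3_IMF1_",
                      c("psd", "skew", "kurt", "de", "apen", "sampen",
                        "tsallis", "hfd")))
  expect_equal(names(fv)[9], "CHF3_IMF2_psd")
  expect_equal(names(fv)[25], "CHO1_IMF1_psd")
  expect_false(anyDuplicated(names(fv)) > 0)
  expect_true(all(is.finite(fv)))

  one <- decomposeSegment(seg[1, , drop = FALSE], 80, vmdConfig(K = 1))
  expect_length(extractFeatures(one, 80), 8)
})

test_that("undefined features become counted sentinels, never silent NaN", {
  # a constant channel forces zero-variance sentinels in every IMF
  seg <- rbind(rnorm(640), rep(1, 640))
  dec <- decomposeSegment(seg, 80, vmdConfig(K = 2),
                          channels = c("F3", "O1"))
  expect_warning(fv <- extractFeatures(dec, 80),
                 class = "vmdEEG_sentinel_summary")
  fv <- suppressWarnings(extractFeatures(dec, 80))
  expect_true(all(is.finite(fv)))
  expect_gt(attr(fv, "n_sentinel"), 0)
})

test_that("entropy parameters are validated", {
  expect_error(entropyParams(m = 0), "config error")
  expect_error(entropyParams(q = 1), "config error")
  expect_error(entropyParams(n_bins = 1), "config error")
})
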