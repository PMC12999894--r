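# In-code fixtures shared across test files.

# A feature table with Gaussian features and an optional class mean shift
# planted on the features of selected channels. Cheap stand-in for the
# full pipeline in model/validation tests.
makeToyFeatureTable <- function(n_subjects_per_class = 4,
                                segments_per_subject = 5,
                                channels = c("F3", "F4", "C3", "C4",
                                             "O1", "O2"),
                                K = 2, effect = 0,
                                effect_channels = channels, seed = 1) {
  set.seed(seed)
  feats <- as.vector(outer(c("psd", "skew", "kurt", "de", "apen",
                             "sampen", "tsallis", "hfd"),
    as.vector(outer(seq_len(K), channels,
                    function(k, ch) paste0("CH", ch, "_IMF", k))),
    function(f, pre) paste0(pre, "_", f)))
  nrows <- 2 * n_subjects_per_class * segments_per_subject
  X <- matrix(rnorm(nrows * length(feats)), nrows,
              dimnames = list(NULL, feats))
  subj <- rep(c(sprintf("SCH%02d", seq_len(n_subjects_per_class)),
                sprintf("CON%02d", seq_len(n_subjects_per_class))),
              each = segments_per_subject)
  y <- rep(c("SCH", "CONTROL"), each = n_subjects_per_class *
             segments_per_subject)
  hit <- grepl(paste0("^CH(", paste(effect_channels, collapse = "|"),
                      ")_"), feats)
  X[y == "SCH", hit] <- X[y == "SCH", hit] + effect
  featureTable(X, y = y, subject_ids = subj)
}

# small deterministic recording of known sinusoids
makeSineRecording <- function(freqs = c(5, 10, 20), fs = 250,
                              seconds = 4, amp = 50, label = "CONTROL",
                              channels = NULL) {
  t <- seq_len(fs * seconds) / fs
  data <- t(vapply(freqs, function(f) amp * sin(2 * pi * f * t), t))
  if (is.null(channels)) channels <- paste0("C", seq_along(freqs))
  Recording(data, fs = fs, channels = channels, subjectId = "sine",
            label = label)
}
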