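#' @include AllClasses.R features.R
NULL

parseFeatureNames <- function(nm) {
  m <- regmatches(nm, regexec("^CH(.+)_IMF([0-9]+)_([a-z]+)$", nm))
  bad <- vapply(m, length, 0L) != 4L
  if (any(bad))
    stop("malformed feature name(s): ", paste(nm[bad][1], collapse = ", "))
  data.frame(channel = vapply(m, `[`, "", 2),
             imf = as.integer(vapply(m, `[`, "", 3)),
             feature = vapply(m, `[`, "", 4))
}

#' Construct a FeatureTable
#'
#' @param X segments x features numeric matrix with the deterministic
#'   `CH{label}_IMF{k}_{feature}` column names.
#' @param y class labels (`"SCH"`/`"CONTROL"`), one per row.
#' @param subject_ids subject id per row.
#' @param segment_index optional per-row segment index within subject.
#' @return a [FeatureTable-class].
#' @export
featureTable <- function(X, y, subject_ids, segment_index = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) stop("X must have feature column names")
  if (length(y) != nrow(X) || length(subject_ids) != nrow(X))
    stop("rows of X, y and subject_ids must align")
  if (is.null(segment_index)) {
    segment_index <- stats::ave(seq_along(subject_ids),
                                subject_ids, FUN = seq_along)
  }
  rd <- parseFeatureNames(colnames(X))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = t(X)),
    rowData = S4Vectors::DataFrame(rd, row.names = colnames(X)),
    colData = S4Vectors::DataFrame(
      subject_id = as.character(subject_ids),
      label = as.character(y),
      segment_index = as.integer(segment_index)))
  new("FeatureTable", se)
}

#' Build a feature table from recordings
#'
#' Runs the full extraction chain: preprocess (band-pass, notch, common
#' average reference, segmentation), per-segment per-channel VMD, and the
#' eight-feature battery, assembling one row per segment.
#'
#' @param recordings list of [Recording-class] objects.
#' @param preCfg a [preprocessConfig()].
#' @param vmdCfg a [vmdConfig()].
#' @param entCfg an [entropyParams()].
#' @param verbose print progress.
#' @return a [FeatureTable-class] with `n_channels * K * 8` feature
#'   columns.
#' @export
buildFeatureTable <- function(recordings, preCfg = preprocessConfig(),
                              vmdCfg = vmdConfig(),
                              entCfg = entropyParams(), verbose = FALSE) {
  if (!length(recordings)) stop("no recordings supplied")
  rows <- list()
  meta <- list()
  for (rec in recordings) {
    seg <- preprocessRecording(rec, preCfg)
    if (verbose)
      message("  ", subjectId(rec), ": ", nSegments(seg), " segments")
    for (i in seq_len(nSegments(seg))) {
      dec <- decomposeSegment(segments(seg)[[i]], samplingRate(seg),
                              vmdCfg, channels = channelLabels(seg))
      fv <- suppressWarnings(extractFeatures(dec, samplingRate(seg), entCfg))
      rows[[length(rows) + 1L]] <- fv
      meta[[length(meta) + 1L]] <- list(subject = subjectId(rec),
                                        label = classLabel(rec),
                                        segment = i)
    }
  }
  X <- do.call(rbind, rows)
  featureTable(X,
               y = vapply(meta, `[[`, "", "label"),
               subject_ids = vapply(meta, `[[`, "", "subject"),
               segment_index = vapply(meta, function(m) m$segment, 0))
}

#' Subset a feature table to one lobe
#'
#' Keeps only the feature columns whose channel belongs to `lobe` under
#' the montage map. Idempotent; errors when the montage has no channel of
#' that lobe in this table.
#'
#' @param tab a [FeatureTable-class].
#' @param lobe lobe name.
#' @param montage channel -> lobe map; see [defaultMontage()].
#' @return a [FeatureTable-class] with the reduced feature set.
#' @export
subsetLobe <- function(tab, lobe, montage = defaultMontage()) {
  lobe <- match.arg(lobe, LOBES)
  ch <- channelOfFeature(tab)
  chans <- lobeChannels(unique(unname(ch)), lobe, montage)
  if (!length(chans))
    stop("no channels of lobe '", lobe, "' in this feature table")
  tab[ch %in% chans, ]
}

#' Leakage-safe z-score normalization
#'
#' `fitNormalizer` learns per-column means and SDs from training rows
#' only; `applyNormalizer` standardizes any matrix with those statistics.
#' Columns with zero training variance are centered but not scaled.
#'
#' @param train_X training matrix (>= 2 rows).
#' @return `fitNormalizer`: an object of class `Normalizer`.
#' @export
fitNormalizer <- function(train_X) {
  train_X <- as.matrix(train_X)
  if (nrow(train_X) < 2) stop("normalizer requires >= 2 training rows")
  mu <- colMeans(train_X)
  sdev <- apply(train_X, 2, sd)
  structure(list(center = mu, scale = ifelse(sdev > 0, sdev, 1)),
            class = "Normalizer")
}

#' @rdname fitNormalizer
#' @param normalizer a fitted `Normalizer`.
#' @param X matrix to transform (same columns as the training matrix).
#' @return `applyNormalizer`: the standardized matrix.
#' @export
applyNormalizer <- function(normalizer, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(normalizer$center))
    stop("column count differs from the normalizer's training matrix")
  sweep(sweep(X, 2, normalizer$center), 2, normalizer$scale, "/")
}

#' Write / read a feature table as CSV with a JSON schema sidecar
#'
#' The CSV holds `subject_id`, `label`, `segment_index` and the feature
#' columns; the sidecar (`<path>.schema.json`) records feature names and
#' the channel map so a round-trip reconstructs the object exactly.
#'
#' @param tab a [FeatureTable-class].
#' @param path CSV output path.
#' @return `path`, invisibly (writer); a [FeatureTable-class] (reader).
#' @export
writeFeatureTable <- function(tab, path) {
  df <- data.frame(subject_id = subjectIds(tab),
                   label = as.character(segmentLabels(tab)),
                   segment_index = SummarizedExperiment::colData(tab)$segment_index,
                   featureMatrix(tab), check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  schema <- list(features = rownames(tab),
                 channel_of_feature = as.list(channelOfFeature(tab)))
  jsonlite::write_json(schema, paste0(path, ".schema.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  meta <- c("subject_id", "label", "segment_index")
  X <- as.matrix(df[, setdiff(colnames(df), meta), drop = FALSE])
  featureTable(X, y = df$label, subject_ids = df$subject_id,
               segment_index = df$segment_index)
}
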