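#' @include vmdEEG-package.R
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Recording: one labeled multichannel EEG recording
#'
#' Container for a single subject's multichannel EEG signal in microvolts,
#' with sampling rate, ordered 10-20 channel labels, and a binary class
#' label (`"SCH"` patient vs `"CONTROL"`).
#'
#' @slot subjectId character scalar subject identifier.
#' @slot label class label, one of `"SCH"`, `"CONTROL"`.
#' @slot fs sampling rate in Hz (positive).
#' @slot channels ordered character vector of unique channel labels.
#' @slot data numeric matrix, channels x samples, microvolts, finite.
#'
#' @seealso [Recording()], [readEDF()], [readMatrixEEG()]
#' @export
setClass("Recording",
  representation(subjectId = "character", label = "character",
                 fs = "numeric", channels = "character", data = "matrix"))

setValidity("Recording", function(object) {
  msg <- character()
  if (length(object@subjectId) != 1L) msg <- c(msg, "subjectId must be scalar")
  if (!object@label %in% c("SCH", "CONTROL"))
    msg <- c(msg, "label must be 'SCH' or 'CONTROL'")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a positive number")
  if (nrow(object@data) != length(object@channels))
    msg <- c(msg, "nrow(data) must equal length(channels)")
  if (anyDuplicated(object@channels))
    msg <- c(msg, "channel labels must be unique")
  if (!all(is.finite(object@data)))
    msg <- c(msg, "data must be finite (no NaN/Inf)")
  if (length(msg)) msg else TRUE
})

#' Construct a Recording
#'
#' @param data channels x samples numeric matrix (microvolts).
#' @param fs sampling rate, Hz.
#' @param channels character vector of channel labels (row order of `data`).
#' @param subjectId subject identifier.
#' @param label `"SCH"` or `"CONTROL"`.
#' @return A [Recording-class] object.
#' @examples
#' rec <- Recording(matrix(rnorm(200), 2), fs = 100,
#'                  channels = c("C3", "C4"), subjectId = "s1")
#' nChannels(rec)
#' @export
Recording <- function(data, fs, channels, subjectId = "subject",
                      label = c("CONTROL", "SCH")) {
  label <- match.arg(label)
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  new("Recording", subjectId = as.character(subjectId), label = label,
      fs = as.numeric(fs), channels = normalizeChannelLabels(channels),
      data = data)
}

#' SegmentedRecording: non-overlapping fixed-length windows of a Recording
#'
#' @slot subjectId,label,fs,channels metadata inherited from the parent
#'   [Recording-class].
#' @slot segments list of channels x window-samples matrices, contiguous,
#'   non-overlapping, in temporal order.
#' @slot windowSeconds window length in seconds.
#' @export
setClass("SegmentedRecording",
  representation(subjectId = "character", label = "character",
                 fs = "numeric", channels = "character",
                 segments = "list", windowSeconds = "numeric"))

setValidity("SegmentedRecording", function(object) {
  msg <- character()
  ws <- round(object@windowSeconds * object@fs)
  shapes <- vapply(object@segments, function(s) dim(s), integer(2))
  if (length(object@segments)) {
    if (any(shapes[1, ] != length(object@channels)))
      msg <- c(msg, "every segment must have one row per channel")
    if (any(shapes[2, ] != ws))
      msg <- c(msg, "every segment must have round(windowSeconds * fs) columns")
  }
  if (length(msg)) msg else TRUE
})

#' VMDResult: variational mode decomposition of one signal
#'
#' Modes are sorted by ascending center frequency; center frequencies are
#' reported in Hz (spectral centroid of each mode).
#'
#' @slot modes K x n numeric matrix of band-limited modes (time domain).
#' @slot centerFreqs K center frequencies, Hz, ascending.
#' @slot fs sampling rate of the decomposed signal, Hz.
#' @slot nIter ADMM iterations used.
#' @slot converged logical; whether the relative-change criterion was met.
#' @slot residual input minus the sum of modes.
#' @slot residualEnergy per-iteration spectral residual energy (diagnostic).
#' @export
setClass("VMDResult",
  representation(modes = "matrix", centerFreqs = "numeric", fs = "numeric",
                 nIter = "integer", converged = "logical",
                 residual = "numeric", residualEnergy = "numeric"))

setValidity("VMDResult", function(object) {
  msg <- character()
  if (nrow(object@modes) != length(object@centerFreqs))
    msg <- c(msg, "one center frequency per mode required")
  if (is.unsorted(object@centerFreqs))
    msg <- c(msg, "modes must be sorted by ascending center frequency")
  if (any(object@centerFreqs < 0 | object@centerFreqs > object@fs / 2 + 1e-9))
    msg <- c(msg, "center frequencies must lie in [0, fs/2]")
  if (!all(is.finite(object@residual)))
    msg <- c(msg, "residual must be finite")
  if (length(msg)) msg else TRUE
})

#' FeatureTable: segments x features container
#'
#' Extends [SummarizedExperiment::SummarizedExperiment-class]: the assay is
#' a features x segments matrix; `rowData` carries the channel, IMF index
#' and feature name of every row; `colData` carries `subject_id`, `label`
#' and `segment_index` per segment.
#'
#' @seealso [buildFeatureTable()], [subsetLobe()], [featureMatrix()]
#' @export
#' @import SummarizedExperiment
setClass("FeatureTable", contains = "SummarizedExperiment")

setValidity("FeatureTable", function(object) {
  msg <- character()
  rd <- SummarizedExperiment::rowData(object)
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("channel", "imf", "feature") %in% colnames(rd)))
    msg <- c(msg, "rowData must have channel, imf, feature")
  if (!all(c("subject_id", "label") %in% colnames(cd)))
    msg <- c(msg, "colData must have subject_id, label")
  else if (!all(cd$label %in% c("SCH", "CONTROL")))
    msg <- c(msg, "labels must be 'SCH' or 'CONTROL'")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "feature names must be unique")
  if (length(msg)) msg else TRUE
})

#' EvaluationReport: classification metric panel
#'
#' Confusion matrix convention: rows = truth (CONTROL, SCH), columns =
#' predicted (CONTROL, SCH); the patient class SCH is positive. Metrics are
#' percentages.
#'
#' @slot metrics named numeric: Ac, SE, SP, PR, F1 (percent).
#' @slot confusion 2x2 integer matrix `[[TN, FP], [FN, TP]]`.
#' @slot auc area under the ROC curve (0-1) or NA.
#' @slot roc data.frame of ROC points (fpr, tpr, threshold).
#' @slot perFold optional per-fold accuracies (percent).
#' @export
setClass("EvaluationReport",
  representation(metrics = "numeric", confusion = "matrix", auc = "numeric",
                 roc = "data.frame", perFold = "numericOrNULL"))

#' LOOCVReport: subject-wise leave-one-out CV summary
#'
#' @slot perSubject named numeric; percent of each held-out subject's
#'   segments classified correctly.
#' @slot meanAccuracy unweighted mean of the per-subject accuracies.
#' @slot sdAccuracy sample SD of the per-subject accuracies.
#' @export
setClass("LOOCVReport",
  representation(perSubject = "numeric", meanAccuracy = "numeric",
                 sdAccuracy = "numeric"))

setValidity("LOOCVReport", function(object) {
  msg <- character()
  if (anyDuplicated(names(object@perSubject)))
    msg <- c(msg, "every subject must appear exactly once")
  if (any(object@perSubject < 0 | object@perSubject > 100))
    msg <- c(msg, "accuracies must be in [0, 100]")
  if (abs(object@meanAccuracy - mean(object@perSubject)) > 1e-8)
    msg <- c(msg, "meanAccuracy must equal the mean of perSubject")
  if (length(msg)) msg else TRUE
})

#' PairedComparison: paired t-test with Cohen's d
#'
#' @slot n number of pairs.
#' @slot meanDiff mean of the paired differences b - a.
#' @slot tStat paired t statistic.
#' @slot pValue two-sided p (NA when the differences have zero variance).
#' @slot cohensD paired effect size mean(d)/sd(d).
#' @export
setClass("PairedComparison",
  representation(n = "integer", meanDiff = "numeric", tStat = "numeric",
                 pValue = "numeric", cohensD = "numeric"))

#' ClassifierSpec: a (family, variant) entry of the classifier registry
#'
#' @slot family one of decision_tree, lda, logistic, naive_bayes, svm,
#'   knn, ensemble, mlp.
#' @slot variant registry variant name (e.g. svm kernel).
#' @slot params named list of fixed hyperparameters.
#' @seealso [classifierSpec()], [classifierRegistry()]
#' @export
setClass("ClassifierSpec",
  representation(family = "character", variant = "character",
                 params = "list"))

#' FittedModel: a trained classifier with its preprocessing bookkeeping
#'
#' @slot spec the [ClassifierSpec-class] used.
#' @slot fit the underlying fitted object.
#' @slot keep integer indices of the feature columns used (zero-variance
#'   columns are dropped at training time).
#' @slot levels class levels, `c("CONTROL", "SCH")`.
#' @export
setClass("FittedModel",
  representation(spec = "ClassifierSpec", fit = "ANY", keep = "integer",
                 levels = "character"))
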