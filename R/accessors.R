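#' @include AllClasses.R
NULL

#' Accessors for pipeline objects
#'
#' Small accessor generics used across the package instead of direct slot
#' access.
#'
#' @param object a package object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("channelLabels", function(object) standardGeneric("channelLabels"))
#' @rdname accessors
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("classLabel", function(object) standardGeneric("classLabel"))
#' @rdname accessors
#' @export
setGeneric("signalData", function(object) standardGeneric("signalData"))
#' @rdname accessors
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setGeneric("segments", function(object) standardGeneric("segments"))
#' @rdname accessors
#' @export
setGeneric("nSegments", function(object) standardGeneric("nSegments"))
#' @rdname accessors
#' @export
setGeneric("modes", function(object) standardGeneric("modes"))
#' @rdname accessors
#' @export
setGeneric("centerFreqs", function(object) standardGeneric("centerFreqs"))
#' @rdname accessors
#' @export
setGeneric("nModes", function(object) standardGeneric("nModes"))

#' @rdname accessors
#' @export
setMethod("samplingRate", "Recording", function(object) object@fs)
#' @rdname accessors
#' @export
setMethod("samplingRate", "SegmentedRecording", function(object) object@fs)
#' @rdname accessors
#' @export
setMethod("channelLabels", "Recording", function(object) object@channels)
#' @rdname accessors
#' @export
setMethod("channelLabels", "SegmentedRecording", function(object) object@channels)
#' @rdname accessors
#' @export
setMethod("subjectId", "Recording", function(object) object@subjectId)
#' @rdname accessors
#' @export
setMethod("subjectId", "SegmentedRecording", function(object) object@subjectId)
#' @rdname accessors
#' @export
setMethod("classLabel", "Recording", function(object) object@label)
#' @rdname accessors
#' @export
setMethod("classLabel", "SegmentedRecording", function(object) object@label)
#' @rdname accessors
#' @export
setMethod("signalData", "Recording", function(object) object@data)
#' @rdname accessors
#' @export
setMethod("nChannels", "Recording", function(object) length(object@channels))
#' @rdname accessors
#' @export
setMethod("segments", "SegmentedRecording", function(object) object@segments)
#' @rdname accessors
#' @export
setMethod("nSegments", "SegmentedRecording", function(object) length(object@segments))
#' @rdname accessors
#' @export
setMethod("modes", "VMDResult", function(object) object@modes)
#' @rdname accessors
#' @export
setMethod("centerFreqs", "VMDResult", function(object) object@centerFreqs)
#' @rdname accessors
#' @export
setMethod("nModes", "VMDResult", function(object) nrow(object@modes))

#' @rdname accessors
#' @export
setGeneric("converged", function(object) standardGeneric("converged"))
#' @rdname accessors
#' @export
setMethod("converged", "VMDResult", function(object) object@converged)

#' Feature-table accessors
#'
#' `featureMatrix` returns the segments x features matrix used by the
#' models; `subjectIds` and `segmentLabels` return per-segment metadata;
#' `channelOfFeature` maps every feature column to its channel label.
#'
#' @param object a [FeatureTable-class].
#' @name featureAccessors
NULL

#' @rdname featureAccessors
#' @export
setGeneric("featureMatrix", function(object) standardGeneric("featureMatrix"))
#' @rdname featureAccessors
#' @export
setMethod("featureMatrix", "FeatureTable", function(object)
  t(SummarizedExperiment::assay(object)))

#' @rdname featureAccessors
#' @export
setGeneric("subjectIds", function(object) standardGeneric("subjectIds"))
#' @rdname featureAccessors
#' @export
setMethod("subjectIds", "FeatureTable", function(object)
  as.character(SummarizedExperiment::colData(object)$subject_id))

#' @rdname featureAccessors
#' @export
setGeneric("segmentLabels", function(object) standardGeneric("segmentLabels"))
#' @rdname featureAccessors
#' @export
setMethod("segmentLabels", "FeatureTable", function(object)
  factor(SummarizedExperiment::colData(object)$label,
         levels = c("CONTROL", "SCH")))

#' @rdname featureAccessors
#' @export
setGeneric("channelOfFeature", function(object) standardGeneric("channelOfFeature"))
#' @rdname featureAccessors
#' @export
setMethod("channelOfFeature", "FeatureTable", function(object)
  setNames(as.character(SummarizedExperiment::rowData(object)$channel),
           rownames(object)))

#' Evaluation-report accessors
#'
#' @param object an [EvaluationReport-class], [LOOCVReport-class] or
#'   [PairedComparison-class].
#' @name reportAccessors
NULL

#' @rdname reportAccessors
#' @export
setGeneric("metrics", function(object) standardGeneric("metrics"))
#' @rdname reportAccessors
#' @export
setMethod("metrics", "EvaluationReport", function(object) object@metrics)

#' @rdname reportAccessors
#' @export
setGeneric("confusionMatrix", function(object) standardGeneric("confusionMatrix"))
#' @rdname reportAccessors
#' @export
setMethod("confusionMatrix", "EvaluationReport", function(object) object@confusion)

#' @rdname reportAccessors
#' @export
setGeneric("rocPoints", function(object) standardGeneric("rocPoints"))
#' @rdname reportAccessors
#' @export
setMethod("rocPoints", "EvaluationReport", function(object) object@roc)

#' @rdname reportAccessors
#' @export
setGeneric("aucValue", function(object) standardGeneric("aucValue"))
#' @rdname reportAccessors
#' @export
setMethod("aucValue", "EvaluationReport", function(object) object@auc)

#' @rdname reportAccessors
#' @export
setGeneric("perSubjectAccuracy", function(object) standardGeneric("perSubjectAccuracy"))
#' @rdname reportAccessors
#' @export
setMethod("perSubjectAccuracy", "LOOCVReport", function(object) object@perSubject)

#' @rdname reportAccessors
#' @export
setGeneric("meanAccuracy", function(object) standardGeneric("meanAccuracy"))
#' @rdname reportAccessors
#' @export
setMethod("meanAccuracy", "LOOCVReport", function(object) object@meanAccuracy)

#' @rdname reportAccessors
#' @export
setGeneric("sdAccuracy", function(object) standardGeneric("sdAccuracy"))
#' @rdname reportAccessors
#' @export
setMethod("sdAccuracy", "LOOCVReport", function(object) object@sdAccuracy)

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording '%s' [%s]: %d channels x %d samples @ %g Hz\n",
              object@subjectId, object@label, nrow(object@data),
              ncol(object@data), object@fs))
  cat("  channels:", paste(object@channels, collapse = " "), "\n")
})

setMethod("show", "SegmentedRecording", function(object) {
  cat(sprintf(
    "SegmentedRecording '%s' [%s]: %d segments of %gs (%d channels @ %g Hz)\n",
    object@subjectId, object@label, length(object@segments),
    object@windowSeconds, length(object@channels), object@fs))
})

setMethod("show", "VMDResult", function(object) {
  cat(sprintf("VMDResult: %d modes, %d samples @ %g Hz (%s in %d iter)\n",
              nrow(object@modes), ncol(object@modes), object@fs,
              if (object@converged) "converged" else "not converged",
              object@nIter))
  cat("  center frequencies (Hz):",
      paste(sprintf("%.2f", object@centerFreqs), collapse = " "), "\n")
})

setMethod("show", "FeatureTable", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat(sprintf("FeatureTable: %d features x %d segments (%d subjects; %d SCH / %d CONTROL segments)\n",
              nrow(object), ncol(object), length(unique(cd$subject_id)),
              sum(cd$label == "SCH"), sum(cd$label == "CONTROL")))
})

setMethod("show", "EvaluationReport", function(object) {
  m <- object@metrics
  cat(sprintf("EvaluationReport: Ac %.2f%%  SE %.2f%%  SP %.2f%%  PR %.2f%%  F1 %.2f%%  AUC %.3f\n",
              m["Ac"], m["SE"], m["SP"], m["PR"], m["F1"], object@auc))
  print(object@confusion)
})

setMethod("show", "LOOCVReport", function(object) {
  cat(sprintf("LOOCVReport: %d subjects, mean Ac %.2f%% (SD %.2f%%)\n",
              length(object@perSubject), object@meanAccuracy,
              object@sdAccuracy))
})

setMethod("show", "PairedComparison", function(object) {
  cat(sprintf("PairedComparison: n=%d, mean diff %.3f, t=%.3f, p=%.4g, Cohen's d=%.3f\n",
              object@n, object@meanDiff, object@tStat, object@pValue,
              object@cohensD))
})

setMethod("show", "ClassifierSpec", function(object) {
  cat(sprintf("ClassifierSpec: %s / %s\n", object@family, object@variant))
  if (length(object@params))
    cat("  params:", paste(names(object@params),
        vapply(object@params, function(p) paste(format(p), collapse = ","),
               ""), sep = "=", collapse = " "), "\n")
})
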