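#' @include validation.R
NULL

#' Published per-subject LOOCV accuracies
#'
#' Per-subject subject-wise LOOCV accuracies reported for the MHRC (39
#' subjects) and RepOD (14 subjects) cohorts, shipped as plain text in
#' `extdata/loocv_subject_accuracy.csv`. Useful as input to
#' [loocvReport()] to reproduce the published aggregation (mean accuracy
#' 81.55% for MHRC, 83.97% for RepOD).
#'
#' @param dataset `"MHRC"` or `"RepOD"`.
#' @return named numeric vector of per-subject accuracies (percent).
#' @examples
#' meanAccuracy(loocvReport(referenceLOOCVAccuracies("MHRC")))
#' @export
referenceLOOCVAccuracies <- function(dataset = c("MHRC", "RepOD")) {
  dataset <- match.arg(dataset)
  df <- read.csv(system.file("extdata", "loocv_subject_accuracy.csv",
                             package = "vmdEEG"))
  df <- df[df$dataset == dataset, ]
  setNames(df$accuracy, paste0("subject", df$subject))
}
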