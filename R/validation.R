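#' @include models.R bayesopt.R
NULL

#' Stratified cross-validation folds
#'
#' Thin seeded wrapper around [caret::createFolds()]; returns test-index
#' vectors whose class proportions match the full data.
#'
#' @param y labels.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return list of k integer vectors (test indices).
#' @export
stratifiedFolds <- function(y, k, seed = 1L) {
  y <- factor(y)
  if (k > length(y))
    stop("k = ", k, " exceeds the number of observations")
  set.seed(seed)
  if (min(table(y)) >= k) {
    caret::createFolds(y, k = k, list = TRUE, returnTrain = FALSE)
  } else {
    # classes smaller than k (e.g. leave-one-segment-out): plain folds
    split(sample(seq_along(y)), rep_len(seq_len(k), length(y)))
  }
}

#' Stratified k-fold cross-validation of a classifier
#'
#' Segment-level stratified folds; the z-score normalizer is fit on each
#' training fold only (leakage-safe) and applied to the held-out fold.
#' Predictions are pooled across folds into a single confusion matrix and
#' ROC.
#'
#' @param spec a [ClassifierSpec-class].
#' @param tab a [FeatureTable-class].
#' @param k number of folds.
#' @param seed RNG seed (folds and stochastic learners).
#' @return an [EvaluationReport-class] with per-fold accuracies.
#' @export
kfoldCV <- function(spec, tab, k = 10L, seed = 1L) {
  X <- featureMatrix(tab)
  y <- segmentLabels(tab)
  folds <- stratifiedFolds(y, k, seed = seed)
  pred <- factor(rep(NA, length(y)), levels = CLASS_LEVELS)
  score <- numeric(length(y))
  perFold <- numeric(length(folds))
  for (i in seq_along(folds)) {
    test <- folds[[i]]
    norm <- fitNormalizer(X[-test, , drop = FALSE])
    model <- trainClassifier(spec, applyNormalizer(norm,
                               X[-test, , drop = FALSE]),
                             y[-test], seed = seed)
    p <- predictClassifier(model, applyNormalizer(norm,
                             X[test, , drop = FALSE]))
    pred[test] <- p$class
    score[test] <- p$score
    perFold[i] <- 100 * mean(p$class == y[test])
  }
  evaluationReport(y, pred, score, perFold = perFold)
}

#' Build a LOOCV report from per-subject accuracies
#'
#' Aggregation used for subject-wise LOOCV: the summary mean is the
#' unweighted arithmetic mean of the per-subject accuracies (not the
#' segment-pooled accuracy), and the SD is the sample SD over subjects.
#'
#' @param perSubject named numeric vector of per-subject accuracies in
#'   percent.
#' @return a [LOOCVReport-class].
#' @examples
#' loocvReport(c(s1 = 100, s2 = 50, s3 = 75))
#' @export
loocvReport <- function(perSubject) {
  new("LOOCVReport", perSubject = perSubject,
      meanAccuracy = mean(perSubject),
      sdAccuracy = sd(perSubject))
}

#' Subject-wise leave-one-out cross-validation
#'
#' For each subject, trains on all other subjects' segments (normalizer
#' fit on the training subjects only) and classifies the held-out
#' subject's segments; the per-subject accuracy is the fraction of that
#' subject's segments classified correctly. Prevents within-subject
#' leakage entirely.
#'
#' @param spec a [ClassifierSpec-class], or a family name with
#'   `optimizePerFold = TRUE`.
#' @param tab a [FeatureTable-class] with >= 3 subjects, both classes
#'   represented.
#' @param seed RNG seed.
#' @param optimizePerFold if `TRUE`, re-runs [bayesOptimize()] inside each
#'   training fold (expensive); by default one fixed configuration is
#'   reused across folds.
#' @param optCfg an [optimizationConfig()] for `optimizePerFold`.
#' @return a [LOOCVReport-class].
#' @export
subjectLOOCV <- function(spec, tab, seed = 1L, optimizePerFold = FALSE,
                         optCfg = optimizationConfig()) {
  X <- featureMatrix(tab)
  y <- segmentLabels(tab)
  subj <- subjectIds(tab)
  ids <- unique(subj)
  if (length(ids) < 3) stop("subject-wise LOOCV requires >= 3 subjects")
  if (nlevels(droplevels(y)) < 2)
    stop("both classes must be represented")
  acc <- setNames(numeric(length(ids)), ids)
  for (s in ids) {
    test <- which(subj == s)
    if (!length(test)) stop("subject ", s, " has zero segments")
    stopifnot(length(intersect(subj[-test], s)) == 0)
    norm <- fitNormalizer(X[-test, , drop = FALSE])
    foldSpec <- spec
    if (optimizePerFold) {
      opt <- bayesOptimize(if (is(spec, "ClassifierSpec")) spec@family
                           else spec,
                           applyNormalizer(norm, X[-test, , drop = FALSE]),
                           y[-test], optCfg)
      foldSpec <- opt$spec
    }
    model <- trainClassifier(foldSpec, applyNormalizer(norm,
                               X[-test, , drop = FALSE]),
                             y[-test], seed = seed)
    p <- predictClassifier(model, applyNormalizer(norm,
                             X[test, , drop = FALSE]))
    acc[s] <- 100 * mean(p$class == y[test])
  }
  loocvReport(acc)
}

#' Lobe-wise evaluation sweep
#'
#' Evaluates every classifier spec on every lobe's feature subset with
#' identical folds (common seed) so comparisons are paired, and reports
#' the best spec per lobe by accuracy (ties resolve to the first spec in
#' input order).
#'
#' @param specs list of [ClassifierSpec-class] objects.
#' @param tab a [FeatureTable-class].
#' @param montage channel -> lobe map.
#' @param lobes lobes to sweep (default: the five standard lobes present
#'   in the table's montage).
#' @param k,seed CV settings passed to [kfoldCV()].
#' @return list with `results` (data.frame: lobe, family, variant, the
#'   metric panel), `reports` (named list of [EvaluationReport-class]),
#'   and `best_per_lobe` (data.frame).
#' @export
lobewiseSweep <- function(specs, tab, montage = defaultMontage(),
                          lobes = NULL, k = 10L, seed = 1L) {
  if (is(specs, "ClassifierSpec")) specs <- list(specs)
  chans <- unique(unname(channelOfFeature(tab)))
  if (is.null(lobes))
    lobes <- LOBES[vapply(LOBES, function(l)
      length(lobeChannels(chans, l, montage)) > 0, TRUE)]
  rows <- list()
  reports <- list()
  for (lobe in lobes) {
    sub <- subsetLobe(tab, lobe, montage)
    for (si in seq_along(specs)) {
      rep <- kfoldCV(specs[[si]], sub, k = k, seed = seed)
      key <- paste(lobe, specs[[si]]@family, specs[[si]]@variant,
                   sep = ":")
      reports[[key]] <- rep
      rows[[key]] <- data.frame(lobe = lobe,
                                family = specs[[si]]@family,
                                variant = specs[[si]]@variant,
                                spec_index = si,
                                t(metrics(rep)))
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  best <- do.call(rbind, lapply(split(results, results$lobe), function(d) {
    d[order(-d$Ac, d$spec_index), ][1, ]
  }))
  rownames(best) <- NULL
  list(results = results, reports = reports, best_per_lobe = best)
}

#' Paired comparison of two performance vectors
#'
#' Two-sided paired t-test on the differences `d = b - a`
#' (`t = mean(d) / (sd(d) / sqrt(n))`, p from the t distribution with
#' n - 1 df) and the paired Cohen's d `mean(d) / sd(d)`. Zero-variance
#' differences make t/p undefined: for `a == b` the result is t = 0,
#' p = 1; for a constant nonzero difference, p and d are NA with a
#' warning.
#'
#' @param a,b numeric vectors of equal length >= 2 (e.g. accuracies in
#'   percent).
#' @return a [PairedComparison-class].
#' @export
pairedComparison <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2)
    stop("a and b must have equal length >= 2")
  d <- b - a
  n <- length(d)
  md <- mean(d)
  sdd <- sd(d)
  if (sdd == 0) {
    if (md == 0)
      return(new("PairedComparison", n = as.integer(n), meanDiff = 0,
                 tStat = 0, pValue = 1, cohensD = 0))
    warning(warningCondition(
      "zero-variance nonzero differences: t/p/d undefined",
      class = "vmdEEG_sentinel"))
    return(new("PairedComparison", n = as.integer(n), meanDiff = md,
               tStat = NA_real_, pValue = NA_real_, cohensD = NA_real_))
  }
  t <- md / (sdd / sqrt(n))
  new("PairedComparison", n = as.integer(n), meanDiff = md, tStat = t,
      pValue = 2 * pt(-abs(t), df = n - 1), cohensD = md / sdd)
}
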