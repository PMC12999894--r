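#' @include AllClasses.R dataset.R
NULL

CLASS_LEVELS <- c("CONTROL", "SCH")

# registry of supported (family, variant) combinations with their fixed
# parameters; variants mirror the usual app-style naming (fine/medium/
# coarse trees, quadratic/cubic SVM, Gaussian kernel scales sqrt(d)/4,
# sqrt(d), 4*sqrt(d), ...)
REGISTRY <- list(
  decision_tree = list(
    fine = list(maxdepth = 30L, minbucket = 1L),
    medium = list(maxdepth = 8L, minbucket = 5L),
    coarse = list(maxdepth = 3L, minbucket = 10L),
    custom = list()),
  lda = list(linear = list()),
  logistic = list(glm = list()),
  naive_bayes = list(gaussian = list()),
  svm = list(
    linear = list(kernel = "linear", cost = 1),
    quadratic = list(kernel = "polynomial", degree = 2L, cost = 1),
    cubic = list(kernel = "polynomial", degree = 3L, cost = 1),
    fine_gaussian = list(kernel = "radial", scale_factor = 0.25, cost = 1),
    medium_gaussian = list(kernel = "radial", scale_factor = 1, cost = 1),
    coarse_gaussian = list(kernel = "radial", scale_factor = 4, cost = 1),
    rbf = list(kernel = "radial", cost = 1),
    custom = list()),
  knn = list(
    fine = list(k = 1L),
    medium = list(k = 10L),
    coarse = list(k = 100L),
    cosine = list(k = 10L, metric = "cosine"),
    weighted = list(k = 10L, weight = "distance"),
    custom = list()),
  ensemble = list(
    bagging = list(n_estimators = 100L),
    adaboost = list(n_estimators = 50L, learning_rate = 0.1,
                    maxdepth = 1L),
    random_subspace = list(n_estimators = 30L, base = "knn"),
    custom = list()),
  mlp = list(
    narrow = list(size = 10L, decay = 1e-4),
    medium = list(size = 25L, decay = 1e-4),
    wide = list(size = 100L, decay = 1e-4),
    custom = list()))

#' Classifier registry
#'
#' Lists the supported classifier families and variants.
#'
#' @return named list: family -> variant names.
#' @export
classifierRegistry <- function() lapply(REGISTRY, names)

#' Construct a ClassifierSpec
#'
#' @param family classifier family (see [classifierRegistry()]).
#' @param variant variant within the family; `"custom"` takes all
#'   hyperparameters from `params`.
#' @param params named list of hyperparameter overrides.
#' @return a [ClassifierSpec-class].
#' @examples
#' classifierSpec("svm", "cubic")
#' classifierSpec("knn", "custom", params = list(k = 7, weight = "distance"))
#' @export
classifierSpec <- function(family, variant = NULL, params = list()) {
  if (!family %in% names(REGISTRY))
    stop("unknown classifier family: ", family)
  if (is.null(variant)) variant <- names(REGISTRY[[family]])[1]
  if (!variant %in% names(REGISTRY[[family]]))
    stop("unknown variant '", variant, "' for family ", family)
  defaults <- REGISTRY[[family]][[variant]]
  defaults[names(params)] <- params
  new("ClassifierSpec", family = family, variant = variant,
      params = defaults)
}

asFactorY <- function(y) {
  y <- factor(as.character(y), levels = CLASS_LEVELS)
  if (anyNA(y)) stop("labels must be 'SCH' or 'CONTROL'")
  y
}

# ---------------------------------------------------------------------------
# k-NN with the metrics and weighting of the search space (the installed
# class::knn supports neither cityblock/cosine distances nor distance
# weighting)

knnDistance <- function(trainX, testX, metric) {
  switch(metric,
    euclidean = {
      d2 <- outer(rowSums(testX^2), rowSums(trainX^2), "+") -
        2 * testX %*% t(trainX)
      sqrt(pmax(d2, 0))
    },
    cityblock = t(apply(testX, 1, function(r)
      colSums(abs(t(trainX) - r)))),
    cosine = {
      nt <- sqrt(rowSums(testX^2))
      ntr <- sqrt(rowSums(trainX^2))
      sim <- (testX %*% t(trainX)) / (pmax(nt, 1e-12) %o% pmax(ntr, 1e-12))
      1 - sim
    },
    stop("unknown knn metric: ", metric))
}

knnScore <- function(trainX, trainY, testX, k, metric = "euclidean",
                     weight = "uniform") {
  trainX <- as.matrix(trainX)
  testX <- as.matrix(testX)
  k <- min(as.integer(k), nrow(trainX))
  D <- knnDistance(trainX, testX, metric)
  pos <- trainY == "SCH"
  vapply(seq_len(nrow(testX)), function(i) {
    ord <- order(D[i, ])[seq_len(k)]
    w <- if (weight == "distance") 1 / (D[i, ord] + 1e-12) else rep(1, k)
    sum(w[pos[ord]]) / sum(w)
  }, 0)
}

# ---------------------------------------------------------------------------
# AdaBoost.M1 over shallow rpart trees (discrete SAMME)

adaboostFit <- function(X, y, n_estimators, learning_rate, maxdepth) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  df <- data.frame(y = y, X)
  learners <- list()
  alphas <- numeric()
  for (t in seq_len(n_estimators)) {
    fit <- rpart::rpart(y ~ ., data = df, weights = w,
                        control = rpart::rpart.control(
                          maxdepth = maxdepth, cp = 0, minsplit = 2,
                          xval = 0))
    pred <- predict(fit, df, type = "class")
    err <- sum(w[pred != y]) / sum(w)
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    alpha <- learning_rate * log((1 - err) / err)
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
    learners[[t]] <- fit
    alphas[t] <- alpha
    if (err < 1e-9) break
  }
  if (!length(learners)) {   # first stump already too weak: keep it anyway
    learners[[1]] <- rpart::rpart(y ~ ., data = df,
      control = rpart::rpart.control(maxdepth = maxdepth, cp = 0,
                                     minsplit = 2, xval = 0))
    alphas <- 1
  }
  list(learners = learners, alphas = alphas, cols = colnames(X))
}

adaboostScore <- function(fit, X) {
  df <- data.frame(X)
  colnames(df) <- fit$cols
  num <- numeric(nrow(df))
  for (t in seq_along(fit$learners)) {
    pred <- predict(fit$learners[[t]], df, type = "class")
    num <- num + fit$alphas[t] * ifelse(pred == "SCH", 1, -1)
  }
  # margin -> [0, 1]
  1 / (1 + exp(-2 * num / sum(fit$alphas)))
}

# ---------------------------------------------------------------------------
# random-subspace ensemble (feature bagging) over 1-NN or LDA base learners

subspaceFit <- function(X, y, n_estimators, base) {
  p <- ncol(X)
  d <- max(1L, floor(p / 2))
  subs <- lapply(seq_len(n_estimators), function(i) sort(sample.int(p, d)))
  list(subs = subs, base = base, X = X, y = y)
}

subspaceScore <- function(fit, X) {
  scores <- vapply(fit$subs, function(idx) {
    if (fit$base == "knn") {
      knnScore(fit$X[, idx, drop = FALSE], fit$y, X[, idx, drop = FALSE],
               k = 1)
    } else {
      f <- MASS::lda(fit$X[, idx, drop = FALSE], grouping = fit$y)
      predict(f, X[, idx, drop = FALSE])$posterior[, "SCH"]
    }
  }, numeric(nrow(X)))
  rowMeans(matrix(scores, nrow = nrow(X)))
}

# ---------------------------------------------------------------------------

#' Train a classifier
#'
#' Fits the specified classifier; all models are deterministic given
#' `seed`. Zero-variance feature columns are dropped (and re-dropped at
#' prediction). The fitted model supports class predictions and a
#' continuous decision score for ROC analysis via [predictClassifier()].
#'
#' @param spec a [ClassifierSpec-class] (or the output of
#'   [classifierSpec()]).
#' @param X numeric feature matrix (rows = observations), finite.
#' @param y class labels; both classes must be present.
#' @param seed RNG seed for stochastic learners.
#' @return a [FittedModel-class].
#' @export
trainClassifier <- function(spec, X, y, seed = 1L) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("X must be finite")
  y <- asFactorY(y)
  if (nlevels(droplevels(y)) < 2)
    stop("both classes must be present in y")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  keep <- which(apply(X, 2, function(col) diff(range(col)) > 0))
  if (!length(keep)) keep <- 1L
  Xk <- X[, keep, drop = FALSE]
  pars <- spec@params
  set.seed(seed)
  fit <- switch(spec@family,
    decision_tree = rpart::rpart(y ~ ., data = data.frame(y = y, Xk),
      method = "class",
      control = rpart::rpart.control(
        maxdepth = min(pars$maxdepth %||% 30L, 30L),
        minbucket = pars$minbucket %||% 1L, cp = 0, xval = 0)),
    lda = MASS::lda(Xk, grouping = y),
    logistic = suppressWarnings(glm(y ~ ., data = data.frame(y = y, Xk),
                                    family = binomial())),
    naive_bayes = e1071::naiveBayes(Xk, y),
    svm = {
      scale_factor <- pars$scale_factor
      gamma <- if (!is.null(pars$kernel_scale)) 1 / pars$kernel_scale^2
               else if (!is.null(scale_factor))
                 1 / (scale_factor * sqrt(ncol(Xk)))^2
               else 1 / ncol(Xk)
      e1071::svm(Xk, y, kernel = pars$kernel %||% "radial",
                 degree = pars$degree %||% 3L, gamma = gamma,
                 cost = pars$cost %||% 1, coef0 = 1, scale = FALSE)
    },
    knn = list(X = Xk, y = y, k = pars$k %||% 5L,
               metric = pars$metric %||% "euclidean",
               weight = pars$weight %||% "uniform"),
    ensemble = switch(pars$method %||% spec@variant,
      bagging = randomForest::randomForest(Xk, y,
        ntree = pars$n_estimators %||% 100L),
      adaboost = adaboostFit(Xk, y,
        n_estimators = pars$n_estimators %||% 50L,
        learning_rate = pars$learning_rate %||% 0.1,
        maxdepth = pars$maxdepth %||% 1L),
      random_subspace = subspaceFit(Xk, y,
        n_estimators = pars$n_estimators %||% 30L,
        base = pars$base %||% "knn"),
      stop("unknown ensemble method")),
    mlp = nnet::nnet(Xk, ifelse(y == "SCH", 1, 0),
                     size = pars$size %||% 10L,
                     decay = pars$decay %||% 1e-4, maxit = 300,
                     trace = FALSE, MaxNWts = 1e6),
    stop("unknown family: ", spec@family))
  new("FittedModel", spec = spec, fit = fit, keep = as.integer(keep),
      levels = CLASS_LEVELS)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict classes and decision scores
#'
#' @param model a [FittedModel-class].
#' @param X feature matrix with the training columns.
#' @return list with `class` (factor CONTROL/SCH) and `score` (continuous,
#'   larger = more SCH-like; a probability where the learner provides one).
#' @export
predictClassifier <- function(model, X) {
  X <- as.matrix(X)
  Xk <- X[, model@keep, drop = FALSE]
  pars <- model@spec@params
  score <- switch(model@spec@family,
    decision_tree = predict(model@fit, data.frame(Xk), type = "prob")[, "SCH"],
    lda = predict(model@fit, Xk)$posterior[, "SCH"],
    logistic = as.numeric(predict(model@fit, data.frame(Xk),
                                  type = "response")),
    naive_bayes = predict(model@fit, Xk, type = "raw")[, "SCH"],
    svm = {
      dv <- attr(predict(model@fit, Xk, decision.values = TRUE),
                 "decision.values")
      if (grepl("^SCH", colnames(dv)[1])) as.numeric(dv)
      else -as.numeric(dv)
    },
    knn = knnScore(model@fit$X, model@fit$y, Xk, k = model@fit$k,
                   metric = model@fit$metric, weight = model@fit$weight),
    ensemble = switch(pars$method %||% model@spec@variant,
      bagging = predict(model@fit, Xk, type = "prob")[, "SCH"],
      adaboost = adaboostScore(model@fit, Xk),
      random_subspace = subspaceScore(model@fit, Xk)),
    mlp = as.numeric(predict(model@fit, Xk)))
  thr <- if (model@spec@family == "svm") 0 else 0.5
  cls <- factor(ifelse(score > thr, "SCH", "CONTROL"),
                levels = CLASS_LEVELS)
  list(class = cls, score = as.numeric(score))
}

# ---------------------------------------------------------------------------

#' Build an evaluation report from predictions
#'
#' Computes the metric panel with SCH as the positive class:
#' `Ac = (TP+TN)/N`, `SE = TP/(TP+FN)`, `SP = TN/(TN+FP)`,
#' `PR = TP/(TP+FP)`, `F1 = 2*PR*SE/(PR+SE)` (percent), the confusion
#' matrix `[[TN, FP], [FN, TP]]`, and ROC points/AUC from the decision
#' scores. A degenerate all-negative predictor yields `PR = 0` with a
#' warning.
#'
#' @param truth true labels.
#' @param pred predicted labels.
#' @param score decision scores (optional; without them no ROC/AUC).
#' @param perFold optional per-fold accuracies to carry along.
#' @return an [EvaluationReport-class].
#' @export
evaluationReport <- function(truth, pred, score = NULL, perFold = NULL) {
  truth <- asFactorY(truth)
  pred <- asFactorY(pred)
  tp <- sum(truth == "SCH" & pred == "SCH")
  tn <- sum(truth == "CONTROL" & pred == "CONTROL")
  fp <- sum(truth == "CONTROL" & pred == "SCH")
  fn <- sum(truth == "SCH" & pred == "CONTROL")
  pr <- if (tp + fp == 0) {
    warning("degenerate predictions: no positive calls; PR set to 0")
    0
  } else 100 * tp / (tp + fp)
  se <- if (tp + fn == 0) 0 else 100 * tp / (tp + fn)
  sp <- if (tn + fp == 0) 0 else 100 * tn / (tn + fp)
  metrics <- c(Ac = 100 * (tp + tn) / length(truth), SE = se, SP = sp,
               PR = pr, F1 = f1Score(se, pr))
  conf <- matrix(as.integer(c(tn, fp, fn, tp)), 2, 2, byrow = TRUE,
                 dimnames = list(truth = CLASS_LEVELS,
                                 predicted = CLASS_LEVELS))
  auc <- NA_real_
  rocdf <- data.frame(fpr = numeric(), tpr = numeric(),
                      threshold = numeric())
  if (!is.null(score) && length(unique(truth)) == 2 &&
      length(unique(score)) > 1) {
    r <- pROC::roc(response = truth, predictor = as.numeric(score),
                   levels = CLASS_LEVELS, direction = "<", quiet = TRUE)
    auc <- as.numeric(pROC::auc(r))
    rocdf <- data.frame(fpr = 1 - r$specificities, tpr = r$sensitivities,
                        threshold = r$thresholds)
  }
  new("EvaluationReport", metrics = metrics, confusion = conf, auc = auc,
      roc = rocdf, perFold = perFold)
}

#' Evaluate a fitted model on labeled data
#'
#' @param model a [FittedModel-class].
#' @param X feature matrix.
#' @param y true labels (both classes present).
#' @return an [EvaluationReport-class].
#' @export
evaluateModel <- function(model, X, y) {
  y <- asFactorY(y)
  if (nlevels(droplevels(y)) < 2)
    stop("both classes must be present in y")
  p <- predictClassifier(model, X)
  evaluationReport(y, p$class, p$score)
}
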