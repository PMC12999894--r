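#' @include models.R
NULL

#' Optimization configuration
#'
#' Bayesian optimization of the cross-validated misclassification rate:
#' a Gaussian-process surrogate with expected-improvement acquisition,
#' 30 objective evaluations by default (5-point space-filling initial
#' design, then GP/EI proposals), 10-fold stratified CV objective.
#'
#' @param n_iterations total objective evaluations.
#' @param n_folds CV folds for the objective.
#' @param n_init initial space-filling design points.
#' @param seed RNG seed.
#' @param xi EI exploration parameter.
#' @return a list of class `OptimizationConfig`.
#' @export
optimizationConfig <- function(n_iterations = 30L, n_folds = 10L,
                               n_init = 5L, seed = 1L, xi = 0.01) {
  if (n_iterations < 1) stop("config error: n_iterations must be >= 1")
  if (n_folds < 2) stop("config error: n_folds must be >= 2")
  structure(list(n_iterations = as.integer(n_iterations),
                 n_folds = as.integer(n_folds),
                 n_init = as.integer(min(n_init, n_iterations)),
                 seed = as.integer(seed), xi = xi),
            class = "OptimizationConfig")
}

#' Hyperparameter search spaces
#'
#' Returns the per-family search space: a list of dimensions, each with a
#' name, type (`num`, `int` or `cat`), bounds (log-scaled where noted) or
#' levels.
#'
#' @param family classifier family.
#' @param n_features feature count of the data (used by kernel scales).
#' @return list of dimension descriptors.
#' @export
searchSpace <- function(family, n_features = 10L) {
  switch(family,
    decision_tree = list(
      list(name = "maxdepth", type = "int", lower = 1, upper = 30),
      list(name = "minbucket", type = "int", lower = 1, upper = 50)),
    svm = list(
      list(name = "cost", type = "num", lower = 1e-3, upper = 1e3,
           log = TRUE),
      list(name = "kernel_scale", type = "num", lower = 1e-3, upper = 1e3,
           log = TRUE),
      list(name = "kernel", type = "cat",
           levels = c("linear", "polynomial", "radial"))),
    knn = list(
      list(name = "k", type = "int", lower = 1, upper = 30),
      list(name = "metric", type = "cat",
           levels = c("euclidean", "cityblock", "cosine")),
      list(name = "weight", type = "cat",
           levels = c("uniform", "distance"))),
    ensemble = list(
      list(name = "method", type = "cat",
           levels = c("bagging", "adaboost", "random_subspace")),
      list(name = "n_estimators", type = "int", lower = 10, upper = 300),
      list(name = "learning_rate", type = "num", lower = 0.01, upper = 1,
           log = TRUE)),
    mlp = list(
      list(name = "size", type = "int", lower = 5, upper = 300),
      list(name = "decay", type = "num", lower = 1e-6, upper = 1e-1,
           log = TRUE)),
    lda = list(),
    logistic = list(),
    naive_bayes = list(),
    stop("unknown family: ", family))
}

decodeUnit <- function(u, space) {
  out <- list()
  for (j in seq_along(space)) {
    d <- space[[j]]
    out[[d$name]] <- switch(d$type,
      num = {
        if (isTRUE(d$log))
          exp(log(d$lower) + u[j] * (log(d$upper) - log(d$lower)))
        else d$lower + u[j] * (d$upper - d$lower)
      },
      int = {
        v <- if (isTRUE(d$log))
          exp(log(d$lower) + u[j] * (log(d$upper) - log(d$lower)))
        else d$lower + u[j] * (d$upper - d$lower)
        as.integer(round(pmin(pmax(v, d$lower), d$upper)))
      },
      cat = d$levels[pmin(length(d$levels),
                          1L + floor(u[j] * length(d$levels)))],
      stop("bad dimension type"))
  }
  out
}

checkSpace <- function(space) {
  for (d in space) {
    if (d$type %in% c("num", "int")) {
      if (!is.finite(d$lower) || !is.finite(d$upper) || d$lower >= d$upper)
        stop("config error: invalid bounds for dimension '", d$name, "'")
      if (isTRUE(d$log) && d$lower <= 0)
        stop("config error: log-scaled dimension '", d$name,
             "' needs positive bounds")
    } else if (!length(d$levels)) {
      stop("config error: empty levels for dimension '", d$name, "'")
    }
  }
  invisible(TRUE)
}

# GP regression with squared-exponential kernel on the unit cube; the
# length scale and noise level are picked from a small grid by marginal
# likelihood
gpFit <- function(U, y) {
  n <- nrow(U)
  mu <- mean(y)
  sdy <- sd(y)
  if (!is.finite(sdy) || sdy == 0) sdy <- 1
  ys <- (y - mu) / sdy
  D2 <- as.matrix(dist(U))^2
  best <- NULL
  for (ell in c(0.05, 0.1, 0.2, 0.4, 0.8)) {
    for (s2n in c(1e-6, 1e-4, 1e-2)) {
      K <- exp(-D2 / (2 * ell^2)) + diag(s2n + 1e-8, n)
      ch <- tryCatch(chol(K), error = function(e) NULL)
      if (is.null(ch)) next
      alpha <- backsolve(ch, forwardsolve(t(ch), ys))
      ll <- -0.5 * sum(ys * alpha) - sum(log(diag(ch)))
      if (is.null(best) || ll > best$ll)
        best <- list(ll = ll, ell = ell, ch = ch, alpha = alpha,
                     mu = mu, sdy = sdy, U = U)
    }
  }
  best
}

gpPredict <- function(gp, Unew) {
  ks <- exp(-outer(rowSums(Unew^2), rowSums(gp$U^2), "+") /
              (2 * gp$ell^2) +
            (Unew %*% t(gp$U)) / gp$ell^2)
  mu <- as.numeric(ks %*% gp$alpha)
  v <- forwardsolve(t(gp$ch), t(ks))     # L^-1 k*, so s2 = 1 - ||v||^2
  s2 <- pmax(1 - colSums(v^2), 1e-12)
  list(mean = gp$mu + gp$sdy * mu, sd = gp$sdy * sqrt(s2))
}

#' Bayesian optimization of an arbitrary objective
#'
#' Minimizes `objective(params)` over the given search space with a
#' Gaussian-process surrogate and the expected-improvement acquisition.
#' Runs exactly `cfg$n_iterations` objective evaluations: `cfg$n_init`
#' space-filling (Latin hypercube) points, then EI proposals selected over
#' a random candidate set. Deterministic given `cfg$seed`; ties in the
#' final arg-min resolve to the earliest evaluation.
#'
#' @param objective function taking a named list of parameters, returning
#'   a scalar loss.
#' @param space search space as returned by [searchSpace()].
#' @param cfg an [optimizationConfig()].
#' @return list with `best_params`, `best_loss`, and a `trace` data.frame
#'   (iteration, loss, best_so_far, plus one column per parameter).
#' @examples
#' res <- bayesOptimizeFunction(function(p) (p$x - 0.3)^2,
#'   list(list(name = "x", type = "num", lower = 0, upper = 1)),
#'   optimizationConfig(n_iterations = 15, seed = 2))
#' res$best_params$x
#' @export
bayesOptimizeFunction <- function(objective, space,
                                  cfg = optimizationConfig()) {
  checkSpace(space)
  d <- length(space)
  set.seed(cfg$seed)
  U <- as.matrix(lhs::maximinLHS(cfg$n_init, max(d, 1L)))[, seq_len(d),
                                                          drop = FALSE]
  evalAt <- function(u) objective(decodeUnit(u, space))
  losses <- apply(U, 1, evalAt)
  while (length(losses) < cfg$n_iterations) {
    cand <- matrix(runif(256 * d), ncol = d)
    gp <- gpFit(U, losses)
    unext <- if (is.null(gp)) {
      cand[1, , drop = TRUE]
    } else {
      pr <- gpPredict(gp, cand)
      fbest <- min(losses)
      xi <- cfg$xi * gp$sdy              # exploration offset, scale-free
      z <- (fbest - pr$mean - xi) / pr$sd
      ei <- (fbest - pr$mean - xi) * pnorm(z) + pr$sd * dnorm(z)
      cand[which.max(ei), , drop = TRUE]
    }
    U <- rbind(U, unext)
    losses <- c(losses, evalAt(unext))
  }
  params <- lapply(seq_len(nrow(U)), function(i) decodeUnit(U[i, ], space))
  bestIdx <- which.min(losses)          # earliest minimum wins
  trace <- data.frame(iteration = seq_along(losses), loss = losses,
                      best_so_far = cummin(losses))
  if (d > 0) {
    pcols <- do.call(rbind, lapply(params, function(p)
      as.data.frame(p, stringsAsFactors = FALSE)))
    trace <- cbind(trace, pcols)
  }
  list(best_params = if (d > 0) params[[bestIdx]] else list(),
       best_loss = losses[bestIdx], trace = trace)
}

cvLossObjective <- function(family, X, y, cfg) {
  y <- asFactorY(y)
  folds <- stratifiedFolds(y, cfg$n_folds, seed = cfg$seed)
  function(params) {
    spec <- classifierSpec(family, "custom", params = params)
    errs <- vapply(folds, function(test) {
      norm <- fitNormalizer(X[-test, , drop = FALSE])
      model <- trainClassifier(spec, applyNormalizer(norm,
                                 X[-test, , drop = FALSE]),
                               y[-test], seed = cfg$seed)
      p <- predictClassifier(model, applyNormalizer(norm,
                               X[test, , drop = FALSE]))
      mean(p$class != y[test])
    }, 0)
    mean(errs)
  }
}

#' Bayesian hyperparameter optimization of a classifier family
#'
#' Minimizes the stratified `n_folds`-fold CV misclassification rate (with
#' fold-internal z-score normalization) over the family's search space
#' using [bayesOptimizeFunction()]. The same folds are reused for every
#' evaluation so comparisons between hyperparameter settings are paired.
#'
#' @param family classifier family name.
#' @param X feature matrix.
#' @param y labels.
#' @param cfg an [optimizationConfig()].
#' @return list with `best_params`, `best_cv_loss`, `trace`, and `spec`
#'   (the [ClassifierSpec-class] of the best configuration).
#' @export
bayesOptimize <- function(family, X, y, cfg = optimizationConfig()) {
  space <- searchSpace(family, n_features = ncol(X))
  if (!length(space))
    stop("family '", family, "' has no tunable search space")
  res <- bayesOptimizeFunction(cvLossObjective(family, X, y, cfg), space,
                               cfg)
  list(best_params = res$best_params, best_cv_loss = res$best_loss,
       trace = res$trace,
       spec = classifierSpec(family, "custom", params = res$best_params))
}
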