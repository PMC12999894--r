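separableXY <- function(n = 50, p = 4, gap = 3, seed = 1) {
  set.seed(seed)
  # class means differ in direction as well as location, so angular
  # metrics (cosine k-NN) can separate them too
  muA <- rep(c(gap, 0), length.out = p)
  muB <- rep(c(0, gap), length.out = p)
  X <- rbind(sweep(matrix(rnorm(n * p), n), 2, muA, "+"),
             sweep(matrix(rnorm(n * p), n), 2, muB, "+"))
  colnames(X) <- paste0("CHF3_IMF", seq_len(p), "_psd")
  list(X = X, y = rep(c("CONTROL", "SCH"), each = n))
}

test_that("every registry family separates linearly separable blobs", {
  d <- separableXY()
  combos <- list(c("decision_tree", "fine"), c("decision_tree", "coarse"),
                 c("lda", "linear"), c("logistic", "glm"),
                 c("naive_bayes", "gaussian"), c("svm", "linear"),
                 c("svm", "quadratic"), c("svm", "cubic"),
                 c("svm", "medium_gaussian"), c("knn", "fine"),
                 c("knn", "medium"), c("knn", "cosine"),
                 c("knn", "weighted"), c("ensemble", "bagging"),
                 c("ensemble", "adaboost"),
                 c("ensemble", "random_subspace"), c("mlp", "narrow"))
  for (cv in combos) {
    m <- trainClassifier(classifierSpec(cv[1], cv[2]), d$X, d$y, seed = 3)
    p <- predictClassifier(m, d$X)
    expect_gte(mean(p$class == d$y), 0.95)
    expect_length(p$score, nrow(d$X))
  }
})

test_that("1-NN memorizes its training set", {
  d <- separableXY(gap = 0.5)
  m <- trainClassifier(classifierSpec("knn", "fine"), d$X, d$y)
  expect_equal(mean(predictClassifier(m, d$X)$class == d$y), 1.0)
})

test_that("label-permuted data scores at chance under 10-fold CV", {
  accs <- vapply(1:10, function(s) {
    tab <- makeToyFeatureTable(n_subjects_per_class = 5,
                               segments_per_subject = 5, K = 1,
                               effect = 0, seed = 100 + s)
    metrics(kfoldCV(classifierSpec("knn", "medium"), tab, k = 10,
                    seed = s))["Ac"]
  }, 0)
  expect_lt(abs(mean(accs) - 50), 10)
  expect_true(all(accs > 25 & accs < 75))
})

test_that("degenerate labels are rejected", {
  d <- separableXY()
  expect_error(trainClassifier(classifierSpec("knn", "fine"), d$X,
                               rep("SCH", nrow(d$X))), "both classes")
  expect_error(classifierSpec("quantum_forest"), "unknown")
  expect_error(classifierSpec("svm", "septic"), "unknown variant")
})

test_that("the metric panel follows its defining identities", {
  y <- rep(c("CONTROL", "SCH"), each = 10)
  perfect <- evaluationReport(y, y, score = c(rep(0, 10), rep(1, 10)))
  expect_equal(unname(metrics(perfect)), rep(100, 5))
  expect_equal(aucValue(perfect), 1)

  expect_warning(
    allneg <- evaluationReport(y, rep("CONTROL", 20)),
    "degenerate")
  m <- metrics(allneg)
  expect_equal(unname(m[c("Ac", "SE", "SP", "PR")]), c(50, 0, 100, 0))

  set.seed(13)
  pred <- sample(y)
  r <- evaluationReport(y, pred, score = runif(20))
  m <- metrics(r)
  expect_equal(m[["F1"]],
               2 * m[["PR"]] * m[["SE"]] / (m[["PR"]] + m[["SE"]]))
  expect_equal(m[["Ac"]], (m[["SE"]] + m[["SP"]]) / 2)  # balanced classes
  cm <- confusionMatrix(r)
  expect_equal(sum(cm), 20)
  expect_equal(cm["SCH", "SCH"], sum(y == "SCH" & pred == "SCH"))
})

test_that("Bayesian optimization locates a known 1-D minimum within budget", {
  calls <- 0
  obj <- function(p) {
    calls <<- calls + 1
    (p$x - 0.3)^2
  }
  space <- list(list(name = "x", type = "num", lower = 0, upper = 1))
  res <- bayesOptimizeFunction(obj, space,
                               optimizationConfig(n_iterations = 30,
                                                  seed = 2))
  expect_equal(calls, 30)                         # never exceeds budget
  expect_lt(abs(res$best_params$x - 0.3), 0.05)
  expect_true(all(diff(res$trace$best_so_far) <= 0))
  res2 <- bayesOptimizeFunction(function(p) (p$x - 0.3)^2, space,
                                optimizationConfig(n_iterations = 30,
                                                   seed = 2))
  expect_identical(res$trace, res2$trace)         # same seed, same trace

  bad <- list(list(name = "x", type = "num", lower = 1, upper = 0))
  expect_error(bayesOptimizeFunction(obj, bad, optimizationConfig()),
               "config error")
})

test_that("CV-loss optimization beats a random-search baseline of equal budget", {
  wins <- vapply(1:5, function(s) {
    tab <- makeToyFeatureTable(n_subjects_per_class = 3,
                               segments_per_subject = 4, K = 1,
                               effect = 1.2, seed = 200 + s)
    X <- featureMatrix(tab)
    y <- segmentLabels(tab)
    cfg <- optimizationConfig(n_iterations = 20, n_folds = 5, seed = s)
    opt <- bayesOptimize("knn", X, y, cfg)
    objective <- vmdEEG:::cvLossObjective("knn", X, y, cfg)
    space <- searchSpace("knn")
    set.seed(1000 + s)
    rnd <- vapply(1:20, function(i) {
      u <- runif(length(space))
      objective(vmdEEG:::decodeUnit(u, space))
    }, 0)
    opt$best_cv_loss <= median(rnd)
  }, TRUE)
  expect_true(all(wins))
})

test_that("family-level optimization returns a trainable spec and its trace", {
  d <- separableXY(n = 25, gap = 1.5)
  opt <- bayesOptimize("knn", d$X, d$y,
                       optimizationConfig(n_iterations = 8, n_folds = 4,
                                          seed = 4))
  expect_s4_class(opt$spec, "ClassifierSpec")
  expect_equal(nrow(opt$trace), 8)
  expect_equal(min(opt$trace$loss), opt$best_cv_loss)
  expect_lte(opt$best_cv_loss, 0.3)
  m <- trainClassifier(opt$spec, d$X, d$y)
  expect_gt(mean(predictClassifier(m, d$X)$class == d$y), 0.85)
  expect_error(bayesOptimize("lda", d$X, d$y), "no tunable")
})
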