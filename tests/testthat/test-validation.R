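test_that("stratified k-fold CV is reproducible and supports k up to n", {
  tab <- makeToyFeatureTable(n_subjects_per_class = 3,
                             segments_per_subject = 5, K = 1,
                             effect = 2, seed = 31)   # 30 rows
  r1 <- kfoldCV(classifierSpec("knn", "medium"), tab, k = 10, seed = 7)
  r2 <- kfoldCV(classifierSpec("knn", "medium"), tab, k = 10, seed = 7)
  expect_identical(confusionMatrix(r1), confusionMatrix(r2))
  expect_length(r1@perFold, 10)

  loso <- kfoldCV(classifierSpec("knn", "fine"), tab, k = 30, seed = 1)
  expect_equal(sum(confusionMatrix(loso)), 30)
  expect_error(kfoldCV(classifierSpec("knn", "fine"), tab, k = 31),
               "exceeds")

  # a clear class contrast is found by CV
  expect_gte(metrics(r1)["Ac"], 90)
})

test_that("subject-wise LOOCV keeps subjects disjoint and averages per subject", {
  tab <- makeToyFeatureTable(n_subjects_per_class = 4,
                             segments_per_subject = 4, K = 1,
                             effect = 2, seed = 32)
  rep <- subjectLOOCV(classifierSpec("knn", "medium"), tab, seed = 1)
  ps <- perSubjectAccuracy(rep)
  expect_setequal(names(ps), unique(subjectIds(tab)))
  expect_equal(meanAccuracy(rep), mean(ps))
  expect_equal(sdAccuracy(rep), sd(ps))
  expect_true(all(ps >= 0 & ps <= 100))
  expect_gte(meanAccuracy(rep), 85)

  expect_error(subjectLOOCV(classifierSpec("knn", "fine"),
                            makeToyFeatureTable(n_subjects_per_class = 1,
                                                segments_per_subject = 2)),
               ">= 3 subjects")
})

test_that("an adversarial subject scores 0% and drags the mean accordingly", {
  tab <- makeToyFeatureTable(n_subjects_per_class = 4,
                             segments_per_subject = 4, K = 1,
                             effect = 3, seed = 33)
  X <- featureMatrix(tab)
  flip <- subjectIds(tab) == "CON01"     # give one control the SCH profile
  X[flip, ] <- X[flip, ] + 3
  tab2 <- featureTable(X, y = as.character(segmentLabels(tab)),
                       subject_ids = subjectIds(tab))
  rep <- subjectLOOCV(classifierSpec("knn", "medium"), tab2, seed = 1)
  expect_equal(unname(perSubjectAccuracy(rep)["CON01"]), 0)
  expect_equal(meanAccuracy(rep), mean(perSubjectAccuracy(rep)))
})

test_that("the published per-subject accuracies aggregate to the reported means", {
  mhrc <- referenceLOOCVAccuracies("MHRC")
  repod <- referenceLOOCVAccuracies("RepOD")
  expect_length(mhrc, 39)
  expect_length(repod, 14)
  expect_equal(meanAccuracy(loocvReport(mhrc)), 81.55, tolerance = 0.005)
  expect_equal(meanAccuracy(loocvReport(repod)), 83.97, tolerance = 0.005)
})

test_that("the lobe-wise sweep is exhaustive, paired, and deterministic", {
  tab <- makeToyFeatureTable(n_subjects_per_class = 3,
                             segments_per_subject = 4,
                             channels = montageChannels("mhrc16"), K = 1,
                             effect = 1.5, seed = 34)
  specs <- list(classifierSpec("knn", "medium"), classifierSpec("lda"))
  sw <- lobewiseSweep(specs, tab, k = 5, seed = 2)
  expect_equal(nrow(sw$results), 10)           # 5 lobes x 2 specs
  expect_length(sw$reports, 10)
  expect_equal(nrow(sw$best_per_lobe), 5)
  sw2 <- lobewiseSweep(specs, tab, k = 5, seed = 2)
  expect_identical(sw$best_per_lobe, sw2$best_per_lobe)
  # ties resolve to the first spec in input order
  tie <- data.frame(lobe = "central", family = c("a", "b"),
                    variant = c("x", "y"), spec_index = 1:2,
                    Ac = c(80, 80), SE = 0, SP = 0, PR = 0, F1 = 0)
  pick <- tie[order(-tie$Ac, tie$spec_index), ][1, ]
  expect_equal(pick$family, "a")
})

test_that("a lobe-restricted class effect is detected in the right lobe", {
  diffs <- vapply(1:5, function(s) {
    tab <- makeToyFeatureTable(n_subjects_per_class = 3,
                               segments_per_subject = 4,
                               channels = montageChannels("mhrc16"),
                               K = 1, effect = 2,
                               effect_channels = c("F3", "F4", "F7", "F8"),
                               seed = 400 + s)
    fr <- metrics(kfoldCV(classifierSpec("knn", "medium"),
                          subsetLobe(tab, "frontal"), k = 5,
                          seed = s))["Ac"]
    oc <- metrics(kfoldCV(classifierSpec("knn", "medium"),
                          subsetLobe(tab, "occipital"), k = 5,
                          seed = s))["Ac"]
    fr - oc
  }, 0)
  expect_gt(mean(diffs), 0)
  expect_gt(sum(diffs > 0), 3)
})

test_that("paired comparisons match the reference t-test implementation", {
  a <- c(84.1, 87.7, 81.7, 86.8, 86.4)   # paired performance vectors
  b <- c(97.7, 99.3, 95.1, 93.8, 96.4)
  pc <- pairedComparison(a, b)
  expect_equal(pc@meanDiff, 11.12, tolerance = 1e-9)
  tt <- t.test(b, a, paired = TRUE)
  expect_equal(pc@tStat, unname(tt$statistic), tolerance = 1e-9)
  expect_equal(pc@pValue, tt$p.value, tolerance = 1e-9)
  expect_equal(pc@cohensD, mean(b - a) / sd(b - a), tolerance = 1e-12)

  set.seed(35)
  x <- runif(12, 50, 100)
  y <- x + rnorm(12, 2)
  pc2 <- pairedComparison(x, y)
  tt2 <- t.test(y, x, paired = TRUE)
  expect_equal(pc2@tStat, unname(tt2$statistic), tolerance = 1e-9)
  expect_equal(pc2@pValue, tt2$p.value, tolerance = 1e-9)

  # antisymmetry
  rev <- pairedComparison(y, x)
  expect_equal(rev@meanDiff, -pc2@meanDiff)
  expect_equal(rev@tStat, -pc2@tStat)
  expect_equal(rev@cohensD, -pc2@cohensD)
})

test_that("degenerate paired differences hit the documented sentinel paths", {
  a <- c(1, 2, 3)
  same <- pairedComparison(a, a)
  expect_equal(c(same@meanDiff, same@tStat, same@pValue), c(0, 0, 1))
  expect_warning(shift <- pairedComparison(a, a + 5),
                 class = "vmdEEG_sentinel")
  expect_equal(shift@meanDiff, 5)
  expect_true(is.na(shift@pValue))
  expect_error(pairedComparison(1, 1:2), "equal length")
})
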