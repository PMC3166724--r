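test_that("leave-one-subject-out folds cover each subject exactly once", {
  mkSeq <- function(subj) new("LabeledSequence",
    X = matrix(rnorm(20), 10, 2), y = rep("S1", 10),
    spurious = rep(FALSE, 10), subjectId = subj)
  data <- lapply(sprintf("p%d", 1:7), mkSeq)
  folds <- losoSplit(data)
  expect_length(folds, 7)
  tested <- unlist(lapply(folds, `[[`, "testIdx"))
  expect_setequal(tested, 1:7)
  for (f in folds)
    expect_length(intersect(f$trainIdx, f$testIdx), 0)
  expect_length(losoSplit(lapply(sprintf("q%d", 1:20), mkSeq)), 20)
  expect_error(losoSplit(list(mkSeq("a"), mkSeq("a"))), "two subjects")
})

test_that("rejection performance reduces to the contingency table", {
  expect_equal(unname(rejectionPerformance(c(TRUE, TRUE, FALSE, FALSE),
    c(TRUE, TRUE, FALSE, FALSE))), c(1, 1))
  expect_equal(unname(rejectionPerformance(c(FALSE, FALSE, TRUE, TRUE),
    c(TRUE, TRUE, FALSE, FALSE))), c(0, 0))
  set.seed(71)
  truth <- sample(c(TRUE, FALSE), 200, replace = TRUE)
  pred <- sample(c(TRUE, FALSE), 200, replace = TRUE)
  perf <- rejectionPerformance(pred, truth)
  tp <- sum(pred & truth); fn <- sum(!pred & truth)
  tn <- sum(!pred & !truth); fp <- sum(pred & !truth)
  expect_equal(perf[["sensitivity"]], tp / (tp + fn))
  expect_equal(perf[["specificity"]], tn / (tn + fp))
  expect_error(rejectionPerformance(pred, rep(FALSE, 200)), "both")
})

test_that("a separable problem scores perfect accuracy", {
  truth <- overlappingChmm(sep = 30)
  # one sequence per subject starting in each state, so that every fold
  # observes every state both inside sequences and as a sequence start
  startAt <- function(state, len, seed, subj) {
    s <- simulateSequence(truth, len + 80, seed = seed, subjectId = subj)
    i <- match(state, frameLabels(s))
    new("LabeledSequence", X = featureMatrix(s)[i:(i + len - 1), ],
      y = frameLabels(s)[i:(i + len - 1)], spurious = rep(FALSE, len),
      subjectId = subj)
  }
  data <- list()
  for (subj in 1:3) for (st in 1:3)
    data[[length(data) + 1]] <- startAt(sprintf("S%d", st), 120,
      seed = 700 + 10 * subj + st, subj = sprintf("p%d", subj))
  for (clf in c("gmm", "chmm1", "chmm2")) {
    rep_ <- evaluateClassifier(data, clf, seed = 1)
    expect_equal(cvAccuracy(rep_), 1)
    expect_true(all(rep_@confusion[upper.tri(rep_@confusion)] == 0))
    expect_true(all(rep_@confusion[lower.tri(rep_@confusion)] == 0))
    # accuracy identity: trace over total of the aggregated matrix
    expect_equal(sum(diag(rep_@confusion)) / sum(rep_@confusion), 1)
  }
})

test_that("accuracy equals trace/total of the confusion matrix without
           rejection", {
  truth <- overlappingChmm(sep = 1.2)
  data <- lapply(1:3, function(s)
    simulateSequence(truth, 150, seed = 720 + s,
      subjectId = sprintf("p%d", s)))
  rep_ <- evaluateClassifier(data, "gmm", seed = 1)
  total <- sum(vapply(data, function(s) nrow(featureMatrix(s)), numeric(1)))
  perSubjectN <- total / 3
  pooled <- sum(rep_@perSubjectAccuracy * perSubjectN) / total
  expect_equal(sum(diag(rep_@confusion)) / sum(rep_@confusion), pooled,
    tolerance = 1e-12)
  expect_equal(sum(rep_@confusion), total)
})

test_that("training folds never see the held-out subject", {
  truth <- overlappingChmm(sep = 2)
  data <- lapply(1:3, function(s)
    simulateSequence(truth, 100, seed = 730 + s,
      subjectId = sprintf("p%d", s)))
  folds <- losoSplit(data)
  f <- folds[[1]]
  # scrambling the held-out subject's labels cannot change the model
  scrambled <- data
  scrambled[[f$testIdx]]@y <- sample(scrambled[[f$testIdx]]@y)
  m1 <- trainLevel1(data[f$trainIdx], seed = 1)
  m2 <- trainLevel1(scrambled[f$trainIdx], seed = 1)
  expect_identical(transitionMatrix(m1), transitionMatrix(m2))
  expect_identical(emissionModels(m1)[[1]]@means,
    emissionModels(m2)[[1]]@means)
})

test_that("confusion counts are tabulated in the declared orientation", {
  m <- confusionCounts(c("a", "a", "b"), c("a", "b", "b"),
    classes = c("a", "b"))
  expect_equal(m["a", "a"], 1L)
  expect_equal(m["a", "b"], 1L)
  expect_equal(m["b", "b"], 1L)
  expect_equal(m["b", "a"], 0L)
  expect_equal(sum(m), 3L)
})

test_that("model serialization round-trips classifiers exactly enough to
           reproduce likelihoods", {
  truth <- overlappingChmm(sep = 2)
  s <- simulateSequence(truth, 60, seed = 741)
  m <- trainLevel1(s, seed = 1)
  f <- withr::local_tempfile(fileext = ".json")
  saveModel(m, f)
  back <- loadModel(f)
  expect_equal(transitionMatrix(back), transitionMatrix(m))
  expect_equal(forwardLoglik(back, featureMatrix(s)),
    forwardLoglik(m, featureMatrix(s)), tolerance = 1e-9)
  clf <- fitGmmClassifier(featureMatrix(s), frameLabels(s))
  f2 <- withr::local_tempfile(fileext = ".json")
  saveModel(clf, f2)
  back2 <- loadModel(f2)
  expect_identical(classifyFrames(back2, featureMatrix(s))$labels,
    classifyFrames(clf, featureMatrix(s))$labels)
})
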