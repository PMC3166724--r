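test_that("first-level training reduces to counting plus per-state fits", {
  truth <- overlappingChmm(sep = 10)
  s <- simulateSequence(truth, 300, seed = 31)
  m <- trainLevel1(s, M = 1, seed = 1)
  # transition part identical to the counting estimator on the same labels
  expect_identical(unname(transitionMatrix(m)),
    unname(unclass(estimateTpm(list(frameLabels(s)),
      stateNames = stateNames(truth)))[, ]))
  # emission part identical to the per-state closed-form fit
  X1 <- featureMatrix(s)[frameLabels(s) == "S1", ]
  expect_equal(unname(emissionModels(m)[[1]]@means[1, ]),
    unname(colMeans(X1)), tolerance = 1e-12)
  # single-state data
  one <- new("LabeledSequence", X = matrix(rnorm(40), 20, 2),
    y = rep("S1", 20), spurious = rep(FALSE, 20))
  m1 <- trainLevel1(one)
  expect_equal(unname(transitionMatrix(m1)), matrix(1, 1, 1))
  expect_error(trainLevel1(one, stateNames = c("S1", "S2")), "S2")
})

test_that("first-level training recovers generating parameters", {
  truth <- overlappingChmm(sep = 10)
  data <- lapply(1:5, function(i) simulateSequence(truth, 400, seed = 40 + i))
  m <- trainLevel1(data, M = 1, seed = 1)
  expect_lt(max(abs(transitionMatrix(m) - transitionMatrix(truth))), 0.05)
  for (i in 1:3)
    expect_lt(max(abs(emissionModels(m)[[i]]@means -
      emissionModels(truth)[[i]]@means)), 0.1)
})

test_that("garbage and transition frames are excluded from level-1 counts", {
  truth <- overlappingChmm(sep = 10)
  s <- simulateSequence(truth, 200, seed = 33)
  # intersperse garbage frames far away; counts must be unaffected
  y2 <- c(frameLabels(s), rep("garbage", 50))
  X2 <- rbind(featureMatrix(s), matrix(99, 50, 2))
  ord <- order(c(seq_len(200), runif(50, 1, 200)))
  contaminated <- new("LabeledSequence", X = X2[ord, ], y = y2[ord],
    spurious = y2[ord] == "garbage")
  mClean <- trainLevel1(s, seed = 1)
  mCont <- trainLevel1(contaminated, seed = 1)
  expect_equal(transitionMatrix(mCont), transitionMatrix(mClean))
  expect_equal(emissionModels(mCont)[[1]]@means,
    emissionModels(mClean)[[1]]@means)
})

test_that("Baum-Welch increases the likelihood monotonically and is stable
           at a fixed point", {
  truth <- overlappingChmm(sep = 2)
  data <- lapply(1:3, function(i) simulateSequence(truth, 150, seed = 50 + i))
  m1 <- trainLevel1(data, seed = 1)
  m2 <- trainLevel2(m1, lapply(data, featureMatrix), maxIter = 200,
    tol = 1e-12)
  tr <- attr(m2, "logLik")
  expect_true(all(diff(tr) >= -1e-6 * pmax(1, abs(tr[-length(tr)]))))
  # converged model: one more iteration moves parameters below 1e-6
  m3 <- trainLevel2(m2, lapply(data, featureMatrix), maxIter = 1)
  expect_lt(max(abs(transitionMatrix(m3) - transitionMatrix(m2))), 1e-6)
  expect_lt(max(abs(priors(m3) - priors(m2))), 1e-6)
})

test_that("Baum-Welch refinement does not move A away from the truth", {
  truth <- overlappingChmm(sep = 4)
  for (r in 1:3) {
    labeled <- simulateSequence(truth, 100, seed = r * 1000 + 61)  # ~10%
    unlabeled <- lapply(1:9, function(i)
      simulateSequence(truth, 100, seed = r * 1000 + 61 + i))
    m1 <- trainLevel1(labeled, seed = 1)
    m2 <- trainLevel2(m1, lapply(unlabeled, featureMatrix), maxIter = 30)
    d1 <- max(rowSums(abs(transitionMatrix(m1) - transitionMatrix(truth))))
    d2 <- max(rowSums(abs(transitionMatrix(m2) - transitionMatrix(truth))))
    expect_lte(d2, d1 + 1e-8)
  }
})

test_that("forward log-likelihood matches direct and path-sum oracles", {
  truth <- overlappingChmm()
  x <- matrix(c(0.3, -0.2), 1, 2)
  direct <- log(sum(priors(truth) * vapply(emissionModels(truth),
    function(m) mixtureDensity(m, x[1, ]), numeric(1))))
  expect_equal(forwardLoglik(truth, x), direct, tolerance = 1e-12)
  # Q = 2, T = 4 path enumeration
  omm <- markovModel(rbind(c(.7, .3), c(.4, .6)), priors = c(.6, .4))
  ch <- new("CHMM", omm = omm,
    emissions = list(mix1(c(0, 0)), mix1(c(1, 1))))
  set.seed(62)
  X <- matrix(rnorm(8), 4, 2)
  lb <- sapply(ch@emissions, function(m) mixtureDensity(m, X, log = TRUE))
  paths <- as.matrix(expand.grid(1:2, 1:2, 1:2, 1:2))
  tot <- log(sum(apply(paths, 1, function(pp) {
    pr <- priors(omm)[pp[1]] *
      prod(transitionMatrix(omm)[cbind(pp[-4], pp[-1])])
    pr * exp(sum(lb[cbind(1:4, pp)]))
  })))
  expect_equal(forwardLoglik(ch, X), tot, tolerance = 1e-9)
  # duplicating states with halved priors leaves the likelihood unchanged
  ommDup <- markovModel(
    rbind(c(.35, .35, .15, .15), c(.35, .35, .15, .15),
          c(.2, .2, .3, .3), c(.2, .2, .3, .3)),
    priors = c(.3, .3, .2, .2))
  chDup <- new("CHMM", omm = ommDup, emissions = list(mix1(c(0, 0)),
    mix1(c(0, 0)), mix1(c(1, 1)), mix1(c(1, 1))))
  expect_equal(forwardLoglik(chDup, X), tot, tolerance = 1e-9)
})

test_that("Viterbi equals exhaustive search and honours structure", {
  # identity transitions + separated emissions: path is per-frame argmax
  ident <- new("CHMM",
    omm = markovModel(diag(3), priors = rep(1 / 3, 3)),
    emissions = list(mix1(c(0, 0)), mix1(c(8, 0)), mix1(c(0, 8))))
  X <- rbind(c(0, 0), c(0.2, 0.1), c(-0.1, 0))
  expect_identical(viterbiDecode(ident, X), rep("S1", 3))
  # random Q = 3, T = 6 model vs brute force over 3^6 paths
  set.seed(63)
  A <- matrix(runif(9), 3); A <- A / rowSums(A)
  omm <- markovModel(A, priors = c(.2, .5, .3))
  ch <- new("CHMM", omm = omm, emissions = list(mix1(c(0, 0)),
    mix1(c(1.5, 0)), mix1(c(0, 1.5))))
  X6 <- matrix(rnorm(12), 6, 2)
  lb <- sapply(ch@emissions, function(m) mixtureDensity(m, X6, log = TRUE))
  paths <- as.matrix(expand.grid(rep(list(1:3), 6)))
  lp <- apply(paths, 1, function(pp)
    log(priors(omm)[pp[1]]) +
      sum(log(transitionMatrix(omm)[cbind(pp[-6], pp[-1])])) +
      sum(lb[cbind(1:6, pp)]))
  oracle <- stateNames(omm)[paths[which.max(lp), ]]
  expect_identical(viterbiDecode(ch, X6), unname(oracle))
  # left-right chain: decoded path can never move to a lower state
  lr <- markovModel(rbind(c(.8, .2, 0), c(0, .8, .2), c(0, 0, 1)),
    priors = c(1, 0, 0))
  chLr <- new("CHMM", omm = lr, emissions = list(mix1(c(0, 0)),
    mix1(c(1, 0)), mix1(c(0, 1))))
  set.seed(64)
  Xlr <- matrix(rnorm(60), 30, 2)   # ambiguous observations
  idx <- match(viterbiDecode(chLr, Xlr), stateNames(lr))
  expect_true(all(diff(idx) >= 0))
})

test_that("decoded paths are at least as probable as the generating path", {
  truth <- overlappingChmm(sep = 1.5)
  logPathProb <- function(states, X) {
    pp <- match(states, stateNames(truth))
    lb <- sapply(truth@emissions, function(m)
      mixtureDensity(m, X, log = TRUE))
    log(priors(truth)[pp[1]]) +
      sum(log(transitionMatrix(truth)[cbind(pp[-length(pp)], pp[-1])])) +
      sum(lb[cbind(seq_along(pp), pp)])
  }
  for (i in 1:5) {
    s <- simulateSequence(truth, 60, seed = 70 + i)
    dec <- viterbiDecode(truth, featureMatrix(s))
    expect_gte(logPathProb(dec, featureMatrix(s)),
      logPathProb(frameLabels(s), featureMatrix(s)) - 1e-9)
  }
})

test_that("rejected frames are skipped and inherit the previous label", {
  ident <- new("CHMM",
    omm = markovModel(rbind(c(.9, .1), c(.1, .9)), priors = c(.5, .5)),
    emissions = list(mix1(0), mix1(8)))
  X <- matrix(c(0, 0.1, 50, 8.2, 7.9), ncol = 1)
  mask <- c(FALSE, FALSE, TRUE, FALSE, FALSE)
  dec <- viterbiDecode(ident, X, mask = mask)
  expect_identical(dec, c("S1", "S1", "S1", "S2", "S2"))
  # a leading rejected frame inherits the first decoded label
  dec2 <- viterbiDecode(ident, X, mask = c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_identical(dec2[1], dec2[2])
  expect_error(viterbiDecode(ident, X, mask = rep(TRUE, 5)), "all frames")
})

test_that("decoding is invariant to a consistent feature permutation", {
  truth <- overlappingChmm(sep = 1.5)
  s <- simulateSequence(truth, 80, seed = 77)
  perm <- c(2, 1)
  permuted <- new("CHMM", omm = truth@omm,
    emissions = lapply(truth@emissions, function(m)
      new("MixtureModel", weights = m@weights,
        means = m@means[, perm, drop = FALSE],
        covariances = lapply(m@covariances, function(s) s[perm, perm]))))
  expect_identical(viterbiDecode(truth, featureMatrix(s)),
    viterbiDecode(permuted, featureMatrix(s)[, perm]))
  expect_equal(forwardLoglik(truth, featureMatrix(s)),
    forwardLoglik(permuted, featureMatrix(s)[, perm]), tolerance = 1e-9)
})

test_that("the sequential decoder beats single-frame classification on
           persistent chains with overlapping emissions", {
  truth <- overlappingChmm(sep = 1.5, diagp = 0.85)
  wins <- 0
  accs <- matrix(0, 5, 2, dimnames = list(NULL, c("gmm", "viterbi")))
  for (i in 1:5) {
    train <- simulateSequence(truth, 300, seed = 80 + i)
    test <- simulateSequence(truth, 300, seed = 90 + i)
    m <- trainLevel1(train, seed = 1)
    clf <- fitGmmClassifier(featureMatrix(train), frameLabels(train))
    gmmAcc <- mean(classifyFrames(clf,
      featureMatrix(test))$labels == frameLabels(test))
    vitAcc <- mean(viterbiDecode(m,
      featureMatrix(test)) == frameLabels(test))
    accs[i, ] <- c(gmmAcc, vitAcc)
  }
  expect_gte(mean(accs[, "viterbi"]), mean(accs[, "gmm"]))
})
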