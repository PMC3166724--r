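test_that("single-component fit is the closed-form mean and covariance", {
  set.seed(21)
  X <- matrix(rnorm(300), ncol = 3)
  m <- fitMixture(X, M = 1)
  expect_equal(unname(m@means[1, ]), unname(colMeans(X)), tolerance = 1e-9)
  expect_equal(unname(m@covariances[[1]]), unname(cov(X)), tolerance = 1e-9)
  expect_equal(sum(m@weights), 1)
  expect_error(fitMixture(X[1:2, ], M = 2), "more observations")
})

test_that("EM recovers well-separated clusters and keeps weights normalized", {
  set.seed(22)
  X <- rbind(matrix(rnorm(300, 0), ncol = 2), matrix(rnorm(300, 10), ncol = 2))
  for (M in 1:5) {
    m <- fitMixture(X, M = M, seed = 5)
    expect_equal(sum(m@weights), 1, tolerance = 1e-9)
    ll <- attr(m, "logLik")
    expect_true(all(diff(ll) >= -1e-8 * pmax(1, abs(ll[-length(ll)]))))
  }
  m2 <- fitMixture(X, M = 2, seed = 5)
  mus <- sort(m2@means[, 1])
  # compare to the empirical cluster means (the recoverable target)
  expect_lt(abs(mus[1] - mean(X[1:150, 1])), 0.05)
  expect_lt(abs(mus[2] - mean(X[151:300, 1])), 0.05)
})

test_that("EM solution agrees with an independent mixture fitter", {
  set.seed(23)
  X <- rbind(matrix(rnorm(400, 0), ncol = 2), matrix(rnorm(400, 6), ncol = 2))
  m <- fitMixture(X, M = 2, seed = 3)
  suppressMessages(library(mclust))
  ref <- Mclust(X, G = 2, modelNames = "VVV", verbose = FALSE)
  refMeans <- t(ref$parameters$mean)
  ours <- m@means[order(m@means[, 1]), ]
  theirs <- refMeans[order(refMeans[, 1]), ]
  expect_equal(unname(ours), unname(theirs), tolerance = 0.05)
})

test_that("mixture density matches closed forms and a term-by-term oracle", {
  std <- mix1(0)
  expect_equal(mixtureDensity(std, 0), 1 / sqrt(2 * pi), tolerance = 1e-12)
  expect_error(mixtureDensity(std, c(1, 2)), "dimension")
  set.seed(24)
  m <- new("MixtureModel", weights = c(0.3, 0.7),
    means = rbind(c(0, 0), c(2, -1)),
    covariances = list(diag(2), matrix(c(2, .5, .5, 1), 2)))
  for (i in 1:10) {
    x <- rnorm(2)
    oracle <- 0
    for (k in 1:2) {
      S <- m@covariances[[k]]; mu <- m@means[k, ]
      oracle <- oracle + m@weights[k] *
        exp(-0.5 * t(x - mu) %*% solve(S) %*% (x - mu)) /
        (2 * pi * sqrt(det(S)))
    }
    expect_equal(mixtureDensity(m, x), as.numeric(oracle), tolerance = 1e-12)
    expect_equal(mixtureDensity(m, x, log = TRUE), log(as.numeric(oracle)),
      tolerance = 1e-12)
  }
  # the density integrates to one (fine-grid quadrature over a wide box)
  g <- seq(-8, 10, length.out = 361)
  dx <- diff(g)[1]
  vals <- mixtureDensity(m, as.matrix(expand.grid(g, g)))
  expect_equal(sum(vals) * dx^2, 1, tolerance = 0.01)
})

test_that("frames go to the class with the highest density, ties to the
           lowest index", {
  cls <- separatedClasses(n = 40, sep = 8, seed = 25)
  clf <- fitGmmClassifier(cls$X, cls$y, M = 1)
  res <- classifyFrames(clf, rbind(c(0, 0), c(8, 8)))
  expect_identical(res$labels, c("a", "b"))
  # decision agrees with the density argmax on a grid of probe points
  grid <- as.matrix(expand.grid(seq(-2, 10, length.out = 10),
    seq(-2, 10, length.out = 5)))
  res2 <- classifyFrames(clf, grid)
  oracle <- apply(grid, 1, function(x) {
    da <- mixtureDensity(clf@mixtures[[1]], x)
    db <- mixtureDensity(clf@mixtures[[2]], x)
    if (da >= db) "a" else "b"
  })
  expect_identical(res2$labels, oracle)
  # identical class models: every frame ties, all go to class 1
  clf2 <- new("GmmClassifier", classes = c("a", "b"),
    mixtures = list(mix1(c(0, 0)), mix1(c(0, 0))))
  expect_identical(unique(classifyFrames(clf2, grid)$labels), "a")
})

test_that("equal-covariance single components induce a linear boundary", {
  clf <- new("GmmClassifier", classes = c("a", "b"),
    mixtures = list(mix1(c(0, 0)), mix1(c(4, 0))))
  # collinear probes cross the boundary exactly once
  probes <- cbind(seq(-3, 7, length.out = 101), 0.5)
  lab <- classifyFrames(clf, probes)$labels
  expect_equal(sum(lab[-1] != lab[-101]), 1)
})

test_that("transition and garbage frames are excluded from class fits", {
  cls <- separatedClasses(n = 20, sep = 6, seed = 26)
  y <- cls$y
  X <- rbind(cls$X, matrix(50, 5, 2))
  y <- c(y, rep("garbage", 5))
  clf <- fitGmmClassifier(X, y, M = 1)
  expect_identical(clf@classes, c("a", "b"))
  expect_lt(max(abs(clf@mixtures[[1]]@means)), 1)
})
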