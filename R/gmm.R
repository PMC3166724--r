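# Gaussian mixture densities and the single-frame maximum-likelihood
# classifier built from them. Full covariance matrices throughout; small
# per-class sample counts are handled by flooring covariance eigenvalues.

#' Fit a Gaussian mixture by expectation-maximization
#'
#' `M = 1` reduces to the closed-form sample mean and sample covariance.
#' For `M > 1` the mixture is fitted by EM from a k-means++-style seeding
#' of the component means; covariance eigenvalues are floored at `reg`
#' after every M-step so that sparsely populated components stay
#' positive-definite.
#'
#' @param X numeric matrix of observations (rows).
#' @param M number of mixture components.
#' @param seed integer seed controlling the seeding (ignored for M = 1).
#' @param reg lower bound applied to covariance eigenvalues.
#' @param maxIter maximum EM iterations.
#' @param tol relative log-likelihood convergence tolerance.
#' @return A [MixtureModel-class]; attribute `"logLik"` holds the per-
#'   iteration log-likelihood trace (monotone non-decreasing).
#' @examples
#' X <- matrix(rnorm(200), ncol = 2)
#' fitMixture(X, M = 1)
#' @export
fitMixture <- function(X, M = 1, seed = NULL, reg = 1e-6, maxIter = 200,
                       tol = 1e-8) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  if (n <= M) stop("need more observations (", n, ") than components (", M, ")")
  if (M == 1) {
    mu <- matrix(colMeans(X), 1, d)
    sigma <- if (n > 1) stats::cov(X) else diag(reg, d)
    sigma <- floorEigenvalues(matrix(sigma, d, d), reg)
    mm <- new("MixtureModel", weights = 1, means = mu,
      covariances = list(sigma))
    attr(mm, "logLik") <- sum(dmvnormLog(X, mu[1, ], sigma))
    return(mm)
  }
  centers <- withLocalSeed(seed, function() kppSeeds(X, M))
  # hard-assignment initialization of the responsibilities
  d2 <- sapply(seq_len(M), function(m) rowSums(sweep(X, 2, centers[m, ])^2))
  assign0 <- max.col(-d2, ties.method = "first")
  resp <- matrix(0, n, M)
  resp[cbind(seq_len(n), assign0)] <- 1
  # guarantee every component owns at least one point
  for (m in seq_len(M)) if (sum(resp[, m]) == 0) {
    j <- which.min(d2[, m])
    resp[j, ] <- 0; resp[j, m] <- 1
  }
  w <- colMeans(resp)
  mu <- matrix(0, M, d)
  sig <- vector("list", M)
  trace <- numeric(0)
  prev <- -Inf
  for (it in seq_len(maxIter)) {
    # M-step
    nk <- colSums(resp)
    for (m in seq_len(M)) {
      mu[m, ] <- colSums(X * resp[, m]) / nk[m]
      xc <- sweep(X, 2, mu[m, ])
      s <- crossprod(xc * resp[, m], xc) / nk[m]
      sig[[m]] <- floorEigenvalues(s, reg)
    }
    w <- nk / n
    # E-step
    lcomp <- sapply(seq_len(M), function(m)
      log(w[m]) + dmvnormLog(X, mu[m, ], sig[[m]]))
    lse <- apply(lcomp, 1, logSumExp)
    ll <- sum(lse)
    trace <- c(trace, ll)
    resp <- exp(lcomp - lse)
    if (is.finite(prev) && abs(ll - prev) <= tol * abs(prev)) break
    prev <- ll
  }
  mm <- new("MixtureModel", weights = w / sum(w), means = mu,
    covariances = sig)
  attr(mm, "logLik") <- trace
  mm
}

# k-means++ style seeding: first center uniform, then points chosen with
# probability proportional to squared distance from the nearest center.
kppSeeds <- function(X, M) {
  n <- nrow(X)
  centers <- matrix(0, M, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  if (M > 1) {
    mind <- rowSums(sweep(X, 2, centers[1, ])^2)
    for (m in 2:M) {
      p <- if (sum(mind) > 0) mind / sum(mind) else rep(1 / n, n)
      centers[m, ] <- X[sample.int(n, 1, prob = p), ]
      mind <- pmin(mind, rowSums(sweep(X, 2, centers[m, ])^2))
    }
  }
  centers
}

#' Evaluate a Gaussian mixture density
#'
#' Weighted sum of multivariate normal densities, computed in the log
#' domain with log-sum-exp.
#'
#' @param model a [MixtureModel-class] object.
#' @param x a single feature vector or a matrix of row vectors.
#' @param log return the log-density?
#' @return Density (or log-density) per row of `x`.
#' @examples
#' m <- new("MixtureModel", weights = 1, means = matrix(0, 1, 1),
#'          covariances = list(matrix(1, 1, 1)))
#' mixtureDensity(m, 0)   # 1 / sqrt(2 * pi)
#' @export
mixtureDensity <- function(model, x, log = FALSE) {
  X <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  d <- ncol(model@means)
  if (ncol(X) != d)
    stop("dimension mismatch: model d = ", d, ", x has ", ncol(X))
  M <- length(model@weights)
  lcomp <- sapply(seq_len(M), function(m)
    log(model@weights[m]) + dmvnormLog(X, model@means[m, ],
      model@covariances[[m]]))
  if (is.null(dim(lcomp))) lcomp <- matrix(lcomp, nrow = nrow(X))
  ld <- apply(lcomp, 1, logSumExp)
  if (log) ld else exp(ld)
}

#' Train a single-frame Gaussian mixture classifier
#'
#' Fits one class-conditional mixture p(x | w_i) per class by
#' [fitMixture()]. Frames labeled `"transition"`, `"garbage"` or `NA` are
#' excluded from fitting.
#'
#' @param X numeric feature matrix, one frame per row.
#' @param y per-frame class labels.
#' @param M mixture components per class.
#' @param seed integer seed for the per-class EM seeding.
#' @param reg covariance eigenvalue floor.
#' @param classes class vocabulary; default sorted unique genuine labels.
#' @return A [GmmClassifier-class] object.
#' @export
fitGmmClassifier <- function(X, y, M = 1, seed = NULL, reg = 1e-6,
                             classes = NULL) {
  X <- as.matrix(X)
  keep <- !is.na(y) & !(y %in% c("transition", "garbage"))
  if (is.null(classes)) classes <- sort(unique(y[keep]))
  if (length(classes) < 1) stop("no genuine class labels in y")
  mixtures <- lapply(seq_along(classes), function(i) {
    idx <- keep & y == classes[i]
    if (sum(idx) <= M)
      stop("class ", classes[i], " has ", sum(idx),
        " frames; need more than M = ", M)
    fitMixture(X[idx, , drop = FALSE], M = M,
      seed = if (is.null(seed)) NULL else seed + i, reg = reg)
  })
  new("GmmClassifier", classes = classes, mixtures = mixtures)
}

#' Per-class log-densities of frames under a classifier
#'
#' @param clf a [GmmClassifier-class] or [CHMM-class] object (for a CHMM
#'   the per-state emission densities are used).
#' @param X numeric feature matrix.
#' @return Matrix of log p(x | w_i), frames in rows, classes in columns.
#' @export
classLogDensities <- function(clf, X) {
  X <- as.matrix(X)
  if (is(clf, "CHMM")) {
    mixtures <- clf@emissions
    cls <- stateNames(clf)
  } else {
    mixtures <- clf@mixtures
    cls <- clf@classes
  }
  ld <- sapply(mixtures, function(m) mixtureDensity(m, X, log = TRUE))
  if (is.null(dim(ld))) ld <- matrix(ld, nrow = nrow(X))
  colnames(ld) <- cls
  ld
}

#' Classify frames by maximum class-conditional density
#'
#' Each frame is assigned to the class with the highest p(x | w_i); no
#' class priors are applied. Ties resolve to the lowest class index.
#'
#' @param clf a [GmmClassifier-class] object.
#' @param X numeric feature matrix.
#' @return List with `labels` (character) and `logDensities`
#'   (frames x classes matrix, for downstream rejection).
#' @export
classifyFrames <- function(clf, X) {
  ld <- classLogDensities(clf, X)
  idx <- max.col(ld, ties.method = "first")
  list(labels = clf@classes[idx], logDensities = ld)
}
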