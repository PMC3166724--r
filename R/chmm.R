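# Continuous-emission HMM classifier: two-level supervised training,
# log-domain forward/backward and Baum-Welch, Viterbi decoding. All
# recursions run in the log domain with log-sum-exp; linear-domain
# arithmetic underflows for realistic frame densities.

#' First-level (supervised) training of the sequential classifier
#'
#' Transition parameters (pi, A) are estimated by counting labeled
#' transitions ([estimatePriors()], [estimateTpm()]); the emission density
#' of each state is a Gaussian mixture fitted to that state's frames by
#' [fitMixture()]. Frames labeled `"transition"`, `"garbage"` or `NA` are
#' excluded from both the counts and the fits; transitions are counted
#' between consecutive retained frames.
#'
#' @param data list of [LabeledSequence-class] objects (or a single one).
#' @param M mixture components per state.
#' @param seed integer seed for the emission fits.
#' @param reg covariance eigenvalue floor.
#' @param stateNames state vocabulary; default the sorted genuine labels
#'   observed in `data`. Every state must be observed.
#' @return A [CHMM-class] object.
#' @seealso [trainLevel2()], [viterbiDecode()]
#' @export
trainLevel1 <- function(data, M = 1, seed = NULL, reg = 1e-6,
                        stateNames = NULL) {
  if (is(data, "LabeledSequence")) data <- list(data)
  cleaned <- lapply(data, function(s) {
    keep <- !is.na(s@y) & !(s@y %in% c("transition", "garbage"))
    list(X = s@X[keep, , drop = FALSE], y = s@y[keep])
  })
  labels <- lapply(cleaned, `[[`, "y")
  observed <- sort(unique(unlist(labels)))
  if (is.null(stateNames)) stateNames <- observed
  missing <- setdiff(stateNames, observed)
  if (length(missing))
    stop("state(s) never observed in the training labels: ",
      paste(missing, collapse = ", "))
  pi0 <- estimatePriors(labels, stateNames = stateNames)
  A <- estimateTpm(labels, stateNames = stateNames)
  attr(A, "degenerate") <- NULL
  omm <- markovModel(A, priors = pi0, stateNames = stateNames,
    mode = "renormalize")
  Xall <- do.call(rbind, lapply(cleaned, `[[`, "X"))
  yall <- unlist(labels)
  emissions <- lapply(seq_along(stateNames), function(i) {
    idx <- yall == stateNames[i]
    if (sum(idx) <= M)
      stop("state ", stateNames[i], " has ", sum(idx),
        " frames; need more than M = ", M)
    fitMixture(Xall[idx, , drop = FALSE], M = M,
      seed = if (is.null(seed)) NULL else seed + i, reg = reg)
  })
  new("CHMM", omm = omm, emissions = emissions)
}

# T x Q matrix of per-state emission log-densities.
emissionLogProb <- function(chmm, X) classLogDensities(chmm, X)

# Log-domain forward pass; returns list(logAlpha, logLik).
forwardPass <- function(logPi, logA, logB) {
  T_ <- nrow(logB); q <- ncol(logB)
  la <- matrix(-Inf, T_, q)
  la[1, ] <- logPi + logB[1, ]
  if (T_ > 1) for (t in 2:T_)
    for (j in seq_len(q))
      la[t, j] <- logSumExp(la[t - 1, ] + logA[, j]) + logB[t, j]
  list(logAlpha = la, logLik = logSumExp(la[T_, ]))
}

backwardPass <- function(logA, logB) {
  T_ <- nrow(logB); q <- ncol(logB)
  lb <- matrix(0, T_, q)
  if (T_ > 1) for (t in (T_ - 1):1)
    for (i in seq_len(q))
      lb[t, i] <- logSumExp(logA[i, ] + logB[t + 1, ] + lb[t + 1, ])
  lb
}

#' Sequence log-likelihood under the sequential classifier
#'
#' log P(X | model) by the forward recursion in the log domain.
#'
#' @param chmm a [CHMM-class] object.
#' @param X numeric T x d feature matrix (time-ordered frames).
#' @return Scalar log-likelihood.
#' @export
forwardLoglik <- function(chmm, X) {
  X <- as.matrix(X)
  logB <- emissionLogProb(chmm, X)
  forwardPass(log(priors(chmm)), log(transitionMatrix(chmm)), logB)$logLik
}

#' Second-level training: Baum-Welch refinement
#'
#' Re-estimates the parameters of a supervised-initialized model by EM on
#' unlabeled sequences. By default only the transition parameters (pi, A)
#' are updated and the emission mixtures stay frozen at their first-level
#' estimates; `update = "all"` also re-estimates the emissions.
#'
#' @param chmm a first-level-trained [CHMM-class] object.
#' @param data list of numeric feature matrices (one per sequence), or
#'   [LabeledSequence-class] objects whose labels are ignored.
#' @param update `"transitions"` (default) or `"all"`.
#' @param maxIter maximum Baum-Welch iterations.
#' @param tol relative log-likelihood convergence tolerance.
#' @param reg covariance eigenvalue floor used when emissions are updated.
#' @return The refined [CHMM-class]; attribute `"logLik"` carries the per-
#'   iteration total log-likelihood trace (monotone non-decreasing).
#' @export
trainLevel2 <- function(chmm, data, update = c("transitions", "all"),
                        maxIter = 50, tol = 1e-6, reg = 1e-6) {
  update <- match.arg(update)
  if (is(data, "LabeledSequence")) data <- list(data)
  seqs <- lapply(data, function(s)
    if (is(s, "LabeledSequence")) s@X else as.matrix(s))
  q <- nStates(chmm)
  M <- length(chmm@emissions[[1]]@weights)
  pi0 <- priors(chmm); A <- transitionMatrix(chmm)
  emissions <- chmm@emissions
  trace <- numeric(0)
  prev <- -Inf
  for (it in seq_len(maxIter)) {
    logPi <- log(pi0); logA <- log(A)
    piAcc <- numeric(q)
    xiAcc <- matrix(0, q, q)
    gAcc <- vector("list", length(seqs))
    total <- 0
    for (s in seq_along(seqs)) {
      X <- seqs[[s]]
      logB <- emissionLogProb(chmm, X)
      fw <- forwardPass(logPi, logA, logB)
      if (!is.finite(fw$logLik))
        stop("sequence ", s, " has zero likelihood under the model; ",
          "consider increasing the covariance floor `reg`")
      lb <- backwardPass(logA, logB)
      ll <- fw$logLik
      total <- total + ll
      gamma <- exp(fw$logAlpha + lb - ll)
      piAcc <- piAcc + gamma[1, ]
      T_ <- nrow(X)
      if (T_ > 1) for (t in seq_len(T_ - 1)) {
        lx <- outer(fw$logAlpha[t, ], rep(1, q)) + logA +
          matrix(logB[t + 1, ] + lb[t + 1, ], q, q, byrow = TRUE) - ll
        xiAcc <- xiAcc + exp(lx)
      }
      gAcc[[s]] <- gamma
    }
    trace <- c(trace, total)
    pi0 <- piAcc / sum(piAcc)
    rs <- rowSums(xiAcc)
    for (i in seq_len(q))
      A[i, ] <- if (rs[i] > 0) xiAcc[i, ] / rs[i] else (seq_len(q) == i)
    if (update == "all") {
      Xall <- do.call(rbind, seqs)
      Gall <- do.call(rbind, gAcc)
      emissions <- lapply(seq_len(q), function(i)
        reestimateMixture(emissions[[i]], Xall, Gall[, i], reg))
    }
    chmm <- new("CHMM",
      omm = markovModel(A, priors = pi0, stateNames = stateNames(chmm),
        mode = "renormalize"),
      emissions = emissions)
    if (is.finite(prev) &&
        abs(total - prev) <= tol * max(1, abs(prev))) break
    prev <- total
  }
  attr(chmm, "logLik") <- trace
  chmm
}

# One EM update of a state's mixture given per-frame state responsibilities.
reestimateMixture <- function(mix, X, gamma, reg) {
  M <- length(mix@weights); d <- ncol(mix@means)
  lcomp <- sapply(seq_len(M), function(m)
    log(mix@weights[m]) + dmvnormLog(X, mix@means[m, ],
      mix@covariances[[m]]))
  if (is.null(dim(lcomp))) lcomp <- matrix(lcomp, nrow = nrow(X))
  lse <- apply(lcomp, 1, logSumExp)
  r <- exp(lcomp - lse) * gamma   # n x M joint responsibilities
  nk <- colSums(r)
  w <- nk / sum(nk)
  mu <- matrix(0, M, d)
  sig <- vector("list", M)
  for (m in seq_len(M)) {
    mu[m, ] <- colSums(X * r[, m]) / nk[m]
    xc <- sweep(X, 2, mu[m, ])
    sig[[m]] <- floorEigenvalues(crossprod(xc * r[, m], xc) / nk[m], reg)
  }
  new("MixtureModel", weights = w, means = mu, covariances = sig)
}

#' Viterbi decoding of the most likely state path
#'
#' Maximum a posteriori state sequence in the log domain. Frames flagged in
#' `mask` (rejected as spurious) are removed before decoding: the retained
#' frames are decoded as one contiguous sequence with unchanged transition
#' probabilities, and each rejected frame inherits the decoded label of the
#' previous retained frame (leading rejected frames inherit the first
#' decoded label). Ties resolve to the lowest state index.
#'
#' @param chmm a [CHMM-class] object.
#' @param X numeric T x d feature matrix.
#' @param mask optional logical vector flagging rejected frames.
#' @return Character vector of decoded state names, length T.
#' @export
viterbiDecode <- function(chmm, X, mask = NULL) {
  X <- as.matrix(X)
  T_ <- nrow(X)
  if (is.null(mask)) mask <- rep(FALSE, T_)
  if (length(mask) != T_) stop("mask must have one flag per frame")
  if (all(mask)) stop("all frames rejected; nothing to decode")
  Xr <- X[!mask, , drop = FALSE]
  logB <- emissionLogProb(chmm, Xr)
  logPi <- log(priors(chmm)); logA <- log(transitionMatrix(chmm))
  Tr <- nrow(logB); q <- ncol(logB)
  delta <- matrix(-Inf, Tr, q)
  psi <- matrix(1L, Tr, q)
  delta[1, ] <- logPi + logB[1, ]
  if (Tr > 1) for (t in 2:Tr) for (j in seq_len(q)) {
    cand <- delta[t - 1, ] + logA[, j]
    psi[t, j] <- which.max(cand)
    delta[t, j] <- cand[psi[t, j]] + logB[t, j]
  }
  path <- integer(Tr)
  path[Tr] <- which.max(delta[Tr, ])
  if (Tr > 1) for (t in (Tr - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  decoded <- stateNames(chmm)[path]
  out <- character(T_)
  out[!mask] <- decoded
  if (any(mask)) {
    lastSeen <- decoded[1]
    for (t in seq_len(T_)) {
      if (mask[t]) out[t] <- lastSeen else lastSeen <- out[t]
    }
  }
  out
}

#' Simulate a labeled sequence from a sequential classifier
#'
#' Samples a state path from the model's Markov chain and, per frame, an
#' emission from the occupied state's Gaussian mixture. Useful for
#' parameter-recovery studies and classifier benchmarking.
#'
#' @param chmm a [CHMM-class] object.
#' @param len number of frames T.
#' @param seed optional integer seed.
#' @param subjectId subject identifier for the returned sequence.
#' @return A [LabeledSequence-class] with the generating path in `y`.
#' @export
simulateSequence <- function(chmm, len, seed = NULL, subjectId = "s1") {
  withLocalSeed(seed, function() {
    path <- sampleChain(chmm@omm, len)
    idx <- match(path, stateNames(chmm))
    d <- ncol(chmm@emissions[[1]]@means)
    X <- matrix(0, len, d)
    for (t in seq_len(len)) {
      mix <- chmm@emissions[[idx[t]]]
      m <- sample.int(length(mix@weights), 1, prob = mix@weights)
      z <- stats::rnorm(d)
      X[t, ] <- mix@means[m, ] + drop(crossprod(chol(mix@covariances[[m]]), z))
    }
    new("LabeledSequence", X = X, y = path,
      spurious = rep(FALSE, len), subjectId = as.character(subjectId))
  })
}
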