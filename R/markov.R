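#' Build (and optionally repair) an observable Markov model
#'
#' Validates a raw transition matrix and prior vector. In `"strict"` mode a
#' row whose sum deviates from 1 by more than 1e-6 is an error; in
#' `"renormalize"` mode each row is divided by its sum and a warning reports
#' the repair. Zero rows are an error in both modes.
#'
#' @param tpm square non-negative matrix of transition probabilities.
#' @param priors prior probability vector; default uniform over states.
#' @param stateNames state labels; default `S1..SQ` or the matrix dimnames.
#' @param mode `"strict"` or `"renormalize"`.
#' @return A [MarkovModel-class] object.
#' @examples
#' A <- matrix(c(.9, .1, .2, .8), 2, byrow = TRUE)
#' markovModel(A)
#' @export
markovModel <- function(tpm, priors = NULL, stateNames = NULL,
                        mode = c("strict", "renormalize")) {
  mode <- match.arg(mode)
  tpm <- as.matrix(tpm)
  if (nrow(tpm) != ncol(tpm)) stop("tpm must be square")
  if (any(tpm < 0)) stop("tpm entries must be non-negative")
  q <- nrow(tpm)
  rs <- rowSums(tpm)
  if (any(rs == 0)) stop("tpm row(s) ", paste(which(rs == 0), collapse = ", "),
    " sum to zero")
  if (is.null(stateNames))
    stateNames <- if (!is.null(rownames(tpm))) rownames(tpm)
      else sprintf("S%d", seq_len(q))
  bad <- which(abs(rs - 1) > 1e-6)
  if (length(bad)) {
    if (mode == "strict")
      stop("tpm row(s) ", paste(stateNames[bad], collapse = ", "),
        " do not sum to 1 (sums ", paste(sprintf("%.4f", rs[bad]),
        collapse = ", "), "); use mode = \"renormalize\" to repair")
    warning("renormalizing tpm row(s) ", paste(stateNames[bad],
      collapse = ", "), " (sums ", paste(sprintf("%.4f", rs[bad]),
      collapse = ", "), ")")
    tpm <- tpm / rs
  }
  if (is.null(priors)) priors <- rep(1 / q, q)
  if (abs(sum(priors) - 1) > 1e-6) stop("priors must sum to 1")
  dimnames(tpm) <- list(stateNames, stateNames)
  names(priors) <- stateNames
  new("MarkovModel", priors = priors, tpm = tpm, stateNames = stateNames)
}

#' Transition matrix of the seven-activity virtual experiments
#'
#' The reference transition probability matrix over the seven activity
#' states (lying, cycling, climbing stairs, walking, running, sitting,
#' standing) used to drive virtual experiments. As shipped, the first row
#' sums to 1.20; `repair = "corrected"` (default) zeroes the implausible
#' lying-to-cycling entry a_12 = 0.20, which restores an exact row sum of 1
#' with a single-entry change, while `repair = "renormalize"` rescales the
#' row instead. `repair = "none"` returns the raw printed matrix.
#'
#' @param repair `"corrected"`, `"renormalize"` or `"none"`.
#' @return For `"none"`, the raw matrix; otherwise a [MarkovModel-class]
#'   with uniform priors (the priors used for virtual experiments are not
#'   part of the matrix's specification).
#' @export
sevenActivityTpm <- function(repair = c("corrected", "renormalize", "none")) {
  repair <- match.arg(repair)
  path <- system.file("extdata", "seven_activity_tpm.csv",
    package = "actichain", mustWork = TRUE)
  raw <- as.matrix(utils::read.csv(path, row.names = 1))
  colnames(raw) <- rownames(raw)
  if (repair == "none") return(raw)
  if (repair == "corrected") {
    raw["S1", "S2"] <- 0
    markovModel(raw, mode = "strict")
  } else {
    suppressWarnings(markovModel(raw, mode = "renormalize"))
  }
}

#' Sample a state sequence from a Markov chain
#'
#' Draws `X(t0)` from the prior vector and each subsequent state from the
#' transition-matrix row of its predecessor.
#'
#' @param omm a [MarkovModel-class] object.
#' @param len sequence length T (>= 1).
#' @param seed optional integer seed for reproducibility; the caller's RNG
#'   state is untouched when given.
#' @return Character vector of state names, length `len`.
#' @export
sampleChain <- function(omm, len, seed = NULL) {
  stopifnot(len >= 1)
  q <- nStates(omm)
  withLocalSeed(seed, function() {
    path <- integer(len)
    path[1] <- sample.int(q, 1, prob = priors(omm))
    A <- transitionMatrix(omm)
    for (t in seq_len(len - 1))
      path[t + 1] <- sample.int(q, 1, prob = A[path[t], ])
    stateNames(omm)[path]
  })
}

#' Count-based estimate of a transition probability matrix
#'
#' Pools transition counts over the given state sequences and normalizes
#' each row: `a_ij = N(i -> j) / N(i -> .)`. States with no outgoing
#' transition receive a one-hot self-loop row and are reported in the
#' `"degenerate"` attribute.
#'
#' @param sequences list of character state sequences (or a single vector).
#' @param stateNames state vocabulary; default the sorted union of observed
#'   states.
#' @return Row-stochastic matrix with a `"degenerate"` attribute naming
#'   states that had no outgoing transitions.
#' @examples
#' estimateTpm(list(c("S1", "S1", "S2")))  # 0.5 / 0.5 first row
#' @export
estimateTpm <- function(sequences, stateNames = NULL) {
  if (is.character(sequences)) sequences <- list(sequences)
  if (length(sequences) == 0 || all(lengths(sequences) == 0))
    stop("no sequences provided")
  if (is.null(stateNames))
    stateNames <- sort(unique(unlist(sequences)))
  q <- length(stateNames)
  counts <- matrix(0, q, q, dimnames = list(stateNames, stateNames))
  for (s in sequences) {
    if (length(s) < 2) next
    from <- factor(s[-length(s)], levels = stateNames)
    to <- factor(s[-1], levels = stateNames)
    counts <- counts + table(from, to)
  }
  out <- rowSums(counts)
  degenerate <- stateNames[out == 0]
  A <- counts
  for (i in seq_len(q)) {
    if (out[i] == 0) {
      A[i, ] <- 0; A[i, i] <- 1
    } else A[i, ] <- counts[i, ] / out[i]
  }
  A <- unclass(A)
  attr(A, "degenerate") <- degenerate
  A
}

#' Empirical prior probabilities from sequence starts
#'
#' @param sequences list of character state sequences.
#' @param stateNames state vocabulary; default sorted union of observed
#'   states.
#' @return Named probability vector of initial-state frequencies.
#' @export
estimatePriors <- function(sequences, stateNames = NULL) {
  if (is.character(sequences)) sequences <- list(sequences)
  if (length(sequences) == 0) stop("no sequences provided")
  starts <- vapply(sequences, function(s) s[1], character(1))
  if (is.null(stateNames)) stateNames <- sort(unique(unlist(sequences)))
  tab <- table(factor(starts, levels = stateNames))
  p <- as.vector(tab) / sum(tab)
  names(p) <- stateNames
  p
}
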