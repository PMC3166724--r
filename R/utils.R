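# Internal numerical helpers.

# log(sum(exp(x))) without overflow; -Inf input handled.
logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Log density of rows of X under N(mean, sigma); Cholesky based.
dmvnormLog <- function(X, mean, sigma) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  d <- length(mean)
  stopifnot(ncol(X) == d)
  ch <- chol(sigma)
  z <- backsolve(ch, t(X) - mean, transpose = TRUE)
  if (is.null(dim(z))) z <- matrix(z, nrow = d)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * d * log(2 * pi)
}

# Clamp eigenvalues of a symmetric matrix from below; keeps the fit
# well-conditioned when a state has few frames.
floorEigenvalues <- function(sigma, floor) {
  e <- eigen(sigma, symmetric = TRUE)
  if (all(e$values >= floor)) return((sigma + t(sigma)) / 2)
  v <- pmax(e$values, floor)
  s <- e$vectors %*% (v * t(e$vectors))
  (s + t(s)) / 2
}

# Evaluate fn() under a locally seeded RNG stream, restoring the caller's
# RNG state afterwards. seed = NULL uses (and advances) the global stream.
withLocalSeed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

# Majority element; ties broken by returning NA (caller decides policy).
majorityLabel <- function(x) {
  tab <- table(x)
  top <- tab[tab == max(tab)]
  if (length(top) > 1) NA_character_ else names(top)
}
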