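# Shared constructors for small test models and datasets.

# Single-component mixture with given mean and covariance.
mix1 <- function(mu, sigma = NULL) {
  d <- length(mu)
  if (is.null(sigma)) sigma <- diag(d)
  new("MixtureModel", weights = 1, means = matrix(mu, 1),
    covariances = list(as.matrix(sigma)))
}

# Persistent Q-state chain with uniform off-diagonal mass.
persistentChain <- function(q = 3, diagp = 0.85, states = sprintf("S%d", 1:q)) {
  A <- matrix((1 - diagp) / (q - 1), q, q)
  diag(A) <- diagp
  markovModel(A, stateNames = states)
}

# Q=3 cHMM with unit-variance emissions whose means sit ~sep apart.
overlappingChmm <- function(sep = 1.5, diagp = 0.85) {
  omm <- persistentChain(3, diagp)
  new("CHMM", omm = omm, emissions = list(
    mix1(c(0, 0)), mix1(c(sep, 0)), mix1(c(sep / 2, sep * 0.87))))
}

# Well-separated Gaussian class data for classifier tests.
separatedClasses <- function(n = 30, sep = 10, d = 2, seed = 1) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n * d), n, d),
      matrix(rnorm(n * d, mean = sep), n, d))
    list(X = X, y = rep(c("a", "b"), each = n))
  })
}

# Direct-summation DFT magnitude oracle (independent of stats::fft).
oracleDftMod <- function(x) {
  n <- length(x)
  k <- 0:(n - 1)
  vapply(k, function(kk)
    Mod(sum(x * exp(-2i * pi * kk * (0:(n - 1)) / n))), numeric(1))
}
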