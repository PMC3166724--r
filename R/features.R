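# Per-frame feature variables. For ch channels with every family enabled
# the dimension is d = 3*ch + ch*(ch+1)/2: one DC, one energy and one
# entropy value per channel plus one correlation value per unordered
# channel pair including self-pairs.

#' DC component of one frame channel
#'
#' Mean of the raw samples in the frame; discriminates static postures
#' through the gravity projection on the sensor axis.
#'
#' @param x numeric sample vector (one channel of one frame).
#' @return Scalar mean.
#' @export
dcComponent <- function(x) {
  if (length(x) == 0) stop("empty frame")
  mean(x)
}

#' Spectral energy of one frame channel
#'
#' Sum of squared magnitude spectrum coefficients of the frame, excluding
#' the DC bin, normalized by the frame length. By Parseval's identity this
#' equals the total signal energy minus the DC contribution:
#' `energy + width * dc^2 = sum(x^2)`.
#'
#' @param x numeric sample vector.
#' @return Scalar energy (g^2 scale).
#' @export
spectralEnergy <- function(x) {
  n <- length(x)
  if (n == 0) stop("empty frame")
  X <- stats::fft(x)
  sum(Mod(X[-1])^2) / n
}

#' Spectral entropy of one frame channel
#'
#' Shannon entropy of a Gaussian kernel density estimate over the non-DC
#' magnitude spectrum coefficients, after normalizing the coefficients to
#' unit sum (which makes the feature invariant to amplitude scaling of the
#' frame). Captures frequency-domain complexity: a broadband frame spreads
#' its coefficients and scores high, a pure tone concentrates them and
#' scores low.
#'
#' The estimate uses Silverman's rule-of-thumb bandwidth and the entropy is
#' computed by trapezoidal integration of `-f log f` over the estimate's
#' support. Degenerate spectra (all-zero, or all coefficients identical)
#' return 0.
#'
#' @param x numeric sample vector with at least 4 samples (>= 2 non-DC
#'   one-sided bins).
#' @return Scalar entropy in nats.
#' @export
spectralEntropy <- function(x) {
  n <- length(x)
  if (n < 4) stop("frame too short for spectral entropy (need >= 4 samples)")
  X <- stats::fft(x)
  # one-sided non-DC magnitude coefficients
  co <- Mod(X[2:(n %/% 2 + 1)])
  s <- sum(co)
  if (s == 0) return(0)
  co <- co / s
  if (diff(range(co)) == 0) return(0)
  bw <- stats::bw.nrd0(co)
  de <- stats::density(co, bw = bw, n = 512)
  y <- de$y
  f <- ifelse(y > 0, -y * log(y), 0)
  dx <- diff(de$x)
  sum((f[-1] + f[-length(f)]) / 2 * dx)
}

#' Correlation coefficients between frame channels
#'
#' Elements of the frame's data covariance matrix: for every unordered pair
#' of channels, including self-pairs, the dot product of the two detrended
#' (mean-removed) channels divided by the frame width. `ch` channels give
#' `ch*(ch+1)/2` values (55 for 10 channels, 6 for 3).
#'
#' @param frame numeric matrix, width x channels.
#' @return Named numeric vector, pairs ordered (1,1), (1,2), ..., (ch,ch).
#' @export
correlationFeatures <- function(frame) {
  frame <- as.matrix(frame)
  w <- nrow(frame)
  ch <- ncol(frame)
  if (w == 0) stop("empty frame")
  centered <- sweep(frame, 2, colMeans(frame))
  cc <- crossprod(centered) / w
  idx <- which(upper.tri(cc, diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  out <- cc[idx]
  names(out) <- sprintf("corr_ch%d_ch%d", idx[, 1], idx[, 2])
  out
}

featureFamilies <- c("dc", "energy", "entropy", "correlation")

#' @describeIn extractFeatures one row of features per frame of a
#'   [FrameSet-class]; columns ordered as DC block, energy block, entropy
#'   block, correlation block.
#' @examples
#' rec <- recording(matrix(rnorm(3 * 200), ncol = 3), samplingRate = 50)
#' X <- extractFeatures(segmentFrames(rec, width = 64))
#' dim(X)   # frames x 15
#' @export
setMethod("extractFeatures", "FrameSet", function(object, families = c("dc",
    "energy", "entropy", "correlation")) {
  families <- match.arg(families, featureFamilies, several.ok = TRUE)
  frms <- frames(object)
  if (length(frms) == 0) stop("no frames to extract features from")
  rows <- lapply(frms, function(f) frameFeatures(f, families))
  X <- do.call(rbind, rows)
  rownames(X) <- NULL
  X
})

# Feature vector of a single frame (width x ch matrix).
frameFeatures <- function(frame, families = featureFamilies) {
  frame <- as.matrix(frame)
  ch <- ncol(frame)
  out <- numeric(0)
  if ("dc" %in% families) {
    v <- apply(frame, 2, dcComponent)
    names(v) <- sprintf("dc_ch%d", seq_len(ch))
    out <- c(out, v)
  }
  if ("energy" %in% families) {
    v <- apply(frame, 2, spectralEnergy)
    names(v) <- sprintf("energy_ch%d", seq_len(ch))
    out <- c(out, v)
  }
  if ("entropy" %in% families) {
    v <- apply(frame, 2, spectralEntropy)
    names(v) <- sprintf("entropy_ch%d", seq_len(ch))
    out <- c(out, v)
  }
  if ("correlation" %in% families)
    out <- c(out, correlationFeatures(frame))
  out
}

#' Number of features produced for a channel count
#'
#' @param ch number of measurement channels.
#' @param families enabled feature families.
#' @return Integer dimension d; with all families `3*ch + ch*(ch+1)/2`
#'   (85 for ch = 10, 15 for ch = 3).
#' @export
featureCount <- function(ch, families = c("dc", "energy", "entropy",
    "correlation")) {
  families <- match.arg(families, featureFamilies, several.ok = TRUE)
  sum(c(dc = ch, energy = ch, entropy = ch,
    correlation = ch * (ch + 1) / 2)[families])
}
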