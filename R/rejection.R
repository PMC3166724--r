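# Threshold-based rejection of spurious frames. A frame whose class-
# conditional density is below the threshold for every state carries too
# little evidence for any known activity and is removed before decoding;
# no extra garbage state or mixture component is introduced.

#' Frame rejection statistic
#'
#' The per-frame statistic thresholded by the detector: the maximum over
#' states of the class-conditional log-density, `max_i log p(x | S_i)`.
#'
#' @param logDensities frames x states matrix of log p(x | S_i).
#' @return Numeric vector, one value per frame.
#' @export
rejectionStatistic <- function(logDensities) {
  apply(as.matrix(logDensities), 1, max)
}

#' Flag spurious frames by likelihood thresholding
#'
#' A frame is marked spurious iff the class-conditional log-density is
#' below `threshold` for every state, i.e. iff
#' `max_i log p(x | S_i) < threshold`.
#'
#' @param logDensities frames x states matrix of log p(x | S_i).
#' @param threshold rejection threshold on the log-density scale
#'   (`-Inf` rejects nothing, `Inf` rejects everything).
#' @return Logical vector, `TRUE` for rejected frames.
#' @export
rejectionMask <- function(logDensities, threshold) {
  rejectionStatistic(logDensities) < threshold
}

#' Sensitivity-specificity curve of the rejection detector
#'
#' Evaluates the detector over a grid of thresholds (the sorted unique
#' statistic values plus `-Inf`). Spurious frames are the positive class:
#' sensitivity is the fraction of truly spurious frames rejected and
#' specificity the fraction of genuine frames retained. Along increasing
#' thresholds sensitivity is non-decreasing and specificity
#' non-increasing.
#'
#' @param logDensities frames x states matrix of log p(x | S_i).
#' @param trueSpurious logical vector of ground-truth garbage flags.
#' @return Data frame with columns `threshold`, `sensitivity`,
#'   `specificity`.
#' @export
rocCurve <- function(logDensities, trueSpurious) {
  stat <- rejectionStatistic(logDensities)
  trueSpurious <- as.logical(trueSpurious)
  if (length(stat) != length(trueSpurious))
    stop("one ground-truth flag per frame required")
  if (all(trueSpurious) || !any(trueSpurious))
    stop("both spurious and genuine frames are required for a ROC curve")
  grid <- c(-Inf, sort(unique(stat)))
  se <- vapply(grid, function(th) mean(stat[trueSpurious] < th), numeric(1))
  sp <- vapply(grid, function(th) mean(stat[!trueSpurious] >= th), numeric(1))
  data.frame(threshold = grid, sensitivity = se, specificity = sp)
}

#' Select the rejection threshold from a ROC curve
#'
#' Chooses the operating point where the specificity is slightly greater
#' than the sensitivity: the largest grid threshold at which
#' `specificity >= sensitivity` (the point just before sensitivity
#' overtakes specificity). If specificity is below sensitivity everywhere,
#' the threshold minimizing their gap is returned.
#'
#' @param roc data frame from [rocCurve()].
#' @return Scalar threshold.
#' @export
selectThreshold <- function(roc) {
  if (nrow(roc) == 0) stop("empty ROC curve")
  ok <- roc$specificity >= roc$sensitivity
  if (any(ok)) max(roc$threshold[ok])
  else roc$threshold[which.min(abs(roc$specificity - roc$sensitivity))]
}
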