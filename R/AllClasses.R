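#' Multichannel accelerometer recording
#'
#' Container for a fixed-rate multichannel acceleration time series, in g
#' units, with optional per-sample activity annotations. All channels share
#' one time base.
#'
#' @slot channels numeric matrix, one row per sample, one column per axis.
#' @slot samplingRate sampling rate in Hz (positive scalar).
#' @slot annotations character vector of per-sample activity labels
#'   (`"transition"` and `"unknown"` are reserved), or length zero when the
#'   recording is unannotated.
#' @slot subjectId subject identifier.
#'
#' @seealso [readRecording()], [segmentFrames()]
#' @export
setClass("Recording",
  representation(
    channels = "matrix",
    samplingRate = "numeric",
    annotations = "character",
    subjectId = "character"
  ),
  prototype(annotations = character(0), subjectId = "s1")
)

setValidity("Recording", function(object) {
  msg <- character(0)
  if (!is.numeric(object@channels))
    msg <- c(msg, "channels must be a numeric matrix")
  if (length(object@samplingRate) != 1 || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a positive scalar (Hz)")
  if (length(object@annotations) > 0 &&
      length(object@annotations) != nrow(object@channels))
    msg <- c(msg, "annotations must have one label per sample")
  if (length(msg)) msg else TRUE
})

#' Set of sliding-window data frames
#'
#' Fixed-width, possibly overlapping windows cut from a [Recording-class].
#' Each frame is a (width x channels) block of raw samples; one feature
#' vector is later computed per frame. Frames never extend past the end of
#' the recording (trailing samples are dropped, no padding).
#'
#' @slot frames list of numeric matrices (width x channels).
#' @slot width frame width in samples.
#' @slot step hop between consecutive frame starts in samples.
#' @slot samplingRate sampling rate in Hz, inherited from the recording.
#' @slot frameLabels per-frame majority label; `"transition"` for frames
#'   overlapping annotated transition zones; `NA` when unannotated.
#' @slot spurious logical per-frame garbage indicator (used by the virtual
#'   experiment generator); length zero when unknown.
#'
#' @export
setClass("FrameSet",
  representation(
    frames = "list",
    width = "integer",
    step = "integer",
    samplingRate = "numeric",
    frameLabels = "character",
    spurious = "logical"
  ),
  prototype(frameLabels = character(0), spurious = logical(0))
)

setValidity("FrameSet", function(object) {
  msg <- character(0)
  if (length(object@frames)) {
    dims <- vapply(object@frames, function(f) dim(f)[1L], integer(1))
    if (any(dims != object@width))
      msg <- c(msg, "all frames must have `width` rows")
  }
  if (object@width < 1L || object@step < 1L)
    msg <- c(msg, "width and step must be positive")
  if (length(object@frameLabels) > 0 &&
      length(object@frameLabels) != length(object@frames))
    msg <- c(msg, "frameLabels must have one entry per frame")
  if (length(object@spurious) > 0 &&
      length(object@spurious) != length(object@frames))
    msg <- c(msg, "spurious must have one entry per frame")
  if (length(msg)) msg else TRUE
})

#' Observable Markov model over activity states
#'
#' The pair (pi, A) of prior probabilities and the row-stochastic transition
#' probability matrix (TPM) governing a first-order Markov chain whose states
#' are activity primitives. pi_i = P(X(t0) = S_i) and
#' a_ij = P(X(t_n) = S_j | X(t_n-1) = S_i).
#'
#' @slot priors numeric prior probability vector pi of length Q.
#' @slot tpm Q x Q row-stochastic transition matrix A.
#' @slot stateNames labels of the Q states.
#'
#' @seealso [markovModel()], [sampleChain()], [estimateTpm()]
#' @export
setClass("MarkovModel",
  representation(
    priors = "numeric",
    tpm = "matrix",
    stateNames = "character"
  )
)

setValidity("MarkovModel", function(object) {
  msg <- character(0)
  q <- length(object@priors)
  tol <- 1e-9
  if (!all(dim(object@tpm) == c(q, q)))
    msg <- c(msg, "tpm must be Q x Q with Q = length(priors)")
  if (length(object@stateNames) != q)
    msg <- c(msg, "stateNames must have one label per state")
  if (any(object@priors < -tol) || abs(sum(object@priors) - 1) > tol)
    msg <- c(msg, "priors must be a probability vector (sum 1 within 1e-9)")
  if (any(object@tpm < -tol) || any(object@tpm > 1 + tol))
    msg <- c(msg, "tpm entries must lie in [0, 1]")
  if (nrow(object@tpm) == q && any(abs(rowSums(object@tpm) - 1) > tol))
    msg <- c(msg, "every tpm row must sum to 1 within 1e-9")
  if (length(msg)) msg else TRUE
})

#' Gaussian mixture density
#'
#' A mixture of M multivariate normal components with full covariance
#' matrices: p(x) = sum_m c_m N(x | mu_m, Sigma_m), sum_m c_m = 1. Used both
#' as the class-conditional density of the single-frame classifier and as
#' the per-state emission density of the sequential classifier.
#'
#' @slot weights mixing coefficients c_m, length M, summing to one.
#' @slot means M x d matrix of component means.
#' @slot covariances list of M symmetric positive-definite d x d matrices.
#'
#' @seealso [fitMixture()], [mixtureDensity()]
#' @export
setClass("MixtureModel",
  representation(
    weights = "numeric",
    means = "matrix",
    covariances = "list"
  )
)

setValidity("MixtureModel", function(object) {
  msg <- character(0)
  m <- length(object@weights)
  d <- ncol(object@means)
  if (abs(sum(object@weights) - 1) > 1e-9 || any(object@weights < 0))
    msg <- c(msg, "mixing weights must be non-negative and sum to 1 within 1e-9")
  if (nrow(object@means) != m)
    msg <- c(msg, "means must have one row per component")
  if (length(object@covariances) != m)
    msg <- c(msg, "covariances must have one matrix per component")
  ok <- vapply(object@covariances, function(s) {
    is.matrix(s) && all(dim(s) == d) && isSymmetric(s, tol = 1e-8)
  }, logical(1))
  if (!all(ok))
    msg <- c(msg, "each covariance must be a symmetric d x d matrix")
  if (length(msg)) msg else TRUE
})

#' Single-frame Gaussian mixture classifier
#'
#' One [MixtureModel-class] per activity class; a frame is assigned to the
#' class whose class-conditional density p(x | w_i) is highest. No class
#' priors enter the decision.
#'
#' @slot classes class labels.
#' @slot mixtures list of per-class [MixtureModel-class] objects.
#'
#' @seealso [fitGmmClassifier()], [classifyFrames()]
#' @export
setClass("GmmClassifier",
  representation(
    classes = "character",
    mixtures = "list"
  )
)

setValidity("GmmClassifier", function(object) {
  msg <- character(0)
  if (length(object@classes) != length(object@mixtures))
    msg <- c(msg, "one mixture per class required")
  d <- vapply(object@mixtures, function(m) ncol(m@means), integer(1))
  if (length(unique(d)) > 1)
    msg <- c(msg, "all class mixtures must share the feature dimension")
  if (length(msg)) msg else TRUE
})

#' Continuous-emission hidden Markov model classifier
#'
#' A [MarkovModel-class] (pi, A) over hidden activity states plus one
#' Gaussian [MixtureModel-class] emission density per state. Trained in two
#' levels: supervised counting/fitting on labeled frames, then optional
#' Baum-Welch refinement; decoded with the Viterbi algorithm.
#'
#' @slot omm the observable Markov model (pi, A).
#' @slot emissions list of per-state [MixtureModel-class] objects.
#'
#' @seealso [trainLevel1()], [trainLevel2()], [viterbiDecode()]
#' @export
setClass("CHMM",
  representation(
    omm = "MarkovModel",
    emissions = "list"
  )
)

setValidity("CHMM", function(object) {
  msg <- character(0)
  if (length(object@emissions) != length(object@omm@priors))
    msg <- c(msg, "one emission model per state required")
  d <- vapply(object@emissions, function(m) ncol(m@means), integer(1))
  if (length(unique(d)) > 1)
    msg <- c(msg, "all emission models must share the feature dimension")
  if (length(msg)) msg else TRUE
})

#' Labeled feature-vector sequence
#'
#' A time-ordered feature matrix (one row per data frame) with per-frame
#' state labels, garbage indicators and a subject identifier; the unit of
#' training and testing for the sequential classifier.
#'
#' @slot X numeric T x d feature matrix.
#' @slot y character labels per frame (state names, `"transition"`,
#'   `"garbage"` or `NA`).
#' @slot spurious logical garbage flags per frame.
#' @slot subjectId subject identifier.
#'
#' @export
setClass("LabeledSequence",
  representation(
    X = "matrix",
    y = "character",
    spurious = "logical",
    subjectId = "character"
  ),
  prototype(subjectId = "s1")
)

setValidity("LabeledSequence", function(object) {
  msg <- character(0)
  if (length(object@y) != nrow(object@X))
    msg <- c(msg, "y must have one label per frame (row of X)")
  if (length(object@spurious) > 0 &&
      length(object@spurious) != nrow(object@X))
    msg <- c(msg, "spurious must have one flag per frame")
  if (length(msg)) msg else TRUE
})

#' Activity emission specification for the synthetic generator
#'
#' Parametric description of the raw acceleration signal emitted while one
#' activity is performed: per-channel DC baseline (gravity projection),
#' per-channel harmonic content (movement rhythmicity) and correlated
#' Gaussian sensor/movement noise. A declared stand-in for real per-activity
#' signal morphology.
#'
#' @slot name activity name.
#' @slot dc per-channel baseline in g.
#' @slot harmonics list (one entry per channel) of matrices with columns
#'   `freq` (Hz) and `amp` (g).
#' @slot noiseSd standard deviation of the additive Gaussian noise (g).
#' @slot crossChannelCorr equicorrelation of the noise across channels.
#'
#' @seealso [activitySpec()], [generateFramePool()]
#' @export
setClass("ActivityEmissionSpec",
  representation(
    name = "character",
    dc = "numeric",
    harmonics = "list",
    noiseSd = "numeric",
    crossChannelCorr = "numeric"
  )
)

setValidity("ActivityEmissionSpec", function(object) {
  msg <- character(0)
  if (length(object@harmonics) != length(object@dc))
    msg <- c(msg, "harmonics must have one entry per channel")
  if (object@noiseSd < 0)
    msg <- c(msg, "noiseSd must be non-negative")
  if (abs(object@crossChannelCorr) > 1)
    msg <- c(msg, "crossChannelCorr must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' Pool of raw frames for one activity
#'
#' The N frames available for one subject and one activity, from which the
#' virtual experiment draws with replacement whenever the Markov chain
#' occupies the matching state.
#'
#' @slot activity activity (state) name.
#' @slot frames list of (width x channels) numeric matrices.
#' @slot subjectId subject identifier.
#' @slot samplingRate sampling rate in Hz.
#'
#' @seealso [generateFramePool()], [virtualExperiment()]
#' @export
setClass("FramePool",
  representation(
    activity = "character",
    frames = "list",
    subjectId = "character",
    samplingRate = "numeric"
  ),
  prototype(subjectId = "s1")
)

setValidity("FramePool", function(object) {
  if (length(object@frames) < 1) "pool must contain at least one frame" else TRUE
})

# ---- show methods ----

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording: %d samples x %d channels at %g Hz (%.2f s), subject %s\n",
    nrow(object@channels), ncol(object@channels), object@samplingRate,
    nrow(object@channels) / object@samplingRate, object@subjectId))
  if (length(object@annotations))
    cat("  annotated: ", paste(unique(object@annotations), collapse = ", "), "\n",
      sep = "")
})

setMethod("show", "FrameSet", function(object) {
  ch <- if (length(object@frames)) ncol(object@frames[[1]]) else 0L
  cat(sprintf("FrameSet: %d frames of %d samples x %d channels (step %d)\n",
    length(object@frames), object@width, ch, object@step))
  if (length(object@frameLabels))
    cat("  labels: ", paste(utils::head(unique(object@frameLabels), 8),
      collapse = ", "), "\n", sep = "")
})

setMethod("show", "MarkovModel", function(object) {
  cat(sprintf("MarkovModel with %d states: %s\n", length(object@priors),
    paste(object@stateNames, collapse = ", ")))
  cat("  priors:", paste(sprintf("%.3f", object@priors), collapse = " "), "\n")
})

setMethod("show", "MixtureModel", function(object) {
  cat(sprintf("MixtureModel: M = %d components in d = %d dimensions\n",
    length(object@weights), ncol(object@means)))
})

setMethod("show", "GmmClassifier", function(object) {
  cat(sprintf("GmmClassifier over %d classes (d = %d): %s\n",
    length(object@classes), ncol(object@mixtures[[1]]@means),
    paste(object@classes, collapse = ", ")))
})

setMethod("show", "CHMM", function(object) {
  cat(sprintf("CHMM: %d states, M = %d mixture components, d = %d\n",
    length(object@omm@priors), length(object@emissions[[1]]@weights),
    ncol(object@emissions[[1]]@means)))
  cat("  states: ", paste(object@omm@stateNames, collapse = ", "), "\n", sep = "")
})

setMethod("show", "LabeledSequence", function(object) {
  cat(sprintf("LabeledSequence: T = %d frames, d = %d features, subject %s\n",
    nrow(object@X), ncol(object@X), object@subjectId))
  if (length(object@spurious))
    cat(sprintf("  spurious frames: %d\n", sum(object@spurious)))
})

setMethod("show", "FramePool", function(object) {
  cat(sprintf("FramePool '%s': N = %d frames, subject %s\n",
    object@activity, length(object@frames), object@subjectId))
})

# ---- accessors ----

#' @rdname channels
#' @export
setMethod("channels", "Recording", function(object) object@channels)

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "Recording", function(object) object@samplingRate)

#' @rdname annotations
#' @export
setMethod("annotations", "Recording", function(object) {
  if (length(object@annotations)) object@annotations else NULL
})

#' @rdname subjectId
#' @export
setMethod("subjectId", "Recording", function(object) object@subjectId)

#' @rdname frames
#' @export
setMethod("frames", "FrameSet", function(object) object@frames)

#' @rdname frameLabels
#' @export
setMethod("frameLabels", "FrameSet", function(object) {
  if (length(object@frameLabels)) object@frameLabels else NULL
})

#' @rdname spuriousFlags
#' @export
setMethod("spuriousFlags", "FrameSet", function(object) {
  if (length(object@spurious)) object@spurious else NULL
})

#' @rdname nStates
#' @export
setMethod("nStates", "MarkovModel", function(object) length(object@priors))

#' @rdname nStates
#' @export
setMethod("nStates", "CHMM", function(object) length(object@omm@priors))

#' @rdname stateNames
#' @export
setMethod("stateNames", "MarkovModel", function(object) object@stateNames)

#' @rdname stateNames
#' @export
setMethod("stateNames", "CHMM", function(object) object@omm@stateNames)

#' @rdname priors
#' @export
setMethod("priors", "MarkovModel", function(object) object@priors)

#' @rdname priors
#' @export
setMethod("priors", "CHMM", function(object) object@omm@priors)

#' @rdname transitionMatrix
#' @export
setMethod("transitionMatrix", "MarkovModel", function(object) object@tpm)

#' @rdname transitionMatrix
#' @export
setMethod("transitionMatrix", "CHMM", function(object) object@omm@tpm)

#' @rdname mixtureWeights
#' @export
setMethod("mixtureWeights", "MixtureModel", function(object) object@weights)

#' @rdname emissionModels
#' @export
setMethod("emissionModels", "CHMM", function(object) object@emissions)

#' @rdname featureMatrix
#' @export
setMethod("featureMatrix", "LabeledSequence", function(object) object@X)

#' @rdname frameLabels
#' @export
setMethod("frameLabels", "LabeledSequence", function(object) object@y)

#' @rdname spuriousFlags
#' @export
setMethod("spuriousFlags", "LabeledSequence", function(object) {
  if (length(object@spurious)) object@spurious else rep(FALSE, nrow(object@X))
})

#' @rdname subjectId
#' @export
setMethod("subjectId", "LabeledSequence", function(object) object@subjectId)
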