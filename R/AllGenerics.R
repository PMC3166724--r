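#' Number of states of a Markov or hidden Markov model
#'
#' @param object a [MarkovModel-class] or [CHMM-class] object.
#' @return Integer number of states.
#' @export
setGeneric("nStates", function(object) standardGeneric("nStates"))

#' State names
#'
#' @param object a [MarkovModel-class] or [CHMM-class] object.
#' @return Character vector of state labels.
#' @export
setGeneric("stateNames", function(object) standardGeneric("stateNames"))

#' Prior state probabilities
#'
#' @param object a [MarkovModel-class] or [CHMM-class] object.
#' @return Numeric probability vector over states.
#' @export
setGeneric("priors", function(object) standardGeneric("priors"))

#' Transition probability matrix
#'
#' @param object a [MarkovModel-class] or [CHMM-class] object.
#' @return Row-stochastic numeric matrix.
#' @export
setGeneric("transitionMatrix", function(object) standardGeneric("transitionMatrix"))

#' Sampled signal channels of a recording
#'
#' @param object a [Recording-class] object.
#' @return Numeric matrix, one column per accelerometer axis.
#' @export
setGeneric("channels", function(object) standardGeneric("channels"))

#' Sampling rate in Hz
#'
#' @param object a [Recording-class] object.
#' @return Sampling rate (Hz).
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' Per-sample annotations of a recording
#'
#' @param object a [Recording-class] object.
#' @return Character vector of per-sample labels, or `NULL` when absent.
#' @export
setGeneric("annotations", function(object) standardGeneric("annotations"))

#' Frames of a segmented recording
#'
#' @param object a [FrameSet-class] object.
#' @return List of numeric matrices (width x channels), one per frame.
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))

#' Per-frame labels
#'
#' @param object a [FrameSet-class] or [LabeledSequence-class] object.
#' @return Character vector of frame labels (possibly `NA`).
#' @export
setGeneric("frameLabels", function(object) standardGeneric("frameLabels"))

#' Spurious-frame indicator
#'
#' @param object a [FrameSet-class] or [LabeledSequence-class] object.
#' @return Logical vector flagging garbage (spurious) frames.
#' @export
setGeneric("spuriousFlags", function(object) standardGeneric("spuriousFlags"))

#' Feature matrix of a labeled sequence
#'
#' @param object a [LabeledSequence-class] object.
#' @return Numeric matrix, frames in rows, features in columns.
#' @export
setGeneric("featureMatrix", function(object) standardGeneric("featureMatrix"))

#' Subject identifier
#'
#' @param object an object carrying a subject id.
#' @return Character scalar.
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))

#' Extract per-frame feature vectors
#'
#' @param object a [FrameSet-class] (or object containing one).
#' @param families character vector of feature families to compute, any of
#'   `"dc"`, `"energy"`, `"entropy"`, `"correlation"`.
#' @return Numeric feature matrix with one row per frame and named columns.
#' @export
setGeneric("extractFeatures", function(object, families = c("dc", "energy",
  "entropy", "correlation")) standardGeneric("extractFeatures"))

#' Mixing weights of a Gaussian mixture
#'
#' @param object a [MixtureModel-class] object.
#' @return Numeric vector summing to one.
#' @export
setGeneric("mixtureWeights", function(object) standardGeneric("mixtureWeights"))

#' Emission mixtures of a continuous-emission HMM
#'
#' @param object a [CHMM-class] object.
#' @return List of per-state [MixtureModel-class] objects.
#' @export
setGeneric("emissionModels", function(object) standardGeneric("emissionModels"))
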