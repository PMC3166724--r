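# Plain-text (JSON) model persistence so that trained classifiers can be
# reused at decode time or shipped alongside a recording.

modelToList <- function(object) {
  if (is(object, "MarkovModel")) {
    list(type = "MarkovModel", stateNames = object@stateNames,
      priors = object@priors, tpm = object@tpm)
  } else if (is(object, "MixtureModel")) {
    list(type = "MixtureModel", weights = object@weights,
      means = object@means, covariances = object@covariances)
  } else if (is(object, "GmmClassifier")) {
    list(type = "GmmClassifier", classes = object@classes,
      mixtures = lapply(object@mixtures, modelToList))
  } else if (is(object, "CHMM")) {
    list(type = "CHMM", omm = modelToList(object@omm),
      emissions = lapply(object@emissions, modelToList))
  } else stop("cannot serialize objects of class ", class(object))
}

modelFromList <- function(x) {
  asMat <- function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  }
  switch(x$type,
    MarkovModel = markovModel(asMat(x$tpm), priors = unlist(x$priors),
      stateNames = unlist(x$stateNames), mode = "renormalize"),
    MixtureModel = {
      covs <- x$covariances
      if (is.array(covs) && length(dim(covs)) == 3)
        covs <- lapply(seq_len(dim(covs)[1]), function(m) covs[m, , ])
      new("MixtureModel", weights = unlist(x$weights),
        means = asMat(x$means), covariances = lapply(covs, asMat))
    },
    GmmClassifier = new("GmmClassifier", classes = unlist(x$classes),
      mixtures = lapply(x$mixtures, modelFromList)),
    CHMM = new("CHMM", omm = modelFromList(x$omm),
      emissions = lapply(x$emissions, modelFromList)),
    stop("unknown model type: ", x$type))
}

#' Save a model to a JSON file
#'
#' Works for [MarkovModel-class], [MixtureModel-class],
#' [GmmClassifier-class] and [CHMM-class] objects; numbers are written at
#' full precision.
#'
#' @param object the model to save.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
saveModel <- function(object, path) {
  jsonlite::write_json(modelToList(object), path, auto_unbox = TRUE,
    digits = NA)
  invisible(path)
}

#' Load a model saved by [saveModel()]
#'
#' @param path path to the JSON model file.
#' @return The reconstructed model object.
#' @export
loadModel <- function(path) {
  modelFromList(jsonlite::fromJSON(path, simplifyVector = TRUE,
    simplifyDataFrame = FALSE, simplifyMatrix = TRUE))
}
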