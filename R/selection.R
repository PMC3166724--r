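# Feature selection: sequential floating forward-backward search driven by
# a within-class Euclidean-distance compactness criterion, with the final
# subset size arbitrated by k-NN cross-validated accuracy; principal
# component analysis for rotation / dimensionality reduction afterwards.
# Features are standardized (training statistics) before any distance is
# computed: the raw features mix units (g, g^2, nats).

# Within-class compactness criterion: negative mean Euclidean distance
# over all same-class pairs, on standardized features restricted to
# `subset`. Larger is better.
distanceCriterion <- function(Xs, y, subset) {
  val <- 0; npairs <- 0
  for (cl in unique(y)) {
    Xc <- Xs[y == cl, subset, drop = FALSE]
    if (nrow(Xc) < 2) next
    dd <- stats::dist(Xc)
    val <- val + sum(dd)
    npairs <- npairs + length(dd)
  }
  if (npairs == 0) stop("need at least two samples in some class")
  -val / npairs
}

# k-NN cross-validated accuracy of a feature subset.
knnCvAccuracy <- function(Xs, y, subset, k, folds, seed) {
  n <- nrow(Xs)
  withLocalSeed(seed, function() {
    fold <- sample(rep_len(seq_len(folds), n))
    correct <- 0
    for (f in seq_len(folds)) {
      te <- fold == f
      if (!any(te) || all(te)) next
      pred <- class::knn(Xs[!te, subset, drop = FALSE],
        Xs[te, subset, drop = FALSE], factor(y[!te]), k = k)
      correct <- correct + sum(pred == y[te])
    }
    correct / n
  })
}

#' Sequential floating forward-backward feature selection
#'
#' Pudil-style floating search. Conditional inclusion and exclusion steps
#' are driven by a within-class compactness criterion (negative mean
#' Euclidean distance between same-class feature vectors, standardized
#' features); the search keeps the best subset found at every size and
#' terminates once every feature has entered the candidate set at least
#' once. A k-nearest-neighbour cross-validation study then arbitrates the
#' final size: the minimal-size subset maximizing the cross-validated
#' accuracy is selected (ties resolve to the smaller size, then
#' lexicographic index order).
#'
#' @param X numeric feature matrix (samples x features).
#' @param y class labels (at least two classes, two samples per class).
#' @param k neighbours for the k-NN criterion.
#' @param folds cross-validation folds.
#' @param seed integer seed fixing fold assignment and k-NN tie-breaks.
#' @return List with `selected` (ordered feature indices), `knnAccuracy`
#'   (accuracy of the selected subset), and `criterionTrace` (data frame of
#'   size, compactness criterion and k-NN accuracy of the best subset per
#'   size).
#' @export
sffsSelect <- function(X, y, k = 5, folds = 10, seed = 1) {
  X <- as.matrix(X)
  y <- as.character(y)
  if (length(unique(y)) < 2)
    stop("feature selection needs at least two classes")
  if (min(table(y)) < 2)
    stop("every class needs at least two samples")
  if (k >= min(table(y)))
    stop("k must be smaller than the smallest class size")
  d <- ncol(X)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1   # constant columns: eligible but inert
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  if (d == 1) {
    acc <- knnCvAccuracy(Xs, y, 1L, k, folds, seed)
    return(list(selected = 1L, knnAccuracy = acc,
      criterionTrace = data.frame(size = 1L,
        criterion = distanceCriterion(Xs, y, 1L), accuracy = acc)))
  }
  best <- vector("list", d)   # best subset per size
  current <- integer(0)
  everIncluded <- logical(d)
  record <- function(subset) {
    sz <- length(subset)
    j <- distanceCriterion(Xs, y, subset)
    if (is.null(best[[sz]]) || j > best[[sz]]$criterion)
      best[[sz]] <<- list(subset = sort(subset), criterion = j)
    j
  }
  while (!all(everIncluded) && length(current) < d) {
    # conditional inclusion: best single addition by the criterion
    cand <- setdiff(seq_len(d), current)
    js <- vapply(cand, function(f)
      distanceCriterion(Xs, y, c(current, f)), numeric(1))
    add <- cand[which.max(js)]
    current <- c(current, add)
    everIncluded[add] <- TRUE
    record(current)
    # conditional exclusion: backtrack while dropping the least
    # significant feature improves on the best subset of the smaller size
    firstExclusion <- TRUE
    while (length(current) > 2) {
      js <- vapply(seq_along(current), function(i)
        distanceCriterion(Xs, y, current[-i]), numeric(1))
      drop <- which.max(js)
      # never immediately undo the inclusion that just happened
      if (firstExclusion && current[drop] == add) break
      firstExclusion <- FALSE
      sz <- length(current) - 1L
      if (!is.null(best[[sz]]) && js[drop] <= best[[sz]]$criterion) break
      current <- current[-drop]
      record(current)
    }
  }
  sizes <- which(!vapply(best, is.null, logical(1)))
  accs <- vapply(sizes, function(sz)
    knnCvAccuracy(Xs, y, best[[sz]]$subset, k, folds, seed), numeric(1))
  top <- max(accs)
  pick <- sizes[accs >= top - 1e-12]
  sel <- best[[min(pick)]]$subset
  list(selected = sel,
    knnAccuracy = accs[match(min(pick), sizes)],
    criterionTrace = data.frame(size = sizes,
      criterion = vapply(sizes, function(sz) best[[sz]]$criterion,
        numeric(1)),
      accuracy = accs))
}

#' Fit a principal component rotation
#'
#' Eigendecomposition of the sample covariance of column-standardized
#' features. The number of retained components is either given explicitly
#' or chosen as the smallest count whose cumulative variance fraction
#' reaches `varianceTarget` (1 keeps all components: pure rotation).
#'
#' @param X numeric feature matrix.
#' @param varianceTarget fraction of variance to retain in (0, 1].
#' @param nKeep explicit number of components (overrides
#'   `varianceTarget`).
#' @return List with `rotation` (orthonormal d x d), `varianceFractions`,
#'   `nKeep`, and the training `center`/`scale` used for
#'   standardization.
#' @export
pcaFit <- function(X, varianceTarget = 1, nKeep = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least two samples")
  sdv <- apply(X, 2, stats::sd)
  if (all(sdv == 0)) stop("zero-variance data")
  if (any(sdv == 0))
    stop("zero-variance feature column(s): ",
      paste(which(sdv == 0), collapse = ", "))
  ctr <- colMeans(X)
  Xs <- sweep(sweep(X, 2, ctr), 2, sdv, "/")
  pc <- stats::prcomp(Xs, center = FALSE, scale. = FALSE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  if (is.null(nKeep)) {
    stopifnot(varianceTarget > 0, varianceTarget <= 1)
    nKeep <- which(cumsum(vf) >= varianceTarget - 1e-12)[1]
  }
  rot <- pc$rotation
  # pad in the degenerate n <= d case so the basis stays d x d
  if (ncol(rot) < ncol(X)) {
    vf <- c(vf, rep(0, ncol(X) - length(vf)))
    rot <- qr.Q(qr(cbind(rot, diag(ncol(X)))))[, seq_len(ncol(X))]
  }
  list(rotation = rot, varianceFractions = vf, nKeep = as.integer(nKeep),
    center = ctr, scale = sdv)
}

#' Project features onto retained principal components
#'
#' @param model a fit from [pcaFit()].
#' @param X numeric feature matrix with matching columns.
#' @return Score matrix (samples x `nKeep`).
#' @export
pcaTransform <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$center))
    stop("dimension mismatch: model expects ", length(model$center),
      " columns, got ", ncol(X))
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  Xs %*% model$rotation[, seq_len(model$nKeep), drop = FALSE]
}

#' Map principal component scores back to feature space
#'
#' Exact inverse when all components are kept; the least-squares
#' reconstruction otherwise.
#'
#' @param model a fit from [pcaFit()].
#' @param scores score matrix from [pcaTransform()].
#' @return Reconstructed feature matrix on the original scale.
#' @export
pcaInverse <- function(model, scores) {
  scores <- as.matrix(scores)
  Xs <- scores %*% t(model$rotation[, seq_len(ncol(scores)), drop = FALSE])
  sweep(sweep(Xs, 2, model$scale, "*"), 2, model$center, "+")
}
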