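# Leave-one-subject-out validation, accuracy / confusion / Se-Sp metrics
# and the virtual-experiment study driver.

#' Cross-validation report
#'
#' Aggregated results of a leave-one-subject-out evaluation.
#'
#' @slot classifier classifier evaluated (`"gmm"`, `"chmm1"` or
#'   `"chmm2"`).
#' @slot perSubjectAccuracy named accuracy per held-out subject.
#' @slot confusion aggregated confusion matrix over retained genuine test
#'   frames (rows: true class; columns: predicted).
#' @slot rejection named vector with the detector's pooled sensitivity and
#'   specificity (length zero when rejection was off).
#' @slot settings evaluation settings (M, reject flag, seed, ...).
#' @export
setClass("CVReport",
  representation(
    classifier = "character",
    perSubjectAccuracy = "numeric",
    confusion = "matrix",
    rejection = "numeric",
    settings = "list"
  )
)

setMethod("show", "CVReport", function(object) {
  acc <- object@perSubjectAccuracy
  cat(sprintf("CVReport [%s%s]: accuracy %.1f%% +/- %.1f%% over %d subjects\n",
    object@classifier,
    if (isTRUE(object@settings$reject)) " + rejection" else "",
    100 * mean(acc), 100 * stats::sd(acc), length(acc)))
  if (length(object@rejection))
    cat(sprintf("  rejection Se = %.1f%%, Sp = %.1f%%\n",
      100 * object@rejection["sensitivity"],
      100 * object@rejection["specificity"]))
})

#' Mean leave-one-subject-out accuracy of a report
#'
#' @param report a [CVReport-class] object.
#' @return Mean of the per-subject accuracies.
#' @export
cvAccuracy <- function(report) mean(report@perSubjectAccuracy)

#' Leave-one-subject-out folds
#'
#' @param data list of [LabeledSequence-class] objects.
#' @return List of folds, each with `trainIdx`, `testIdx` (indices into
#'   `data`) and `subject` (the held-out subject). Every subject is tested
#'   exactly once.
#' @export
losoSplit <- function(data) {
  subjects <- vapply(data, subjectId, character(1))
  uniq <- unique(subjects)
  if (length(uniq) < 2)
    stop("leave-one-subject-out needs at least two subjects")
  lapply(uniq, function(s)
    list(trainIdx = which(subjects != s), testIdx = which(subjects == s),
      subject = s))
}

#' Sensitivity and specificity of the rejection detector
#'
#' Spurious frames are the positive class: Se = TP / (TP + FN) (spurious
#' frames correctly rejected), Sp = TN / (TN + FP) (genuine frames
#' correctly retained).
#'
#' @param predFlags logical predicted rejection flags.
#' @param trueFlags logical ground-truth spurious flags.
#' @return Named vector `c(sensitivity, specificity)`.
#' @export
rejectionPerformance <- function(predFlags, trueFlags) {
  predFlags <- as.logical(predFlags); trueFlags <- as.logical(trueFlags)
  if (all(trueFlags) || !any(trueFlags))
    stop("ground truth must contain both spurious and genuine frames")
  c(sensitivity = mean(predFlags[trueFlags]),
    specificity = mean(!predFlags[!trueFlags]))
}

#' Confusion counts between true and predicted labels
#'
#' @param true true class labels.
#' @param pred predicted class labels.
#' @param classes class vocabulary (row and column order).
#' @return Q x Q integer matrix, rows = true class, columns = predicted.
#' @export
confusionCounts <- function(true, pred, classes = sort(unique(c(true, pred)))) {
  tab <- table(factor(true, levels = classes),
    factor(pred, levels = classes))
  m <- matrix(as.integer(tab), nrow = length(classes),
    dimnames = list(true = classes, predicted = classes))
  m
}

#' Leave-one-subject-out evaluation of a classifier
#'
#' For every fold: the classifier is trained on all other subjects
#' (supervised first level; Baum-Welch second level for `"chmm2"`, run on
#' the training sequences with their known-garbage frames removed), the
#' rejection threshold — when `reject = TRUE` — is selected on the ROC
#' curve of the training frames only, and the held-out subject's sequences
#' are decoded. No information from the test subject enters training.
#'
#' Accuracy accounting: without rejection the denominator is all test
#' frames and a garbage frame is always an error (it has no correct
#' label). With rejection, rejected frames are excluded from the
#' denominator and a retained garbage frame is an error;
#' `strictAccuracy = TRUE` instead keeps all frames in the denominator so
#' that rejected genuine frames count as errors.
#'
#' @param data list of [LabeledSequence-class] objects spanning >= 2
#'   subjects.
#' @param classifier `"gmm"` (single-frame), `"chmm1"` (supervised HMM) or
#'   `"chmm2"` (supervised HMM + Baum-Welch refinement).
#' @param M mixture components per class/state.
#' @param reject apply the spurious-frame detector?
#' @param seed integer seed for emission fitting.
#' @param reg covariance eigenvalue floor.
#' @param strictAccuracy see above.
#' @param level2MaxIter Baum-Welch iteration cap for `"chmm2"`.
#' @return A [CVReport-class] object.
#' @export
evaluateClassifier <- function(data, classifier = c("chmm2", "chmm1", "gmm"),
                               M = 1, reject = FALSE, seed = NULL,
                               reg = 1e-6, strictAccuracy = FALSE,
                               level2MaxIter = 10) {
  classifier <- match.arg(classifier)
  folds <- losoSplit(data)
  classes <- sort(unique(unlist(lapply(data, function(s)
    setdiff(s@y, c("garbage", "transition", NA))))))
  conf <- matrix(0L, length(classes), length(classes),
    dimnames = list(true = classes, predicted = classes))
  accs <- numeric(length(folds))
  names(accs) <- vapply(folds, `[[`, character(1), "subject")
  rejPred <- logical(0); rejTrue <- logical(0)
  for (fi in seq_along(folds)) {
    fold <- folds[[fi]]
    train <- data[fold$trainIdx]
    test <- data[fold$testIdx]
    model <- switch(classifier,
      gmm = {
        Xtr <- do.call(rbind, lapply(train, featureMatrix))
        ytr <- unlist(lapply(train, frameLabels))
        fitGmmClassifier(Xtr, ytr, M = M, seed = seed, reg = reg,
          classes = classes)
      },
      chmm1 = trainLevel1(train, M = M, seed = seed, reg = reg,
        stateNames = classes),
      chmm2 = {
        m1 <- trainLevel1(train, M = M, seed = seed, reg = reg,
          stateNames = classes)
        clean <- lapply(train, function(s) {
          keep <- !is.na(s@y) & !(s@y %in% c("transition", "garbage"))
          s@X[keep, , drop = FALSE]
        })
        trainLevel2(m1, clean, update = "transitions",
          maxIter = level2MaxIter, reg = reg)
      })
    threshold <- -Inf
    if (reject) {
      Xtr <- do.call(rbind, lapply(train, featureMatrix))
      sptr <- unlist(lapply(train, spuriousFlags))
      ldTr <- classLogDensities(model, Xtr)
      threshold <- selectThreshold(rocCurve(ldTr, sptr))
    }
    nCorrect <- 0; nDenom <- 0
    for (s in test) {
      ld <- classLogDensities(model, s@X)
      mask <- if (reject) rejectionMask(ld, threshold)
        else rep(FALSE, nrow(s@X))
      if (all(mask)) mask[which.max(rejectionStatistic(ld))] <- FALSE
      pred <- if (classifier == "gmm")
        classes[max.col(ld, ties.method = "first")]
      else viterbiDecode(model, s@X, mask = mask)
      sp <- spuriousFlags(s)
      genuine <- !sp & s@y %in% classes
      correct <- genuine & pred == s@y & !mask
      if (reject && !strictAccuracy) {
        nDenom <- nDenom + sum(!mask)
      } else {
        nDenom <- nDenom + length(mask)
      }
      nCorrect <- nCorrect + sum(correct)
      keep <- genuine & !mask
      if (any(keep))
        conf <- conf + confusionCounts(s@y[keep], pred[keep], classes)
      if (reject) {
        rejPred <- c(rejPred, mask)
        rejTrue <- c(rejTrue, sp)
      }
    }
    accs[fi] <- nCorrect / nDenom
  }
  rejPerf <- if (reject && any(rejTrue) && !all(rejTrue))
    rejectionPerformance(rejPred, rejTrue) else numeric(0)
  new("CVReport", classifier = classifier, perSubjectAccuracy = accs,
    confusion = conf, rejection = rejPerf,
    settings = list(M = M, reject = reject, seed = seed,
      strictAccuracy = strictAccuracy))
}

#' Simulate a multi-subject virtual-experiment study
#'
#' Generates, for each subject, per-activity frame pools (with a small
#' subject-specific perturbation of the DC baselines, emulating
#' between-subject variability) and a set of virtual experiments driven by
#' the given Markov model, contaminated with garbage frames. Features are
#' extracted once per pool frame and reused across draws.
#'
#' @param nSubjects number of subjects.
#' @param experimentsPerSubject virtual experiments per subject.
#' @param len genuine frames per experiment (T).
#' @param omm a [MarkovModel-class]; default the seven-activity chain.
#' @param specs named list of emission specs including a `"garbage"`
#'   entry; default [defaultActivitySpecs()].
#' @param garbageRatio garbage-to-genuine ratio (default 1:3).
#' @param poolSize frames per activity pool (the classic setting draws
#'   pools of 18 to 58 frames; a scalar fixes the size).
#' @param width frame width in samples.
#' @param samplingRate sampling rate in Hz.
#' @param subjectDcSd standard deviation of the per-subject DC
#'   perturbation (g).
#' @param seed integer seed.
#' @return List of [LabeledSequence-class] objects (one per experiment),
#'   suitable for [evaluateClassifier()].
#' @export
simulateVirtualStudy <- function(nSubjects = 3, experimentsPerSubject = 2,
                                 len = 300, omm = sevenActivityTpm(),
                                 specs = defaultActivitySpecs(),
                                 garbageRatio = 1 / 3,
                                 poolSize = c(18, 58), width = 512,
                                 samplingRate = 76.25,
                                 subjectDcSd = 0.005, seed = NULL) {
  states <- stateNames(omm)
  if (!all(states %in% names(specs)))
    stop("specs must cover every state of the chain")
  withLocalSeed(seed, function() {
    out <- list()
    for (subj in seq_len(nSubjects)) {
      sid <- sprintf("subject%02d", subj)
      poolFeat <- list()
      for (nm in c(states, "garbage")) {
        sp <- specs[[nm]]
        if (is.null(sp)) next
        pert <- activitySpec(sp@name,
          dc = sp@dc + stats::rnorm(length(sp@dc), sd = subjectDcSd),
          harmonics = sp@harmonics, noiseSd = sp@noiseSd,
          crossChannelCorr = sp@crossChannelCorr)
        N <- if (length(poolSize) == 2)
          sample(seq(poolSize[1], poolSize[2]), 1) else poolSize
        pool <- generateFramePool(pert, N = N, width = width,
          samplingRate = samplingRate, subjectId = sid)
        poolFeat[[nm]] <- do.call(rbind, lapply(pool@frames, frameFeatures))
      }
      for (e in seq_len(experimentsPerSubject)) {
        path <- sampleChain(omm, len)
        nG <- if (garbageRatio > 0) as.integer(round(len * garbageRatio))
          else 0L
        total <- len + nG
        flags <- rep(FALSE, total)
        if (nG > 0) flags[sample.int(total, nG)] <- TRUE
        X <- matrix(0, total, ncol(poolFeat[[states[1]]]))
        colnames(X) <- colnames(poolFeat[[states[1]]])
        labs <- character(total)
        gi <- 1L
        for (t in seq_len(total)) {
          if (flags[t]) {
            X[t, ] <- poolFeat[["garbage"]][
              sample.int(nrow(poolFeat[["garbage"]]), 1), ]
            labs[t] <- "garbage"
          } else {
            st <- path[gi]; gi <- gi + 1L
            X[t, ] <- poolFeat[[st]][sample.int(nrow(poolFeat[[st]]), 1), ]
            labs[t] <- st
          }
        }
        out[[length(out) + 1L]] <- new("LabeledSequence", X = X, y = labs,
          spurious = flags, subjectId = sid)
      }
    }
    out
  })
}
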