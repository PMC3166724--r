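# Synthetic data generation. Real per-activity accelerometer morphology is
# not available, so each activity is emulated by a declared parametric
# stand-in: a per-channel gravity baseline, rhythmic harmonics with random
# phase, and correlated Gaussian noise. Virtual experiments then chain
# activities with a first-order Markov model and intersperse garbage
# frames, mimicking sequence-level validation without real recordings.

#' Construct an activity emission specification
#'
#' @param name activity name.
#' @param dc per-channel DC baseline in g (gravity projection).
#' @param harmonics list with one entry per channel; each entry a matrix or
#'   data frame with columns `freq` (Hz) and `amp` (g), possibly empty, or
#'   `NULL` for no harmonic content.
#' @param noiseSd standard deviation of the additive Gaussian noise (g).
#' @param crossChannelCorr equicorrelation of the noise across channels.
#' @return An [ActivityEmissionSpec-class] object.
#' @export
activitySpec <- function(name, dc, harmonics = NULL, noiseSd = 0.05,
                         crossChannelCorr = 0.2) {
  ch <- length(dc)
  if (is.null(harmonics)) harmonics <- vector("list", ch)
  harmonics <- lapply(harmonics, function(h) {
    if (is.null(h) || NROW(h) == 0)
      return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("freq", "amp"))))
    h <- as.matrix(as.data.frame(h))
    colnames(h) <- c("freq", "amp")
    h
  })
  new("ActivityEmissionSpec", name = name, dc = dc, harmonics = harmonics,
    noiseSd = noiseSd, crossChannelCorr = crossChannelCorr)
}

#' Default emission specifications for the seven-activity vocabulary
#'
#' Three-channel stand-ins for lying (S1), cycling (S2), climbing stairs
#' (S3), walking (S4), running (S5), sitting (S6) and standing (S7).
#' Static postures differ in gravity projection only; dynamic activities
#' add gait/pedaling harmonics. Climbing stairs and walking are given
#' deliberately close baselines and harmonics so that they remain the
#' dominant confusion pair, and the garbage ("unknown") activity has its
#' own distinct morphology rather than pure noise.
#'
#' @return Named list of [ActivityEmissionSpec-class] objects, states
#'   `S1..S7` plus `"garbage"`.
#' @export
defaultActivitySpecs <- function() {
  h <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    colnames(m) <- c("freq", "amp")
    m
  }
  list(
    S1 = activitySpec("lying", dc = c(0.02, 0.05, 0.98),
      noiseSd = 0.04),
    S2 = activitySpec("cycling", dc = c(0.10, 0.35, 0.90),
      harmonics = list(h(1.2, 0.25), h(1.2, 0.18), NULL), noiseSd = 0.05),
    S3 = activitySpec("climbing stairs", dc = c(0.40, 0.60, 0.61),
      harmonics = list(h(1.8, 0.32, 3.6, 0.12), h(1.8, 0.22), NULL),
      noiseSd = 0.09),
    S4 = activitySpec("walking", dc = c(0.40, 0.60, 0.63),
      harmonics = list(h(2.0, 0.30, 4.0, 0.10), h(2.0, 0.20), NULL),
      noiseSd = 0.09),
    S5 = activitySpec("running", dc = c(0.50, 0.70, 0.45),
      harmonics = list(h(2.8, 0.80, 5.6, 0.30), h(2.8, 0.50), NULL),
      noiseSd = 0.15),
    S6 = activitySpec("sitting", dc = c(0.30, 0.80, 0.50),
      noiseSd = 0.04),
    S7 = activitySpec("standing", dc = c(0.02, 0.99, 0.10),
      noiseSd = 0.05),
    garbage = activitySpec("unknown", dc = c(0.20, 0.40, 0.80),
      harmonics = list(h(0.7, 0.50, 5.0, 0.20), h(0.7, 0.35), NULL),
      noiseSd = 0.12)
  )
}

#' Generate a pool of raw frames for one activity
#'
#' Each frame is `dc + harmonics with independently random phase +
#' correlated Gaussian noise`, emulating the N frames available for one
#' subject and one activity from which virtual experiments draw with
#' replacement.
#'
#' @param spec an [ActivityEmissionSpec-class] object.
#' @param N pool size (frames).
#' @param width frame width in samples.
#' @param samplingRate sampling rate in Hz.
#' @param seed optional integer seed.
#' @param subjectId subject identifier.
#' @return A [FramePool-class] object.
#' @export
generateFramePool <- function(spec, N, width, samplingRate, seed = NULL,
                              subjectId = "s1") {
  stopifnot(N >= 1, width >= 1)
  ch <- length(spec@dc)
  for (h in spec@harmonics)
    if (NROW(h) && any(h[, "freq"] >= samplingRate / 2))
      stop("harmonic frequency at or above Nyquist (",
        samplingRate / 2, " Hz)")
  tt <- (seq_len(width) - 1) / samplingRate
  rho <- spec@crossChannelCorr
  withLocalSeed(seed, function() {
    frms <- lapply(seq_len(N), function(i) {
      f <- matrix(0, width, ch)
      for (c_ in seq_len(ch)) {
        x <- rep(spec@dc[c_], width)
        hh <- spec@harmonics[[c_]]
        if (NROW(hh)) for (r in seq_len(nrow(hh)))
          x <- x + hh[r, "amp"] *
            sin(2 * pi * hh[r, "freq"] * tt + stats::runif(1, 0, 2 * pi))
        f[, c_] <- x
      }
      if (spec@noiseSd > 0) {
        common <- stats::rnorm(width)
        noise <- sapply(seq_len(ch), function(c_)
          sqrt(max(rho, 0)) * common +
            sqrt(1 - max(rho, 0)) * stats::rnorm(width))
        f <- f + spec@noiseSd * noise
      }
      f
    })
    new("FramePool", activity = spec@name, frames = frms,
      subjectId = as.character(subjectId), samplingRate = samplingRate)
  })
}

#' Simulate one virtual experiment
#'
#' Samples a state path of length `len` from the observable Markov model;
#' every visited state emits a frame drawn with replacement from its pool.
#' Garbage frames from `garbagePool` are then interspersed at uniformly
#' random positions, `garbageRatio` garbage frames per genuine frame
#' (the default 1/3 gives the 1:3 proportion, i.e. 100 garbage frames for
#' a 300-frame path; use 0.5 for the "one-third of the total" reading).
#'
#' @param omm a [MarkovModel-class] driving the activity sequence.
#' @param pools named list of [FramePool-class] objects, one per state.
#' @param len number of genuine frames T (default 300).
#' @param garbagePool optional [FramePool-class] of out-of-vocabulary
#'   frames.
#' @param garbageRatio garbage-to-genuine frame ratio (0 disables).
#' @param seed optional integer seed.
#' @return A [FrameSet-class] whose `frameLabels` are the emitting states
#'   (`"garbage"` for interspersed frames) and whose `spurious` slot flags
#'   the garbage frames.
#' @export
virtualExperiment <- function(omm, pools, len = 300, garbagePool = NULL,
                              garbageRatio = 1 / 3, seed = NULL) {
  missing <- setdiff(stateNames(omm), names(pools))
  if (length(missing))
    stop("no frame pool for state(s): ", paste(missing, collapse = ", "))
  withLocalSeed(seed, function() {
    path <- sampleChain(omm, len)
    genuine <- lapply(path, function(s) {
      p <- pools[[s]]
      p@frames[[sample.int(length(p@frames), 1)]]
    })
    nG <- if (is.null(garbagePool) || garbageRatio <= 0) 0L
      else as.integer(round(len * garbageRatio))
    total <- len + nG
    flags <- rep(FALSE, total)
    if (nG > 0) flags[sample.int(total, nG)] <- TRUE
    frms <- vector("list", total)
    labs <- character(total)
    frms[!flags] <- genuine
    labs[!flags] <- path
    if (nG > 0) {
      gidx <- sample.int(length(garbagePool@frames), nG, replace = TRUE)
      frms[flags] <- garbagePool@frames[gidx]
      labs[flags] <- "garbage"
    }
    width <- nrow(frms[[1]])
    anyPool <- pools[[stateNames(omm)[1]]]
    new("FrameSet", frames = frms, width = as.integer(width),
      step = as.integer(width), samplingRate = anyPool@samplingRate,
      frameLabels = labs, spurious = flags)
  })
}

#' Turn a labeled frame set into a feature-level labeled sequence
#'
#' @param frameSet a [FrameSet-class] with frame labels (e.g. from
#'   [virtualExperiment()] or [segmentFrames()] on annotated data).
#' @param subjectId subject identifier.
#' @param families feature families passed to [extractFeatures()].
#' @return A [LabeledSequence-class].
#' @export
asLabeledSequence <- function(frameSet, subjectId = "s1",
                              families = c("dc", "energy", "entropy",
                                "correlation")) {
  labs <- frameLabels(frameSet)
  if (is.null(labs)) stop("frameSet carries no frame labels")
  sp <- spuriousFlags(frameSet)
  if (is.null(sp)) sp <- labs == "garbage"
  new("LabeledSequence", X = extractFeatures(frameSet, families = families),
    y = labs, spurious = sp, subjectId = as.character(subjectId))
}

#' Generate a synthetic sit-stand-walk recording
#'
#' A continuous three-channel recording emulating a subject who sits,
#' stands up, pauses, and starts walking: static gravity projections for
#' sit and stand, a smooth sigmoid reorientation during each postural
#' transition, and gait harmonics during walking. Per-sample annotations
#' mark `sit`, `transition`, `stand`, `transition`, `walk` in order. The
#' defaults give about 15 s at 250 Hz (3750 samples).
#'
#' @param durations sit, stand and walk phase durations in seconds.
#' @param transitionDuration nominal duration of each postural transition
#'   in seconds.
#' @param transitionSd standard deviation of the jitter on the transition
#'   durations in seconds (0 for exactly reproducible phase boundaries).
#' @param samplingRate sampling rate in Hz.
#' @param seed optional integer seed.
#' @param subjectId subject identifier.
#' @param noiseSd sensor noise standard deviation (g).
#' @return An annotated [Recording-class].
#' @export
generateSitStandWalk <- function(durations = c(4.5, 4, 4.5),
                                 transitionDuration = 1,
                                 transitionSd = 0, samplingRate = 250,
                                 seed = NULL, subjectId = "s1",
                                 noiseSd = 0.02) {
  stopifnot(length(durations) == 3, all(durations > 0))
  gSit <- c(0.15, 0.70, 0.65)
  gStand <- c(0.05, 0.99, 0.10)
  withLocalSeed(seed, function() {
    td <- pmax(0.2, stats::rnorm(2, transitionDuration, transitionSd))
    lens <- round(c(durations[1], td[1], durations[2], td[2],
      durations[3]) * samplingRate)
    labels <- c("sit", "transition", "stand", "transition", "walk")
    total <- sum(lens)
    x <- matrix(0, total, 3)
    ann <- rep(labels, lens)
    bounds <- cumsum(c(0, lens))
    for (ph in seq_len(5)) {
      idx <- (bounds[ph] + 1):bounds[ph + 1]
      n <- length(idx)
      tt <- (seq_len(n) - 1) / samplingRate
      seg <- switch(ph,
        matrix(gSit, n, 3, byrow = TRUE),
        {   # sit -> stand reorientation + movement burst
          s <- stats::plogis(seq(-6, 6, length.out = n))
          base <- outer(1 - s, gSit) + outer(s, gStand)
          base + 0.10 * sin(2 * pi * 1.5 * tt) * (s * (1 - s) * 4)
        },
        matrix(gStand, n, 3, byrow = TRUE),
        {   # stand -> incipient walk: posture held, activity ramps up
          s <- stats::plogis(seq(-6, 6, length.out = n))
          base <- matrix(gStand, n, 3, byrow = TRUE)
          base + s * 0.15 * sin(2 * pi * 2 * tt)
        },
        {   # walking: gait harmonics on all channels
          base <- matrix(gStand, n, 3, byrow = TRUE)
          base[, 1] <- base[, 1] + 0.25 * sin(2 * pi * 2 * tt)
          base[, 2] <- base[, 2] + 0.30 * sin(2 * pi * 2 * tt + 1) +
            0.10 * sin(2 * pi * 4 * tt)
          base[, 3] <- base[, 3] + 0.20 * sin(2 * pi * 2 * tt + 2)
          base
        })
      x[idx, ] <- seg
    }
    x <- x + matrix(stats::rnorm(total * 3, sd = noiseSd), total, 3)
    recording(x, samplingRate, annotations = ann, subjectId = subjectId)
  })
}
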