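test_that("frame pools realize the requested DC, harmonics and noise", {
  # static spec: DC feature concentrates at the configured baseline
  static <- activitySpec("posture", dc = c(0.1, 0.9), noiseSd = 0.05)
  pool <- generateFramePool(static, N = 30, width = 256, samplingRate = 50,
    seed = 51)
  dcs <- vapply(pool@frames, function(f) mean(f[, 1]), numeric(1))
  expect_true(all(abs(dcs - 0.1) < 3 * 0.05 / sqrt(256)))
  # walking-like spec: spectral peak at the configured gait frequency
  walk <- activitySpec("walk", dc = 0.5,
    harmonics = list(cbind(freq = 2, amp = 0.5)), noiseSd = 0.01)
  poolW <- generateFramePool(walk, N = 1, width = 200, samplingRate = 50,
    seed = 52)
  mod <- oracleDftMod(poolW@frames[[1]][, 1])[2:100]
  peakHz <- which.max(mod) * 50 / 200
  expect_equal(peakHz, 2, tolerance = 0.26)
  # noiseless static frames are constant with zero spectral energy
  quiet <- activitySpec("still", dc = 0.7, noiseSd = 0)
  poolQ <- generateFramePool(quiet, N = 2, width = 64, samplingRate = 50)
  expect_equal(spectralEnergy(poolQ@frames[[1]][, 1]), 0, tolerance = 1e-18)
  # harmonics above Nyquist are refused
  bad <- activitySpec("bad", dc = 0, harmonics = list(cbind(30, 1)))
  expect_error(generateFramePool(bad, 1, 64, 50), "Nyquist")
  # reproducibility
  p1 <- generateFramePool(static, 5, 64, 50, seed = 53)
  p2 <- generateFramePool(static, 5, 64, 50, seed = 53)
  expect_identical(p1@frames, p2@frames)
})

test_that("virtual experiments intersperse garbage at the 1:3 proportion", {
  omm <- persistentChain(2, 0.9)
  specs <- list(S1 = activitySpec("a", dc = c(0, 0), noiseSd = 0.01),
    S2 = activitySpec("b", dc = c(1, 1), noiseSd = 0.01),
    g = activitySpec("u", dc = c(5, 5), noiseSd = 0.01))
  pools <- list(
    S1 = generateFramePool(specs$S1, 20, 32, 50, seed = 1),
    S2 = generateFramePool(specs$S2, 20, 32, 50, seed = 2))
  gp <- generateFramePool(specs$g, 20, 32, 50, seed = 3)
  ve <- virtualExperiment(omm, pools, len = 300, garbagePool = gp,
    garbageRatio = 1 / 3, seed = 54)
  expect_length(frames(ve), 400)
  expect_equal(sum(spuriousFlags(ve)), 100)
  expect_equal(sum(frameLabels(ve) == "garbage"), 100)
  # garbage off: all labels are states, no flags
  ve0 <- virtualExperiment(omm, pools, len = 50, garbageRatio = 0, seed = 55)
  expect_false(any(spuriousFlags(ve0)))
  expect_true(all(frameLabels(ve0) %in% c("S1", "S2")))
  expect_error(virtualExperiment(omm, pools["S1"], len = 10), "S2")
  # reproducibility
  ve1 <- virtualExperiment(omm, pools, len = 40, garbagePool = gp, seed = 56)
  ve2 <- virtualExperiment(omm, pools, len = 40, garbagePool = gp, seed = 56)
  expect_identical(frameLabels(ve1), frameLabels(ve2))
  expect_identical(frames(ve1), frames(ve2))
})

test_that("virtual-experiment label sequences reproduce the generating TPM", {
  omm <- sevenActivityTpm()
  A0 <- transitionMatrix(omm)
  seqs <- lapply(1:20, function(i) sampleChain(omm, 300, seed = 500 + i))
  A <- estimateTpm(seqs, stateNames = stateNames(omm))
  # exact per-entry check: conditional on the observed number of
  # transitions out of each state, each count is Binomial(n_i, a_ij);
  # assert every count inside its central 99.98% interval (Bonferroni
  # over the 49 entries)
  for (i in 1:7) {
    from <- sprintf("S%d", i)
    ni <- sum(vapply(seqs, function(s)
      sum(s[-length(s)] == from), numeric(1)))
    for (j in 1:7) {
      k <- A[i, j] * ni
      lo <- qbinom(1e-4, ni, A0[i, j])
      hi <- qbinom(1 - 1e-4, ni, A0[i, j])
      expect_gte(k, lo - 0.5)
      expect_lte(k, hi + 0.5)
    }
  }
  # rows with enough traffic meet the 0.05 max-abs recovery bound
  ev <- eigen(t(A0))
  statio <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  statio <- statio / sum(statio)
  busy <- which(statio >= 0.05)
  expect_lt(max(abs(A[busy, ] - A0[busy, ])), 0.05)
  # high-occupancy spot checks stay within 0.05 of the printed values
  expect_lt(abs(A["S2", "S2"] - 0.90), 0.05)
  expect_lt(abs(A["S4", "S4"] - 0.80), 0.05)
})

test_that("the sit-stand-walk recording has the expected shape", {
  rec <- generateSitStandWalk(seed = 57)
  expect_equal(nrow(channels(rec)), 3750)   # 15 s at 250 Hz
  expect_equal(samplingRate(rec), 250)
  expect_identical(rle(annotations(rec))$values,
    c("sit", "transition", "stand", "transition", "walk"))
  # DC of sit frames differs from stand frames by the gravity delta
  fs <- segmentFrames(rec, width = 64, overlap = 0.5)
  X <- extractFeatures(fs, families = "dc")
  labs <- frameLabels(fs)
  delta <- colMeans(X[labs == "sit", ]) - colMeans(X[labs == "stand", ])
  expect_equal(unname(delta), c(0.15, 0.70, 0.65) - c(0.05, 0.99, 0.10),
    tolerance = 0.05)
  expect_identical(channels(generateSitStandWalk(seed = 58)),
    channels(generateSitStandWalk(seed = 58)))
})
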