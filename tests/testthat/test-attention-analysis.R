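# Selection profiles, TSTs, delta contrasts, quartile variability, CSD
# condition comparison.

smoothMat <- function(n, Tn, seed, sd = 1) {
  withr::with_seed(seed,
    smoothBidirectional(matrix(rnorm(n * Tn, sd = sd), n), 15, fsHz = 1000))
}

mkEpochs <- function(mat3d, timeMs) {
  new("EpochTensor", data = mat3d, timeMs = timeMs,
      alignment = "array_onset", trialIndex = seq_len(dim(mat3d)[1L]),
      normalized = TRUE)
}

test_that("identically generated target and distractor trials yield no TST", {
  tm <- seq(-50, 249)
  map <- assignCompartments(6, 8)
  tArr <- array(smoothMat(40 * 8, 300, 51), c(40, 8, 300))
  dArr <- array(smoothMat(40 * 8, 300, 52), c(40, 8, 300))
  tst <- targetSelectionTime(mkEpochs(tArr, tm), mkEpochs(dArr, tm), map)
  expect_true(all(is.na(tst$compartment)))
})

test_that("TST recovers an injected selection step per channel and
           compartment", {
  tm <- seq(-50, 249)
  map <- assignCompartments(6, 8)
  tArr <- array(smoothMat(40 * 8, 300, 53, sd = 0.3), c(40, 8, 300))
  dArr <- array(smoothMat(40 * 8, 300, 54, sd = 0.3), c(40, 8, 300))
  tArr[, , tm >= 90] <- tArr[, , tm >= 90] + 2
  res <- targetSelectionTime(mkEpochs(tArr, tm), mkEpochs(dArr, tm), map,
                             level = c("compartment", "channel"))
  expect_true(all(abs(res$compartment - 90) <= 17))
  expect_true(all(abs(res$channel - 90) <= 17))
})

test_that("increasing the selection gain never delays the recovered TST", {
  tstFor <- function(gain, seed) {
    cfg <- deskCfg(seed, nBlocks = 16L, adaptationFactor = 1,
                   selectionGain = gain)
    sim <- simulateSession(cfg)
    pp <- leanPreprocess(sim)
    tt <- pp$trials
    rT <- which(tt$correct & tt$context == "predictable" &
                  tt$rf_stimulus == "target_in_rf")
    rD <- which(tt$correct & tt$context == "predictable" &
                  tt$rf_stimulus == "distractor_in_rf")
    targetSelectionTime(laminarpop:::subsetEpochs(pp$epochs, rT),
                        laminarpop:::subsetEpochs(pp$epochs, rD),
                        pp$map)$compartment[["middle"]]
  }
  for (seed in c(61, 62)) {
    lo <- tstFor(0.35, seed)
    hi <- tstFor(0.7, seed)    # same seed, stronger selection
    expect_lte(ifelse(is.na(hi), Inf, hi), ifelse(is.na(lo), Inf, lo))
  }
})

test_that("selection profiles subtract distractor from target responses", {
  tm <- seq(-50, 149)
  map <- assignCompartments(6, 8)
  base <- array(smoothMat(20 * 8, 200, 55), c(20, 8, 200))
  p <- selectionProfile(mkEpochs(base, tm), mkEpochs(base, tm), map)
  expect_equal(max(abs(p$all)), 0)
  expect_equal(max(abs(p$middle)), 0)
  shifted <- base + 1.5                       # constant target offset
  p2 <- selectionProfile(mkEpochs(shifted, tm), mkEpochs(base, tm), map)
  expect_equal(mean(p2$all), 1.5, tolerance = 1e-10)
  expect_equal(mean(p2$deep), 1.5, tolerance = 1e-10)
})

test_that("delta contrasts find nothing when contexts are identical", {
  tm <- seq(-300, 249)
  tp <- smoothMat(8, 550, 70); tu <- smoothMat(8, 550, 71)
  dp <- smoothMat(8, 550, 72); du <- smoothMat(8, 550, 73)
  d <- deltaTeDs(tp, tu, dp, du, tm)
  expect_equal(nrow(d$te$test@clusters), 0)
  expect_equal(nrow(d$ds$test@clusters), 0)
  expect_true(is.na(d$te$onsetMs))
})

test_that("attenuated predictable distractor processing appears as a
           negative delta-DS with an early onset and no delta-TE", {
  # isolate the distractor pathway: equal selection onsets across contexts
  # and a flat 0.9 gain on repeated distractors
  dAll <- NULL; tAll <- NULL; dUn <- NULL; tUn <- NULL
  for (sd in 81:88) {
    cfg <- deskCfg(sd, nBlocks = 12L, adaptationFactor = 0.9,
                   selectionOnsetMs = c(unpredictable = 84, predictable = 84))
    sim <- simulateSession(cfg)
    pp <- leanPreprocess(sim)
    tt <- pp$trials
    wave <- function(ctx, stim) {
      rows <- which(tt$correct & tt$context == ctx & tt$rf_stimulus == stim)
      colMeans(laminarpop:::compartmentTrialMatrix(
        laminarpop:::subsetEpochs(pp$epochs, rows), pp$map, "all"))
    }
    tAll <- rbind(tAll, wave("predictable", "target_in_rf"))
    tUn <- rbind(tUn, wave("unpredictable", "target_in_rf"))
    dAll <- rbind(dAll, wave("predictable", "distractor_in_rf"))
    dUn <- rbind(dUn, wave("unpredictable", "distractor_in_rf"))
  }
  tm <- seq(-260, 250)
  d <- deltaTeDs(tAll, tUn, dAll, dUn, tm)
  expect_false(is.na(d$ds$onsetMs))
  expect_lte(d$ds$onsetMs, 110)               # early response window
  ds <- d$ds$test@clusters
  expect_true(all(ds$sign[ds$start_ms < 150] == -1))   # suppression
  expect_equal(nrow(d$te$test@clusters), 0)   # target pathway untouched
})

test_that("delta-TE and delta-DS from disjoint trial sets are independent
           under the null", {
  tm <- seq(-300, 149)
  occ <- withr::with_seed(314, t(replicate(200, {
    d <- deltaTeDs(smoothBidirectional(matrix(rnorm(8 * 450, sd = 0.25), 8),
                                       15, fsHz = 1000) + rnorm(8, sd = 0.1),
                   matrix(0, 8, 450),
                   smoothBidirectional(matrix(rnorm(8 * 450, sd = 0.25), 8),
                                       15, fsHz = 1000) + rnorm(8, sd = 0.1),
                   matrix(0, 8, 450), tm, alpha = 0.3, minClusterMs = 10)
    c(te = nrow(d$te$test@clusters) > 0, ds = nrow(d$ds$test@clusters) > 0)
  })))
  pTe <- mean(occ[, "te"]); pDs <- mean(occ[, "ds"])
  pBoth <- mean(occ[, "te"] & occ[, "ds"])
  se <- sqrt(pTe * pDs * (1 - pTe * pDs) / 200)
  expect_lte(abs(pBoth - pTe * pDs), 3 * se + 0.02)
})

test_that("between-quartile variability matches its closed forms", {
  tm <- seq(-300, 199)
  w <- matrix(1, 4, 500)
  v <- quartileVariability(w, tm)
  expect_equal(max(v$variance), 0)
  offs <- matrix(rep(c(0, 1, 2, 3), 500), 4)
  v2 <- quartileVariability(offs, tm)
  expect_equal(unique(round(v2$variance, 12)), 5 / 3)
  expect_equal(v2$baselineMean, 5 / 3)
  # two-pass oracle on random waveforms
  rw <- matrix(rnorm(2000), 4)
  v3 <- quartileVariability(rw, tm)
  oracle <- vapply(seq_len(500), function(t) {
    m <- mean(rw[, t]); sum((rw[, t] - m)^2) / 3
  }, numeric(1))
  expect_equal(v3$variance, oracle, tolerance = 1e-12)
  expect_error(quartileVariability(matrix(1, 3, 10), 1:10), "exactly 4")
})

test_that("CSD condition comparison averages within compartments", {
  tm <- seq(-50, 49)
  map <- assignCompartments(16, 32)
  # interior-channel CSD epochs constant within compartments
  vals <- c(upper = -2, middle = 5, deep = 1)
  arr <- array(0, c(6, 30, 100))
  for (cp in names(vals)) {
    rows <- compartmentChannels(map, cp) - 1L   # probe -> interior row
    arr[, rows, ] <- vals[[cp]]
  }
  ep <- mkEpochs(arr, tm)
  cc <- csdConditionComparison(list(a = ep, b = ep), map)
  expect_equal(cc$traces$a[, 1], c(upper = -2, middle = 5, deep = 1))
  expect_equal(max(abs(cc$traces$a - cc$traces$b)), 0)
  # attenuating the upper-compartment sink in condition b flips the sign
  # of the difference trace there only
  arr2 <- arr
  rows <- compartmentChannels(map, "upper") - 1L
  arr2[, rows, ] <- arr2[, rows, ] * 0.5        # shallower sink (-1 vs -2)
  cc2 <- csdConditionComparison(list(a = ep, b = mkEpochs(arr2, tm)), map)
  diffTrace <- cc2$traces$b - cc2$traces$a
  expect_true(all(diffTrace["upper", ] > 0))    # less negative = attenuated
  expect_equal(max(abs(diffTrace[c("middle", "deep"), ])), 0)
})
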