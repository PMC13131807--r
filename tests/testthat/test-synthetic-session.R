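# Synthetic session generator: determinism, behavioral statistics,
# injected neural structure, ground-truth ledger.

test_that("identical configurations produce bit-identical sessions", {
  cfg <- deskCfg(7, nBlocks = 3L, nChannels = 8L, sinkChannel = 6L)
  a <- simulateSession(cfg)
  b <- simulateSession(cfg)
  expect_identical(samples(a$session@signals$envelope),
                   samples(b$session@signals$envelope))
  expect_identical(samples(a$session@signals$lfp),
                   samples(b$session@signals$lfp))
  expect_identical(a$session@trials, b$session@trials)
  expect_identical(a$truth, b$truth)
  # the caller's RNG stream is untouched
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(simulateSession(cfg)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("invalid configurations are rejected", {
  expect_error(simConfig(adaptationFactor = 0), "adaptationFactor")
  expect_error(simConfig(accuracyPlateau = 1.2), "probabilities")
  expect_error(simConfig(selectionOnsetMs = c(unpredictable = 80,
                                              predictable = 120)),
               "selection onset")
  expect_error(simConfig(nPositions = 1L), "nPositions")
  expect_error(simConfig(rfPosition = 6L), "rfPosition")
  expect_warning(simulateSession(deskCfg(1, nBlocks = 2L, blockLength = 10L,
                                         nChannels = 8L, sinkChannel = 6L)),
                 "blockLength")
})

test_that("target placement is uniform: target-in-RF fraction is 1/6", {
  # trial-level statistics only; tiny probe and packed timing for speed
  cfg <- simConfig(seed = 31, nChannels = 8L, sinkChannel = 6L,
                   nBlocks = 500L, blockLength = 20L,
                   itiRangeMs = c(40, 60))
  sim <- simulateSession(cfg)
  n <- nrow(sim$truth)
  expect_equal(n, 10000L)
  frac <- mean(sim$truth$rf_stimulus == "target_in_rf")
  p <- 1 / 6
  expect_lte(abs(frac - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("the RT context shift is recovered from medians", {
  # blocks of 4 balance the two contexts at 5000 trials each
  cfg <- simConfig(seed = 32, nChannels = 8L, sinkChannel = 6L,
                   nBlocks = 2500L, blockLength = 4L,
                   itiRangeMs = c(40, 60))
  sim <- suppressWarnings(simulateSession(cfg))
  tr <- sim$truth
  dm <- stats::median(tr$rt_ms[tr$context == "predictable"]) -
    stats::median(tr$rt_ms[tr$context == "unpredictable"])
  boot <- withr::with_seed(1, replicate(300, {
    i <- sample(nrow(tr), replace = TRUE)
    stats::median(tr$rt_ms[i][tr$context[i] == "predictable"]) -
      stats::median(tr$rt_ms[i][tr$context[i] == "unpredictable"])
  }))
  expect_lte(abs(dm - (-15)), 3 * stats::sd(boot) + 1)
})

test_that("accuracy follows the saturating curve and plateaus", {
  cfg <- simConfig(seed = 33, nChannels = 8L, sinkChannel = 6L,
                   nBlocks = 400L, blockLength = 20L, itiRangeMs = c(40, 60))
  sim <- simulateSession(cfg)
  tr <- sim$truth
  accObs <- tapply(tr$correct, tr$trial_in_block, mean)[1:15]
  accExp <- expectedAccuracy(cfg, 1:15)
  se <- sqrt(accExp * (1 - accExp) / 400)
  expect_true(all(abs(accObs - accExp) <= 4 * se))
  # non-decreasing in expectation, approaching the plateau
  expect_true(all(diff(accExp) >= 0))
  expect_lte(abs(accExp[15] - cfg@accuracyPlateau), 0.001)
})

test_that("adaptation exponents equal an independent scan of the table", {
  sim <- simulateSession(deskCfg(34, nBlocks = 10L, nChannels = 8L,
                                 sinkChannel = 6L, itiRangeMs = c(40, 60)))
  tr <- sim$truth
  expo <- integer(nrow(tr))
  streak <- 0L
  for (i in seq_len(nrow(tr))) {
    if (i > 1L && tr$block[i] != tr$block[i - 1L]) streak <- 0L
    if (tr$rf_stimulus[i] == "distractor_in_rf") {
      expo[i] <- streak; streak <- streak + 1L
    } else streak <- 0L
  }
  expect_equal(tr$adapt_exponent, expo)
  expect_equal(tr$adapt_multiplier,
               ifelse(tr$rf_stimulus == "distractor_in_rf", 0.97^expo, 1))
  # summed exponents equal the independent count of consecutive repeats
  expect_equal(sum(tr$adapt_exponent), sum(expo))
})

test_that("the ground-truth report has one documented row per trial", {
  sim <- simulateSession(deskCfg(35, nBlocks = 2L, nChannels = 8L,
                                 sinkChannel = 6L, itiRangeMs = c(40, 60)))
  rep <- truthReport(sim$truth)
  expect_equal(nrow(rep), nrow(sim$session@trials))
  expect_equal(names(rep)[1:4],
               c("trial", "block", "trial_in_block", "context"))
  empty <- truthReport(sim$truth[0, ])
  expect_equal(nrow(empty), 0)
  expect_true(all(c("adapt_exponent", "rt_ms") %in% names(empty)))
  expect_error(truthReport(data.frame(trial = 1)), "missing")
})

test_that("trial timing keeps rt_ms consistent with the event samples", {
  sim <- simulateSession(deskCfg(36, nBlocks = 3L, nChannels = 8L,
                                 sinkChannel = 6L))
  tt <- sim$session@trials
  fs <- sim$session@signals$envelope@fsHz
  expect_equal(tt$rt_ms,
               (tt$saccade_onset_sample - tt$array_onset_sample) * 1000 / fs)
  expect_true(all(tt$rt_ms >= 150))
})

test_that("configured evoked latency and selection gain are realized", {
  cfg <- deskCfg(37, nBlocks = 20L, adaptationFactor = 1)
  sim <- simulateSession(cfg)
  pp <- leanPreprocess(sim)
  tt <- pp$trials
  # evoked latency: the mean middle-compartment distractor response leaves
  # its baseline near the configured 50 ms
  rows <- which(tt$rf_stimulus == "distractor_in_rf" & tt$correct)
  m <- colMeans(laminarpop:::compartmentTrialMatrix(
    laminarpop:::subsetEpochs(pp$epochs, rows), pp$map, "middle"))
  tm <- timeMs(pp$epochs)
  base <- m[tm < 0]
  onset <- tm[tm > 20][which(m[tm > 20] > mean(base) + 6 * sd(base))[1]]
  expect_lte(abs(onset - cfg@evokedLatencyMs[["middle"]]), 15)
  # selection gain: target/distractor response ratio after the selection
  # onset in the predictable context approaches 1 + selectionGain
  rowsT <- which(tt$rf_stimulus == "target_in_rf" & tt$context == "predictable")
  mt <- colMeans(laminarpop:::compartmentTrialMatrix(
    laminarpop:::subsetEpochs(pp$epochs, rowsT), pp$map, "middle"))
  rowsD <- which(tt$rf_stimulus == "distractor_in_rf" &
                   tt$context == "predictable")
  md <- colMeans(laminarpop:::compartmentTrialMatrix(
    laminarpop:::subsetEpochs(pp$epochs, rowsD), pp$map, "middle"))
  win <- tm >= 120 & tm <= 200
  expect_lte(abs(mean(mt[win]) / mean(md[win]) - (1 + cfg@selectionGain)),
             0.15)
})

test_that("realized adaptation attenuation matches the configured factor", {
  cfg <- deskCfg(38, nBlocks = 30L, adaptationFactor = 0.9,
                 nChannels = 8L, sinkChannel = 6L, itiRangeMs = c(450, 550))
  sim <- simulateSession(cfg)
  pp <- leanPreprocess(sim, windowMs = c(-255, 120))
  tt <- pp$trials
  tm <- timeMs(pp$epochs)
  win <- tm >= 55 & tm <= 90
  mid <- laminarpop:::compartmentTrialMatrix(pp$epochs, pp$map, "middle")
  resp <- rowMeans(mid[, win])
  ex <- sim$truth$adapt_exponent[pp$epochs@trialIndex]
  rf <- sim$truth$rf_stimulus[pp$epochs@trialIndex]
  r0 <- mean(resp[rf == "distractor_in_rf" & ex == 0])
  r2 <- mean(resp[rf == "distractor_in_rf" & ex == 2])
  expect_lte(abs(r2 / r0 - 0.9^2), 0.08)
})

test_that("broadband output passed through the MUA chain recovers the
           injected envelope", {
  cfg <- simConfig(seed = 39, mode = "broadband", nChannels = 6L,
                   sinkChannel = 4L, nBlocks = 1L, blockLength = 8L,
                   itiRangeMs = c(500, 700),
                   baselineSd = c(unpredictable = 0, predictable = 0),
                   lfpNoiseSd = 0,
                   compartmentAmp = c(upper = 3, middle = 4, deep = 3,
                                      outside = 1))
  sim <- suppressWarnings(simulateSession(cfg))
  expect_equal(sim$session@signals$broadband@fsHz, 24414)
  env <- extractMuaEnvelope(sim$session@signals$broadband,
                            decimateToHz = NULL)
  inj <- samples(sim$session@signals$envelope)
  for (ch in seq_len(6))
    expect_gt(stats::cor(samples(env)[ch, ], inj[ch, ]), 0.9)
})
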