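# Shared fixtures for the test suite. Desk-scale configurations keep the
# generator's behavioral and neural effect parameters at their defaults
# and only shrink problem sizes (channels, blocks, inter-trial interval)
# for runtime; the inter-trial interval stays >= 450 ms so that the 350 ms
# evoked kernel of one trial can never reach the next trial's baseline.

deskCfg <- function(seed, ...) {
  args <- list(...)
  defaults <- list(seed = seed, nChannels = 20L, sinkChannel = 12L,
                   itiRangeMs = c(500, 700), nBlocks = 8L)
  do.call(simConfig, utils::modifyList(defaults, args))
}

# envelope-mode session preprocessed without the CSD path, using the
# generator's true laminar layout (for tests that target stages after
# alignment)
leanPreprocess <- function(sim, windowMs = c(-260, 250)) {
  tt <- sim$session@trials
  tt$context <- labelContext(tt$trial_in_block)
  tt$rf_stimulus <- labelRfStimulus(tt$target_position, tt$rf_position)
  tt$quartile <- quartileLabels(tt)
  ep <- epochExtract(sim$session@signals$envelope, tt$array_onset_sample,
                     windowMs, trialIndex = seq_len(nrow(tt)))
  ep <- zNormalize(ep, c(-250, 0))
  ep <- smoothBidirectional(ep, 15)
  map <- assignCompartments(sim$truth$sink_bottom_channel[1L],
                            sim$session@nChannels)
  list(trials = tt, epochs = ep, map = map)
}

# independent brute-force oracle for T-D-D-D-D sequence mining: checks
# every 5-trial window against the constraints, then (optionally) applies
# left-to-right non-overlap selection
bruteForceSequences <- function(tt, requireCorrect = TRUE,
                                allowOverlap = FALSE) {
  rf <- labelRfStimulus(tt$target_position, tt$rf_position)
  ctx <- labelContext(tt$trial_in_block)
  n <- nrow(tt)
  starts <- integer(0)
  for (i in seq_len(max(0L, n - 4L))) {
    w <- i:(i + 4L)
    if (rf[i] != "target_in_rf") next
    if (ctx[i] != "predictable") next
    if (!all(rf[w[-1L]] == "distractor_in_rf")) next
    if (length(unique(tt$block[w])) != 1L) next
    if (requireCorrect && !all(tt$correct[w])) next
    starts <- c(starts, i)
  }
  if (!allowOverlap && length(starts) > 1L) {
    keep <- starts[1L]
    for (s in starts[-1L]) if (s > keep[length(keep)] + 4L) keep <- c(keep, s)
    starts <- keep
  }
  starts
}

# random trial table for sequence-mining equivalence checks
randomTrialTable <- function(seed, nTrials = 60L) {
  withr::with_seed(seed, {
    blockLen <- sample(6:20, 1L)
    nb <- ceiling(nTrials / blockLen)
    tt <- data.frame(
      session_id = "t",
      target_feature = rep(rep(c("red", "green"), length.out = nb),
                           each = blockLen)[1:nTrials],
      target_position = sample(0:5, nTrials, replace = TRUE),
      rf_position = 0L,
      correct = stats::runif(nTrials) < 0.8)
    parseBlocks(tt)
  })
}
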