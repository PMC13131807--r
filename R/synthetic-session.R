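# Synthetic laminar pop-out sessions with a ground-truth ledger. The
# generator injects exactly the statistical structure the downstream
# analyses assume - block structure with feature swaps, context-dependent
# selection onsets, RT coupled to feedforward amplitude, multiplicative
# distractor adaptation, and a granular LFP dipole - so every stage of the
# pipeline can be validated against known parameters.

#' Synthetic session configuration
#'
#' Builds a [SimConfig-class] with the generator's default study
#' conditions: a 32-channel probe at 0.1 mm spacing, six array positions,
#' 20-trial feature blocks, a 259 ms baseline RT that shortens by 15 ms in
#' the predictable context, selection onsets of 134 ms (unpredictable) and
#' 84 ms (predictable), a 0.97 multiplicative attenuation per consecutive
#' distractor repetition, and ongoing noise that is lower in the
#' predictable context.
#'
#' @param seed integer seed for the session's single random stream.
#' @param mode "envelope" (1 kHz MUA envelope + LFP) or "broadband"
#'   (spike-band carrier at 24414 Hz).
#' @param fsHz sampling rate; defaults to 1000 (envelope) or 24414
#'   (broadband).
#' @param nChannels,spacingMm probe geometry.
#' @param nBlocks,blockLength,nPositions,rfPosition task structure
#'   (positions are 0-based).
#' @param rtBaseMs,rtContextShiftMs,rtNoiseSdMs,rtAmplitudeCoupling
#'   reaction-time model: RT = base + shift (predictable) +
#'   coupling x (-z(amplitude)) + Gaussian noise, truncated at 150 ms.
#' @param accuracyStart,accuracyPlateau,accuracyTau saturating accuracy
#'   curve acc(t) = plateau - (plateau - start) exp(-(t - 1)/tau).
#' @param evokedLatencyMs named evoked latencies per compartment (ms).
#' @param selectionOnsetMs named selection onsets per context (ms).
#' @param selectionGain fractional target gain from the selection onset.
#' @param adaptationFactor per-repetition distractor attenuation in (0, 1].
#' @param baselineSd named ongoing-noise SD per context (a.u.).
#' @param ampJitterSd SD of the shared trial-to-trial amplitude jitter.
#' @param compartmentAmp named evoked amplitudes per compartment.
#' @param sustainedGain sustained plateau as a fraction of the transient.
#' @param sinkChannel center channel of the granular LFP dipole.
#' @param lfpAmp,lfpSinkWidthCh,lfpNoiseSd,lfpLatencyMs LFP dipole model.
#' @param itiRangeMs uniform saccade-to-next-onset interval (ms).
#' @return a validated [SimConfig-class].
#' @export
simConfig <- function(seed = 1L, mode = c("envelope", "broadband"),
                      fsHz = NULL, nChannels = 32L, spacingMm = 0.1,
                      nBlocks = 10L, blockLength = 20L, nPositions = 6L,
                      rfPosition = 0L, rtBaseMs = 259,
                      rtContextShiftMs = -15, rtNoiseSdMs = 30,
                      rtAmplitudeCoupling = 15, accuracyStart = 0.70,
                      accuracyPlateau = 0.92, accuracyTau = 1,
                      evokedLatencyMs = c(upper = 60, middle = 50, deep = 60),
                      selectionOnsetMs = c(unpredictable = 134,
                                           predictable = 84),
                      selectionGain = 0.5, adaptationFactor = 0.97,
                      baselineSd = c(unpredictable = 1.15,
                                     predictable = 1.15),
                      ampJitterSd = 0.15,
                      compartmentAmp = c(upper = 0.8, middle = 1.0,
                                         deep = 0.8, outside = 0.2),
                      sustainedGain = 0.4, sinkChannel = 16L, lfpAmp = 50,
                      lfpSinkWidthCh = 1.5, lfpNoiseSd = 5,
                      lfpLatencyMs = 45, itiRangeMs = c(750, 1250)) {
  mode <- match.arg(mode)
  if (is.null(fsHz)) fsHz <- if (mode == "envelope") 1000 else 24414
  new("SimConfig", seed = as.integer(seed), mode = mode,
      nChannels = as.integer(nChannels), spacingMm = spacingMm, fsHz = fsHz,
      nBlocks = as.integer(nBlocks), blockLength = as.integer(blockLength),
      nPositions = as.integer(nPositions), rfPosition = as.integer(rfPosition),
      rtBaseMs = rtBaseMs, rtContextShiftMs = rtContextShiftMs,
      rtNoiseSdMs = rtNoiseSdMs, rtAmplitudeCoupling = rtAmplitudeCoupling,
      accuracyStart = accuracyStart, accuracyPlateau = accuracyPlateau,
      accuracyTau = accuracyTau, evokedLatencyMs = evokedLatencyMs,
      selectionOnsetMs = selectionOnsetMs, selectionGain = selectionGain,
      adaptationFactor = adaptationFactor, baselineSd = baselineSd,
      ampJitterSd = ampJitterSd, compartmentAmp = compartmentAmp,
      sustainedGain = sustainedGain, sinkChannel = as.integer(sinkChannel),
      lfpAmp = lfpAmp, lfpSinkWidthCh = lfpSinkWidthCh,
      lfpNoiseSd = lfpNoiseSd, lfpLatencyMs = lfpLatencyMs,
      itiRangeMs = itiRangeMs)
}

#' Expected accuracy at a trial position in a block
#'
#' The saturating curve acc(t) = plateau - (plateau - start)
#' exp(-(t - 1)/tau): accuracy rises from `accuracyStart` on trial 1
#' toward `accuracyPlateau` as the target feature repeats.
#'
#' @param cfg a [SimConfig-class].
#' @param trialInBlock trial position(s) since the feature swap (1-based).
#' @return expected probability correct.
#' @export
expectedAccuracy <- function(cfg, trialInBlock) {
  cfg@accuracyPlateau - (cfg@accuracyPlateau - cfg@accuracyStart) *
    exp(-(trialInBlock - 1) / cfg@accuracyTau)
}

#' Chance level of target selection among array positions
#'
#' @param nPositions number of equiprobable array positions (default 6).
#' @return 1/nPositions, the probability of selecting (or containing) the
#'   target by chance.
#' @export
chanceLevel <- function(nPositions = 6L) 1 / nPositions

# evoked-response kernel: gamma-shaped transient (peak 1, ~16 ms after the
# latency) plus a sustained plateau, tapered over the final 50 ms.
evokedKernel <- function(latencyMs, sustainedGain, fsHz, durMs = 350) {
  t <- seq(0, durMs - 1000 / fsHz, by = 1000 / fsHz)
  tt <- t - latencyMs
  k <- numeric(length(t))
  on <- tt > 0
  trans <- (tt[on] / 8)^2 * exp(-tt[on] / 8)
  trans <- trans / ((16 / 8)^2 * exp(-2))   # normalize transient peak to 1
  sust <- sustainedGain * (1 - exp(-tt[on] / 20))
  k[on] <- trans + sust
  taper <- t > durMs - 50
  k[taper] <- k[taper] * 0.5 * (1 + cos(pi * (t[taper] - (durMs - 50)) / 50))
  list(timeMs = t, k = k)
}

# Bottom channel of the sink region the configured LFP dipole injects:
# the contiguous run of interior channels with negative CSD around the
# most negative value. This, not the dipole center, is what the
# functional marker recovers.
dipoleSinkBottom <- function(cfg) {
  ch <- seq_len(cfg@nChannels)
  prof <- -exp(-(ch - cfg@sinkChannel)^2 / (2 * cfg@lfpSinkWidthCh^2))
  n <- cfg@nChannels
  q <- prof[1:(n - 2L)] + prof[3:n] - 2 * prof[2:(n - 1L)]
  csdInterior <- -q                       # sign of -sigma * d2/z^2
  sink <- csdInterior < 0
  runs <- trueRuns(sink)
  minRow <- which.min(csdInterior)
  hit <- which(runs[, 1L] <= minRow & runs[, 2L] >= minRow)
  as.integer(runs[hit, 2L] + 1L)          # interior row -> channel index
}

# consecutive distractor-in-RF repetition count preceding each trial
# (0 for the first distractor after a target or a block boundary; targets
# get 0 and reset the streak)
adaptExponents <- function(block, rfStimulus) {
  n <- length(block)
  expo <- integer(n)
  streak <- 0L
  for (i in seq_len(n)) {
    if (i > 1L && block[i] != block[i - 1L]) streak <- 0L
    if (rfStimulus[i] == "distractor_in_rf") {
      expo[i] <- streak
      streak <- streak + 1L
    } else {
      expo[i] <- 0L
      streak <- 0L
    }
  }
  expo
}

#' Simulate a laminar pop-out session
#'
#' Generates one complete session: the trial table with block structure
#' (target feature swapping at each block boundary, target position uniform
#' over the array positions), reaction times and correctness from the
#' configured behavioral models, continuous signals carrying
#' compartment-specific evoked responses, and a ground-truth ledger of
#' every injected quantity. The evoked response of a target-in-RF trial is
#' scaled by (1 + selectionGain) from the context's selection onset
#' onward; the response of a distractor-in-RF trial is multiplied by
#' adaptationFactor^r after r consecutive distractor repetitions. The LFP
#' carries an evoked dipole centered on `sinkChannel` whose second spatial
#' derivative exhibits a granular sink. In broadband mode the signal is a
#' spike-band noise carrier modulated by the injected envelope, plus the
#' LFP; the injected envelope is returned alongside for validation.
#'
#' Identical configurations (including the seed) produce bit-identical
#' sessions: all draws come from one deterministic stream and the caller's
#' RNG state is left untouched.
#'
#' @param cfg a [SimConfig-class].
#' @return list with elements `session` (a [LaminarSession-class]) and
#'   `truth` (one ground-truth row per trial; see [truthReport()]).
#' @export
simulateSession <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  validObject(cfg)
  if (cfg@blockLength < 15L)
    warning("blockLength < 15: the context labels expect trials 3-15 ",
            "after each feature change")
  withSeed(cfg@seed, function() simulateSessionImpl(cfg))
}

simulateSessionImpl <- function(cfg) {
  fs <- cfg@fsHz
  nTrials <- cfg@nBlocks * cfg@blockLength
  block <- rep(seq_len(cfg@nBlocks), each = cfg@blockLength)
  tib <- rep(seq_len(cfg@blockLength), times = cfg@nBlocks)
  feature <- rep(c("red", "green"), length.out = cfg@nBlocks)[block]
  targetPos <- sample(0:(cfg@nPositions - 1L), nTrials, replace = TRUE)
  rfStim <- labelRfStimulus(targetPos, cfg@rfPosition)
  context3 <- labelContext(tib)
  genContext <- ifelse(tib <= 2L, "unpredictable", "predictable")

  expo <- adaptExponents(block, rfStim)
  adaptMult <- ifelse(rfStim == "distractor_in_rf",
                      cfg@adaptationFactor^expo, 1)

  ampFF <- pmax(0.2, 1 + stats::rnorm(nTrials, 0, cfg@ampJitterSd))
  zAmp <- as.vector(scale(ampFF))
  rtNoise <- stats::rnorm(nTrials, 0, cfg@rtNoiseSdMs)
  rtShift <- ifelse(genContext == "predictable", cfg@rtContextShiftMs, 0)
  rtCoupling <- cfg@rtAmplitudeCoupling * (-zAmp)
  rtMs <- pmax(150, cfg@rtBaseMs + rtShift + rtCoupling + rtNoise)
  correct <- stats::runif(nTrials) < expectedAccuracy(cfg, tib)

  iti <- stats::runif(nTrials, cfg@itiRangeMs[1L], cfg@itiRangeMs[2L])
  preMarginS <- as.integer(round(0.5 * fs))
  onset <- integer(nTrials)
  onset[1L] <- preMarginS + 1L
  if (nTrials > 1L) for (i in 2:nTrials)
    onset[i] <- onset[i - 1L] +
      as.integer(round((rtMs[i - 1L] + iti[i - 1L]) * fs / 1000))
  saccade <- onset + as.integer(round(rtMs * fs / 1000))
  nS <- onset[nTrials] + as.integer(round(0.7 * fs))
  rtMs <- (saccade - onset) * 1000 / fs   # exact to the sample

  # laminar layout around the bottom of the injected sink region (what
  # the functional marker recovers), not the dipole center itself
  sinkBottom <- dipoleSinkBottom(cfg)
  trueMap <- assignCompartments(sinkBottom, cfg@nChannels, cfg@spacingMm)
  lab <- trueMap@compartments
  chAmp <- unname(cfg@compartmentAmp[lab])
  latBy <- c(cfg@evokedLatencyMs,
             outside = unname(cfg@evokedLatencyMs[["upper"]]))

  # per-compartment kernels: plain, and target variants per context
  comps <- c("upper", "middle", "deep", "outside")
  kern <- list()
  for (cp in comps) {
    base <- evokedKernel(latBy[[cp]], cfg@sustainedGain, fs)
    kern[[cp]] <- list(plain = base$k)
    for (ctx in c("unpredictable", "predictable")) {
      ksel <- base$k
      ksel[base$timeMs >= cfg@selectionOnsetMs[[ctx]]] <-
        ksel[base$timeMs >= cfg@selectionOnsetMs[[ctx]]] *
        (1 + cfg@selectionGain)
      kern[[cp]][[ctx]] <- ksel
    }
  }
  kLen <- length(kern[[1L]]$plain)

  # injected envelope: baseline level 1 + evoked responses
  env <- matrix(1, cfg@nChannels, nS)
  chBy <- lapply(comps, function(cp) which(lab == cp))
  names(chBy) <- comps
  for (i in seq_len(nTrials)) {
    idx <- onset[i]:(onset[i] + kLen - 1L)
    variant <- if (rfStim[i] == "target_in_rf") genContext[i] else "plain"
    a <- ampFF[i] * adaptMult[i]
    for (cp in comps) {
      rows <- chBy[[cp]]
      if (length(rows) == 0L) next
      env[rows, idx] <- env[rows, idx] +
        (a * chAmp[rows]) %o% kern[[cp]][[variant]]
    }
  }

  # evoked LFP dipole: negative trough at the sink channel
  klfp <- evokedKernel(cfg@lfpLatencyMs, 0, fs, durMs = 200)$k
  prof <- -cfg@lfpAmp *
    exp(-(seq_len(cfg@nChannels) - cfg@sinkChannel)^2 /
          (2 * cfg@lfpSinkWidthCh^2))
  lfp <- if (cfg@lfpNoiseSd > 0)
    matrix(stats::rnorm(cfg@nChannels * nS, 0, cfg@lfpNoiseSd),
           cfg@nChannels, nS)
  else matrix(0, cfg@nChannels, nS)
  lLen <- length(klfp)
  for (i in seq_len(nTrials)) {
    idx <- onset[i]:(onset[i] + lLen - 1L)
    lfp[, idx] <- lfp[, idx] + (ampFF[i] * prof) %o% klfp
  }

  # ongoing noise with context-dependent SD (piecewise per trial epoch)
  sdVec <- numeric(nS)
  bounds <- c(onset - preMarginS, nS + 1L)
  bounds[1L] <- 1L
  for (i in seq_len(nTrials)) {
    sdVec[bounds[i]:(bounds[i + 1L] - 1L)] <- cfg@baselineSd[[genContext[i]]]
  }
  noise <- matrix(stats::rnorm(cfg@nChannels * nS), cfg@nChannels, nS) *
    rep(sdVec, each = cfg@nChannels)

  signals <- list()
  if (cfg@mode == "envelope") {
    signals$envelope <- ContinuousSignal(env + noise, fs, cfg@spacingMm,
                                         unit = "a.u.")
    signals$lfp <- ContinuousSignal(lfp, fs, cfg@spacingMm, unit = "uV")
  } else {
    nyq <- fs / 2
    bp <- signal::butter(4, c(500, 5000) / nyq, type = "pass")
    carrier <- matrix(stats::rnorm(cfg@nChannels * nS), cfg@nChannels, nS)
    carrier <- filtfiltRows(carrier, bp,
                            min(nS - 1L, as.integer(round(0.05 * fs))))
    carrier <- carrier / stats::sd(carrier[1L, ])
    signals$broadband <- ContinuousSignal(carrier * (env + noise) * 20 + lfp,
                                          fs, cfg@spacingMm, unit = "uV")
    signals$lfp <- ContinuousSignal(lfp, fs, cfg@spacingMm, unit = "uV")
    signals$envelope <- ContinuousSignal(env, fs, cfg@spacingMm,
                                         unit = "a.u.")
  }

  trialsDf <- data.frame(
    session_id = sprintf("sim%03d", cfg@seed),
    trial = seq_len(nTrials),
    block = block,
    trial_in_block = tib,
    target_feature = feature,
    target_position = targetPos,
    rf_position = cfg@rfPosition,
    correct = correct,
    rt_ms = rtMs,
    array_onset_sample = onset,
    saccade_onset_sample = saccade,
    stringsAsFactors = FALSE)

  truth <- data.frame(
    trial = seq_len(nTrials),
    block = block,
    trial_in_block = tib,
    context = context3,
    target_feature = feature,
    target_position = targetPos,
    rf_stimulus = rfStim,
    amp_ff = ampFF,
    adapt_exponent = expo,
    adapt_multiplier = adaptMult,
    amp_upper = ampFF * adaptMult * cfg@compartmentAmp[["upper"]],
    amp_middle = ampFF * adaptMult * cfg@compartmentAmp[["middle"]],
    amp_deep = ampFF * adaptMult * cfg@compartmentAmp[["deep"]],
    selection_onset_ms = ifelse(rfStim == "target_in_rf",
                                unname(cfg@selectionOnsetMs[genContext]),
                                NA_real_),
    sink_channel = cfg@sinkChannel,
    sink_bottom_channel = sinkBottom,
    rt_base_ms = cfg@rtBaseMs,
    rt_context_shift_ms = rtShift,
    rt_coupling_term_ms = rtCoupling,
    rt_noise_ms = rtNoise,
    rt_ms = rtMs,
    correct = correct,
    stringsAsFactors = FALSE)

  session <- new("LaminarSession", id = sprintf("sim%03d", cfg@seed),
                 signals = signals, trials = trialsDf,
                 nChannels = cfg@nChannels, spacingMm = cfg@spacingMm)
  list(session = session, truth = truth)
}

#' Ground-truth report
#'
#' Returns the per-trial ground-truth ledger in its stable, documented
#' column order: trial identifiers and block structure, context, stimulus
#' identity in the RF, injected amplitudes per compartment, the adaptation
#' exponent/multiplier, the selection onset used (target trials only), the
#' generative RT components and correctness.
#'
#' @param truth the `truth` element returned by [simulateSession()].
#' @return data.frame with one row per trial (header only for an empty
#'   session).
#' @export
truthReport <- function(truth) {
  cols <- c("trial", "block", "trial_in_block", "context", "target_feature",
            "target_position", "rf_stimulus", "amp_ff", "adapt_exponent",
            "adapt_multiplier", "amp_upper", "amp_middle", "amp_deep",
            "selection_onset_ms", "sink_channel", "sink_bottom_channel",
            "rt_base_ms",
            "rt_context_shift_ms", "rt_coupling_term_ms", "rt_noise_ms",
            "rt_ms", "correct")
  missing <- setdiff(cols, names(truth))
  if (length(missing) > 0L)
    stop("not a ground-truth table; missing: ", paste(missing, collapse = ", "))
  truth[, cols, drop = FALSE]
}
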