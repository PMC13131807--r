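#' @import methods
NULL

#' Multichannel continuous recording
#'
#' A channels-by-time matrix of regularly sampled signal from a laminar
#' linear array, together with its sampling rate, the inter-contact spacing
#' and a unit tag. Channel index increases with cortical depth (channel 1 is
#' the most superficial contact).
#'
#' @slot samples numeric matrix, channels x time. Voltage in microvolts for
#'   broadband/LFP signals, arbitrary units for MUA envelopes.
#' @slot fsHz sampling rate in Hz.
#' @slot spacingMm inter-channel distance in mm (0.1 for the 32-channel
#'   arrays this package targets).
#' @slot unit free-text unit tag, e.g. "uV" or "a.u.".
#' @exportClass ContinuousSignal
setClass("ContinuousSignal",
  representation(samples = "matrix", fsHz = "numeric",
                 spacingMm = "numeric", unit = "character"),
  prototype(spacingMm = 0.1, unit = "a.u."),
  validity = function(object) {
    if (!is.numeric(object@samples)) return("samples must be numeric")
    if (!all(is.finite(object@samples))) return("samples must be finite")
    if (length(object@fsHz) != 1L || object@fsHz <= 0)
      return("fsHz must be a single positive number")
    if (length(object@spacingMm) != 1L || object@spacingMm <= 0)
      return("spacingMm must be a single positive number")
    TRUE
  })

#' Construct a ContinuousSignal
#'
#' @param samples channels x time numeric matrix.
#' @param fsHz sampling rate (Hz).
#' @param spacingMm inter-channel spacing (mm).
#' @param unit unit tag.
#' @return A [ContinuousSignal-class] object.
#' @export
ContinuousSignal <- function(samples, fsHz, spacingMm = 0.1, unit = "a.u.") {
  new("ContinuousSignal", samples = as.matrix(samples), fsHz = fsHz,
      spacingMm = spacingMm, unit = unit)
}

#' Current source density matrix
#'
#' CSD for the interior channels of a laminar probe, computed as the
#' negative conductivity-scaled second spatial derivative of the field
#' potential. Sinks (net inward current) are negative under this convention.
#'
#' @slot samples (channels - 2) x time numeric matrix; row i corresponds to
#'   input channel i + channelOffset.
#' @slot sigma cortical conductivity (S/m) used for scaling.
#' @slot channelOffset integer; interior row 1 maps to input channel
#'   1 + channelOffset (always 1 for the plain second difference).
#' @slot fsHz sampling rate in Hz.
#' @slot spacingMm inter-channel distance in mm.
#' @exportClass CsdMatrix
setClass("CsdMatrix",
  representation(samples = "matrix", sigma = "numeric",
                 channelOffset = "integer", fsHz = "numeric",
                 spacingMm = "numeric"),
  prototype(channelOffset = 1L),
  validity = function(object) {
    if (length(object@sigma) != 1L || object@sigma <= 0)
      return("sigma must be a single positive conductivity")
    TRUE
  })

#' Event-aligned epoch tensor
#'
#' Trials x channels x time array extracted around an alignment event, with
#' the time axis in ms relative to that event and a record of the baseline
#' window and normalization state.
#'
#' @slot data trials x channels x time numeric array.
#' @slot timeMs time axis in ms relative to the alignment event.
#' @slot alignment event name, e.g. "array_onset" or "saccade_onset".
#' @slot baselineMs closed baseline interval in ms (c(start, end)).
#' @slot normalized TRUE once single-trial baseline z-normalization has been
#'   applied.
#' @slot trialIndex integer ids of the trials in dimension 1 (row numbers of
#'   the originating trial table).
#' @slot metadata free-form list (exclusion logs etc.).
#' @exportClass EpochTensor
setClass("EpochTensor",
  representation(data = "array", timeMs = "numeric", alignment = "character",
                 baselineMs = "numeric", normalized = "logical",
                 trialIndex = "integer", metadata = "list"),
  prototype(normalized = FALSE, baselineMs = c(-250, 0), metadata = list()),
  validity = function(object) {
    if (length(dim(object@data)) != 3L)
      return("data must be a trials x channels x time array")
    if (length(object@timeMs) != dim(object@data)[3L])
      return("timeMs length must equal the time dimension")
    if (length(object@baselineMs) != 2L ||
        object@baselineMs[1L] > object@baselineMs[2L])
      return("baselineMs must be an ordered interval")
    if (length(object@trialIndex) != dim(object@data)[1L])
      return("trialIndex length must equal the trial dimension")
    TRUE
  })

#' Laminar alignment map
#'
#' Functional laminar alignment of a probe: the granular sink marker channel
#' and the assignment of every channel to the upper, middle or deep 0.5 mm
#' compartment (or "outside").
#'
#' @slot markerChannel channel index of the bottom of the initial granular
#'   input sink (1-based, increasing with depth).
#' @slot compartments character vector, one label per channel, each one of
#'   "upper", "middle", "deep", "outside".
#' @slot spacingMm inter-channel spacing in mm.
#' @slot truncated TRUE when a compartment ran off the edge of the array and
#'   was truncated.
#' @exportClass LaminarMap
setClass("LaminarMap",
  representation(markerChannel = "integer", compartments = "character",
                 spacingMm = "numeric", truncated = "logical"),
  validity = function(object) {
    ok <- c("upper", "middle", "deep", "outside")
    if (!all(object@compartments %in% ok))
      return("compartments must be upper/middle/deep/outside")
    if (object@markerChannel < 1L ||
        object@markerChannel > length(object@compartments))
      return("markerChannel out of range")
    TRUE
  })

#' Running nonparametric test result
#'
#' Result of a pointwise rank test over time with minimum-cluster
#' thresholding: per-timepoint statistic, p-value and direction sign, the
#' post-threshold significance mask, and the surviving clusters.
#'
#' @slot timeMs time axis in ms.
#' @slot statistic per-timepoint test statistic (rank-sum z or
#'   Kruskal-Wallis H).
#' @slot p per-timepoint p-value.
#' @slot sign per-timepoint direction sign (+1 where group A exceeds group
#'   B; all zero for the k-group test).
#' @slot mask logical; TRUE only inside surviving clusters.
#' @slot clusters data.frame with columns start_ms, end_ms, one row per
#'   surviving cluster.
#' @slot alpha pointwise significance level.
#' @slot minClusterMs minimum cluster duration in ms.
#' @slot test "ranksum" or "kruskal".
#' @exportClass RunningTestResult
setClass("RunningTestResult",
  representation(timeMs = "numeric", statistic = "numeric", p = "numeric",
                 sign = "numeric", mask = "logical", clusters = "data.frame",
                 alpha = "numeric", minClusterMs = "numeric",
                 test = "character"),
  validity = function(object) {
    n <- length(object@timeMs)
    if (length(object@p) != n || length(object@mask) != n)
      return("p and mask must match the time axis")
    TRUE
  })

#' Page's L trend test result
#'
#' @slot L observed trend statistic (sum over conditions of predicted rank
#'   times observed rank sum).
#' @slot n number of subjects (independent rankings).
#' @slot k number of ordered conditions.
#' @slot mu null mean n*k*(k+1)^2/4.
#' @slot sigma2 null variance n*k^2*(k+1)*(k^2-1)/144.
#' @slot z standardized statistic (L - mu)/sqrt(sigma2).
#' @slot pNormal one-sided upper-tail p from the normal approximation.
#' @slot pExact one-sided upper-tail p from the exact convolution null
#'   (NA when k > 8 and the exact method is skipped).
#' @slot method "exact" or "normal" - which p is recommended for inference.
#' @slot direction "increasing" or "decreasing" predicted trend.
#' @exportClass PageLResult
setClass("PageLResult",
  representation(L = "numeric", n = "integer", k = "integer", mu = "numeric",
                 sigma2 = "numeric", z = "numeric", pNormal = "numeric",
                 pExact = "numeric", method = "character",
                 direction = "character"))

#' One-way repeated-measures ANOVA result
#'
#' @slot statistic F ratio MS_effect / MS_error.
#' @slot dfEffect numerator degrees of freedom (k - 1).
#' @slot dfError denominator degrees of freedom ((n - 1)(k - 1)).
#' @slot p upper-tail p-value.
#' @slot ss named sums of squares: effect, subject, error.
#' @exportClass AnovaResult
setClass("AnovaResult",
  representation(statistic = "numeric", dfEffect = "integer",
                 dfError = "integer", p = "numeric", ss = "numeric"))

#' Laminar recording session
#'
#' Container for one session: the continuous signals (any of a broadband
#' recording, an MUA envelope and an LFP), the per-trial event table and the
#' probe geometry.
#'
#' @slot id session identifier.
#' @slot signals named list of [ContinuousSignal-class] objects; recognized
#'   names are "broadband", "envelope", "lfp".
#' @slot trials data.frame with one row per trial (see [parseBlocks()] for
#'   the column conventions: target_feature, target_position, rf_position,
#'   correct, rt_ms, array_onset_sample, saccade_onset_sample, ...).
#' @slot nChannels number of probe channels.
#' @slot spacingMm inter-channel spacing in mm.
#' @exportClass LaminarSession
setClass("LaminarSession",
  representation(id = "character", signals = "list", trials = "data.frame",
                 nChannels = "integer", spacingMm = "numeric"),
  validity = function(object) {
    if (!all(vapply(object@signals, is, logical(1L), "ContinuousSignal")))
      return("signals must be ContinuousSignal objects")
    TRUE
  })

#' Synthetic session configuration
#'
#' Parameters of the synthetic laminar pop-out session generator. Defaults
#' encode the study conditions the pipeline is designed for: a 32-channel
#' probe at 0.1 mm spacing, six search-array positions, blocks of repeated
#' target features, context-dependent selection onsets, reaction times
#' coupled to the single-trial feedforward amplitude, and multiplicative
#' adaptation of the response to repeated distractors in the receptive
#' field.
#'
#' @slot seed integer seed for the session's single pseudo-random stream.
#' @slot mode "envelope" (1 kHz MUA envelope + LFP) or "broadband"
#'   (spike-band carrier plus LFP at the full rate).
#' @slot nChannels number of probe channels (default 32).
#' @slot spacingMm contact spacing in mm (default 0.1).
#' @slot fsHz sampling rate: 1000 in envelope mode, 24414 in broadband mode.
#' @slot nBlocks number of target-feature blocks.
#' @slot blockLength trials per block (default 20; the context labels use
#'   trials 1-15 after each feature change, so values below 15 trigger a
#'   warning).
#' @slot nPositions number of array positions (default 6).
#' @slot rfPosition 0-based index of the position at the receptive-field
#'   center.
#' @slot rtBaseMs baseline reaction time in ms (default 259).
#' @slot rtContextShiftMs additive RT shift for the predictable context
#'   (default -15 ms).
#' @slot rtNoiseSdMs SD of the Gaussian RT noise in ms.
#' @slot rtAmplitudeCoupling RT gain in ms per SD of (negated) single-trial
#'   feedforward amplitude: stronger feedforward drive, faster saccade.
#' @slot accuracyStart probability correct on trial 1 of a block.
#' @slot accuracyPlateau asymptotic probability correct.
#' @slot accuracyTau e-fold constant (trials) of the accuracy rise.
#' @slot evokedLatencyMs named latencies (ms) of the evoked response per
#'   compartment: c(upper=, middle=, deep=).
#' @slot selectionOnsetMs named selection onsets (ms) per context:
#'   c(unpredictable=, predictable=).
#' @slot selectionGain fractional response gain for the target in the RF
#'   from the selection onset onward.
#' @slot adaptationFactor multiplicative attenuation per consecutive
#'   distractor-in-RF repetition, in (0, 1].
#' @slot baselineSd named ongoing-noise SD (envelope a.u.) per context:
#'   c(unpredictable=, predictable=).
#' @slot ampJitterSd SD of the shared multiplicative trial-to-trial
#'   feedforward amplitude jitter.
#' @slot compartmentAmp named evoked amplitude per compartment, including
#'   "outside" channels.
#' @slot sustainedGain sustained-plateau amplitude as a fraction of the
#'   transient peak.
#' @slot sinkChannel channel at the center of the granular LFP dipole.
#' @slot lfpAmp evoked LFP trough amplitude (uV).
#' @slot lfpSinkWidthCh Gaussian depth width (channels) of the dipole.
#' @slot lfpNoiseSd LFP noise SD (uV).
#' @slot lfpLatencyMs latency of the evoked LFP trough (ms).
#' @slot itiRangeMs uniform range of the interval between saccade and the
#'   next array onset (the fore-period; the generator makes no fidelity
#'   claim about its distribution).
#' @exportClass SimConfig
setClass("SimConfig",
  representation(seed = "integer", mode = "character", nChannels = "integer",
                 spacingMm = "numeric", fsHz = "numeric", nBlocks = "integer",
                 blockLength = "integer", nPositions = "integer",
                 rfPosition = "integer", rtBaseMs = "numeric",
                 rtContextShiftMs = "numeric", rtNoiseSdMs = "numeric",
                 rtAmplitudeCoupling = "numeric", accuracyStart = "numeric",
                 accuracyPlateau = "numeric", accuracyTau = "numeric",
                 evokedLatencyMs = "numeric", selectionOnsetMs = "numeric",
                 selectionGain = "numeric", adaptationFactor = "numeric",
                 baselineSd = "numeric", ampJitterSd = "numeric",
                 compartmentAmp = "numeric", sustainedGain = "numeric",
                 sinkChannel = "integer", lfpAmp = "numeric",
                 lfpSinkWidthCh = "numeric", lfpNoiseSd = "numeric",
                 lfpLatencyMs = "numeric", itiRangeMs = "numeric"),
  validity = function(object) {
    pr <- c(object@accuracyStart, object@accuracyPlateau)
    if (any(pr < 0 | pr > 1)) return("accuracy probabilities must be in [0,1]")
    if (object@adaptationFactor <= 0 || object@adaptationFactor > 1)
      return("adaptationFactor must be in (0, 1]")
    so <- object@selectionOnsetMs
    if (!all(c("unpredictable", "predictable") %in% names(so)))
      return("selectionOnsetMs needs unpredictable and predictable entries")
    if (so[["predictable"]] > so[["unpredictable"]])
      return("predictable selection onset must not exceed the unpredictable one")
    if (object@nPositions < 2L) return("nPositions must be at least 2")
    if (object@fsHz <= 0 || object@rtNoiseSdMs < 0)
      return("rates must be positive")
    if (object@rfPosition < 0L || object@rfPosition >= object@nPositions)
      return("rfPosition out of range")
    if (!all(c("upper", "middle", "deep") %in% names(object@evokedLatencyMs)))
      return("evokedLatencyMs needs upper/middle/deep entries")
    if (!all(c("unpredictable", "predictable") %in% names(object@baselineSd)))
      return("baselineSd needs unpredictable and predictable entries")
    TRUE
  })

#' Pipeline configuration
#'
#' All analysis parameters of the end-to-end pipeline in one object; see
#' [pipelineConfig()] for defaults and units.
#'
#' @slot simConfigs list of [SimConfig-class] (sessions to simulate), or
#'   empty when sessionPaths is used.
#' @slot sessionPaths directories of stored sessions to load.
#' @slot sigma cortical conductivity (S/m) for CSD scaling.
#' @slot csdBandHz LFP band (Hz) filtered before second differencing.
#' @slot epochWindowMs epoch window around array onset (ms).
#' @slot baselineNormMs baseline for single-trial z-normalization (ms).
#' @slot baselineVarMs baseline window for variability summaries (ms).
#' @slot baselineDeltaMs baseline window for the delta-contrast test (ms).
#' @slot smoothWindowMs bidirectional moving-average window (ms).
#' @slot alphaCluster pointwise alpha of the running cluster tests.
#' @slot alphaTrend alpha for trend/ANOVA tests.
#' @slot minClusterMs minimum cluster length (ms) for running tests.
#' @slot minClusterDeltaMs minimum cluster length (ms) for the delta
#'   contrasts.
#' @slot adaptEarlyMs early adaptation window (ms after array onset).
#' @slot adaptLateStartMs start (ms) of the late adaptation window; the
#'   window ends adaptLateSaccadeOffsetMs before saccade onset.
#' @slot adaptLateSaccadeOffsetMs gap (ms) between the late-window end and
#'   saccade onset.
#' @slot minSequencesPerSession minimum qualifying adaptation sequences for
#'   a session to enter the trend test.
#' @slot quartilePerContext quartile RTs within each context separately.
#' @slot markerSdThreshold sink-detection threshold in baseline SDs.
#' @slot markerSearchMs sink search window (ms after array onset).
#' @slot outputDir directory for result files ("" = do not write).
#' @exportClass PipelineConfig
setClass("PipelineConfig",
  representation(simConfigs = "list", sessionPaths = "character",
                 sigma = "numeric", csdBandHz = "numeric",
                 epochWindowMs = "numeric", baselineNormMs = "numeric",
                 baselineVarMs = "numeric", baselineDeltaMs = "numeric",
                 smoothWindowMs = "numeric", alphaCluster = "numeric",
                 alphaTrend = "numeric", minClusterMs = "numeric",
                 minClusterDeltaMs = "numeric", adaptEarlyMs = "numeric",
                 adaptLateStartMs = "numeric",
                 adaptLateSaccadeOffsetMs = "numeric",
                 minSequencesPerSession = "integer",
                 quartilePerContext = "logical",
                 markerSdThreshold = "numeric", markerSearchMs = "numeric",
                 outputDir = "character"),
  validity = function(object) {
    win <- list(object@epochWindowMs, object@baselineNormMs,
                object@baselineVarMs, object@baselineDeltaMs,
                object@adaptEarlyMs)
    for (w in win)
      if (length(w) != 2L || w[1L] >= w[2L])
        return("every window must be an ordered pair")
    if (object@alphaCluster <= 0 || object@alphaCluster >= 1 ||
        object@alphaTrend <= 0 || object@alphaTrend >= 1)
      return("alphas must be in (0, 1)")
    TRUE
  })
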