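# End-to-end orchestration: simulate/load -> preprocess -> align ->
# analyze -> report.

#' Pipeline configuration
#'
#' Collects every analysis parameter of the pipeline with the defaults
#' used throughout: single-trial z-normalization against the -250..0 ms
#' baseline, 15 ms bidirectional smoothing, running cluster tests at
#' pointwise alpha 0.01 with 25 ms minimum clusters (20 ms for the delta
#' contrasts), trend/ANOVA tests at alpha 0.05, adaptation windows 58-78
#' ms (early) and 78 ms to saccade-minus-10-ms (late), and at least 15
#' qualifying sequences per session.
#'
#' @param simConfigs list of [SimConfig-class] objects (sessions to
#'   simulate); ignored when `sessionPaths` is given.
#' @param sessionPaths directories of stored sessions (see
#'   [readSession()]).
#' @param sigma cortical conductivity (S/m).
#' @param csdBandHz LFP band for CSD (Hz).
#' @param epochWindowMs,baselineNormMs,baselineVarMs,baselineDeltaMs
#'   windows in ms.
#' @param smoothWindowMs smoothing window (ms).
#' @param alphaCluster,alphaTrend significance levels.
#' @param minClusterMs,minClusterDeltaMs minimum cluster lengths (ms).
#' @param adaptEarlyMs,adaptLateStartMs,adaptLateSaccadeOffsetMs
#'   adaptation windows (ms).
#' @param minSequencesPerSession session inclusion threshold.
#' @param quartilePerContext quartile within context (default TRUE).
#' @param markerSdThreshold,markerSearchMs sink detection parameters.
#' @param outputDir directory for result files ("" = in-memory only).
#' @return a validated [PipelineConfig-class].
#' @export
pipelineConfig <- function(simConfigs = list(), sessionPaths = character(0),
                           sigma = 0.4, csdBandHz = c(1, 100),
                           epochWindowMs = c(-300, 300),
                           baselineNormMs = c(-250, 0),
                           baselineVarMs = c(-300, 0),
                           baselineDeltaMs = c(-250, 0),
                           smoothWindowMs = 15, alphaCluster = 0.01,
                           alphaTrend = 0.05, minClusterMs = 25,
                           minClusterDeltaMs = 20, adaptEarlyMs = c(58, 78),
                           adaptLateStartMs = 78,
                           adaptLateSaccadeOffsetMs = 10,
                           minSequencesPerSession = 15L,
                           quartilePerContext = TRUE,
                           markerSdThreshold = 3, markerSearchMs = c(25, 100),
                           outputDir = "") {
  new("PipelineConfig", simConfigs = simConfigs,
      sessionPaths = sessionPaths, sigma = sigma, csdBandHz = csdBandHz,
      epochWindowMs = epochWindowMs, baselineNormMs = baselineNormMs,
      baselineVarMs = baselineVarMs, baselineDeltaMs = baselineDeltaMs,
      smoothWindowMs = smoothWindowMs, alphaCluster = alphaCluster,
      alphaTrend = alphaTrend, minClusterMs = minClusterMs,
      minClusterDeltaMs = minClusterDeltaMs, adaptEarlyMs = adaptEarlyMs,
      adaptLateStartMs = adaptLateStartMs,
      adaptLateSaccadeOffsetMs = adaptLateSaccadeOffsetMs,
      minSequencesPerSession = as.integer(minSequencesPerSession),
      quartilePerContext = quartilePerContext,
      markerSdThreshold = markerSdThreshold,
      markerSearchMs = markerSearchMs, outputDir = outputDir)
}

# subset an EpochTensor by trial-table row ids
subsetEpochs <- function(epochs, rowIds) {
  keep <- which(epochs@trialIndex %in% rowIds)
  out <- epochs
  out@data <- epochs@data[keep, , , drop = FALSE]
  out@trialIndex <- epochs@trialIndex[keep]
  out
}

#' Preprocess and align one session
#'
#' Runs the per-session stages: trial-table parsing (blocks, context, RF
#' stimulus identity, RT quartiles), MUA envelope (extracted from the
#' broadband signal when no precomputed envelope is present), epoch
#' extraction, single-trial z-normalization, smoothing, LFP band-limiting,
#' CSD, and functional laminar alignment. Sessions without a discernible
#' sink raise a `laminarpop_no_sink` condition (callers typically exclude
#' them).
#'
#' @param session a [LaminarSession-class].
#' @param cfg a [PipelineConfig-class].
#' @return list with `trials` (augmented table), `epochs` (normalized,
#'   smoothed MUA epochs), `csdEpochs`, `map` ([LaminarMap-class]) and
#'   `log` (exclusion counts).
#' @export
preprocessSession <- function(session, cfg = pipelineConfig()) {
  stopifnot(is(session, "LaminarSession"))
  tt <- session@trials
  if (is.null(tt$trial_in_block)) tt <- parseBlocks(tt)
  tt$context <- labelContext(tt$trial_in_block)
  tt$rf_stimulus <- labelRfStimulus(tt$target_position, tt$rf_position)
  tt$quartile <- quartileLabels(tt, perContext = cfg@quartilePerContext)

  env <- session@signals$envelope
  fsRaw <- if (!is.null(session@signals$broadband))
    session@signals$broadband@fsHz else env@fsHz
  if (is.null(env)) {
    if (is.null(session@signals$broadband))
      stop("session has neither an envelope nor a broadband signal")
    env <- extractMuaEnvelope(session@signals$broadband)
  }
  onsetEnv <- as.integer(round((tt$array_onset_sample - 1L) *
                                 env@fsHz / fsRaw)) + 1L
  epochs <- epochExtract(env, onsetEnv, cfg@epochWindowMs, "array_onset",
                         trialIndex = seq_len(nrow(tt)))
  epochs <- zNormalize(epochs, cfg@baselineNormMs)
  epochs <- smoothBidirectional(epochs, cfg@smoothWindowMs)

  lfp <- session@signals$lfp
  if (is.null(lfp)) stop("session has no LFP signal for laminar alignment")
  lfpF <- filterBand(lfp, cfg@csdBandHz)
  csd <- computeCsd(lfpF, cfg@sigma)
  csdSig <- ContinuousSignal(csd@samples, csd@fsHz, csd@spacingMm,
                             unit = "csd")
  onsetLfp <- as.integer(round((tt$array_onset_sample - 1L) *
                                 lfp@fsHz / fsRaw)) + 1L
  csdEpochs <- epochExtract(csdSig, onsetLfp, cfg@epochWindowMs,
                            "array_onset", trialIndex = seq_len(nrow(tt)))
  evoked <- evokedCsd(csdEpochs, cfg@baselineNormMs)
  marker <- findGranularMarker(evoked, searchMs = cfg@markerSearchMs,
                               k = cfg@markerSdThreshold,
                               baselineMs = cfg@baselineNormMs,
                               channelOffset = csd@channelOffset)
  map <- assignCompartments(marker, session@nChannels, session@spacingMm)

  list(id = session@id, trials = tt, epochs = epochs, csdEpochs = csdEpochs,
       map = map,
       log = list(nExcludedZeroVar = epochs@metadata$nExcludedZeroVar,
                  nDroppedBounds = epochs@metadata$nDroppedBounds))
}

# pooled target-vs-distractor TST across sessions at the compartment level
pooledTst <- function(ppList, selector, cfg) {
  tm <- ppList[[1L]]$epochs@timeMs
  ti <- which(tm >= 0)
  out <- c(upper = NA_real_, middle = NA_real_, deep = NA_real_)
  for (cp in names(out)) {
    A <- NULL; B <- NULL
    for (pp in ppList) {
      sel <- selector(pp$trials)
      rows <- which(sel & pp$trials$rf_stimulus == "target_in_rf")
      rowsD <- which(sel & pp$trials$rf_stimulus == "distractor_in_rf")
      if (length(rows) == 0L || length(rowsD) == 0L) next
      A <- rbind(A, compartmentTrialMatrix(subsetEpochs(pp$epochs, rows),
                                           pp$map, cp))
      B <- rbind(B, compartmentTrialMatrix(subsetEpochs(pp$epochs, rowsD),
                                           pp$map, cp))
    }
    if (is.null(A) || is.null(B) || nrow(A) < 2L || nrow(B) < 2L) next
    res <- runningRanksumCluster(A[, ti, drop = FALSE],
                                 B[, ti, drop = FALSE], tm[ti],
                                 cfg@alphaCluster, cfg@minClusterMs,
                                 direction = "greater")
    out[[cp]] <- clusterOnset(res, "positive")
  }
  out
}

# per-session mean compartment waveform over a trial subset (NULL if empty)
sessionMeanWave <- function(pp, rows, compartment) {
  if (length(rows) == 0L) return(NULL)
  m <- compartmentTrialMatrix(subsetEpochs(pp$epochs, rows), pp$map,
                              compartment)
  colMeans(m)
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) every configured session, preprocesses and aligns
#' it, and produces the complete result bundle: the target-selection-time
#' table per compartment x context x RT quartile, delta-TE/delta-DS
#' contrasts with onsets (overall and per compartment), between-quartile
#' variability profiles per context, adaptation trend tests per
#' compartment and window, behavioral summaries (median RT per context,
#' accuracy-by-trial curve with a repeated-measures ANOVA across
#' sessions), and an exclusion log. Deterministic given the configuration
#' (including the simulation seeds).
#'
#' @param cfg a [PipelineConfig-class].
#' @return a result list; when `outputDir` is set, tables are also written
#'   as CSV/JSON files there.
#' @export
runPipeline <- function(cfg) {
  stopifnot(is(cfg, "PipelineConfig"))
  sessions <- if (length(cfg@sessionPaths) > 0L) {
    lapply(cfg@sessionPaths, function(p)
      tryCatch(readSession(p), error = function(e) e))
  } else {
    lapply(cfg@simConfigs, function(sc) simulateSession(sc)$session)
  }
  exclusions <- list()
  ppList <- list()
  for (s in sessions) {
    if (inherits(s, "error")) {
      exclusions[[length(exclusions) + 1L]] <-
        list(id = "unreadable", reason = conditionMessage(s))
      next
    }
    pp <- tryCatch(preprocessSession(s, cfg), error = function(e) e)
    if (inherits(pp, "error")) {
      exclusions[[length(exclusions) + 1L]] <-
        list(id = s@id, reason = conditionMessage(pp))
      next
    }
    ppList[[length(ppList) + 1L]] <- pp
  }
  if (length(ppList) == 0L) stop("no usable sessions")
  tm <- ppList[[1L]]$epochs@timeMs

  # --- TST table (compartment x context x quartile) ---
  qLevels <- c("all", "fastest", "faster", "slower", "slowest")
  contexts <- c("unpredictable", "predictable")
  tst <- array(NA_real_, dim = c(3L, 2L, 5L),
               dimnames = list(c("upper", "middle", "deep"), contexts,
                               qLevels))
  for (ctx in contexts) for (q in qLevels) {
    sel <- function(trials) {
      ok <- trials$correct & trials$context == ctx
      if (q != "all") ok <- ok & !is.na(trials$quartile) &
          trials$quartile == q
      ok
    }
    tst[, ctx, q] <- pooledTst(ppList, sel, cfg)
  }

  # --- delta TE / delta DS ---
  stackWaves <- function(compartment) {
    cells <- list(targetPred = NULL, targetUnpred = NULL, distPred = NULL,
                  distUnpred = NULL)
    for (pp in ppList) {
      tt <- pp$trials
      pick <- function(ctx, stim)
        which(tt$correct & tt$context == ctx & tt$rf_stimulus == stim)
      w <- list(
        targetPred = sessionMeanWave(pp, pick("predictable", "target_in_rf"),
                                     compartment),
        targetUnpred = sessionMeanWave(pp, pick("unpredictable",
                                                "target_in_rf"), compartment),
        distPred = sessionMeanWave(pp, pick("predictable",
                                            "distractor_in_rf"), compartment),
        distUnpred = sessionMeanWave(pp, pick("unpredictable",
                                              "distractor_in_rf"),
                                     compartment))
      if (any(vapply(w, is.null, logical(1L)))) next
      for (nm in names(cells)) cells[[nm]] <- rbind(cells[[nm]], w[[nm]])
    }
    cells
  }
  delta <- list()
  for (cp in c("all", "middle", "upper", "deep")) {
    cells <- stackWaves(cp)
    if (is.null(cells$targetPred) || nrow(cells$targetPred) < 2L) next
    delta[[cp]] <- deltaTeDs(cells$targetPred, cells$targetUnpred,
                             cells$distPred, cells$distUnpred, tm,
                             cfg@baselineDeltaMs, cfg@alphaCluster,
                             cfg@minClusterDeltaMs)
  }

  # --- between-quartile variability (target responses, general profile) ---
  variability <- list()
  for (ctx in contexts) {
    waves <- NULL
    for (q in qLevels[-1L]) {
      pooled <- NULL
      for (pp in ppList) {
        tt <- pp$trials
        rows <- which(tt$correct & tt$context == ctx &
                        !is.na(tt$quartile) & tt$quartile == q &
                        tt$rf_stimulus == "target_in_rf")
        if (length(rows) == 0L) next
        allCh <- sort(unlist(lapply(c("upper", "middle", "deep"),
                                    function(c2)
                                      compartmentChannels(pp$map, c2))))
        sub <- subsetEpochs(pp$epochs, rows)
        pooled <- rbind(pooled, apply(sub@data[, allCh, , drop = FALSE],
                                      c(1L, 3L), mean))
      }
      if (is.null(pooled)) { waves <- NULL; break }
      waves <- rbind(waves, colMeans(pooled))
    }
    if (!is.null(waves) && nrow(waves) == 4L)
      variability[[ctx]] <- quartileVariability(waves, tm,
                                                cfg@baselineVarMs, ctx)
  }

  # --- adaptation ---
  adaptation <- runAdaptation(ppList, cfg)

  # --- behavior ---
  rtAll <- do.call(rbind, lapply(ppList, function(pp)
    pp$trials[pp$trials$correct &
                pp$trials$context %in% contexts,
              c("context", "rt_ms")]))
  medianRt <- tapply(rtAll$rt_ms, rtAll$context, stats::median)
  accMat <- t(vapply(ppList, function(pp) {
    tt <- pp$trials
    vapply(1:15, function(t)
      mean(tt$correct[tt$trial_in_block == t]), numeric(1L))
  }, numeric(15L)))
  accAnova <- if (nrow(accMat) >= 2L && all(is.finite(accMat)))
    rmAnova(accMat) else NULL

  result <- list(
    nSessionsUsed = length(ppList),
    maps = lapply(ppList, `[[`, "map"),
    tstTable = tst,
    delta = delta,
    variability = variability,
    adaptation = adaptation,
    behavior = list(medianRtMs = medianRt, accuracyByTrial = accMat,
                    accuracyAnova = accAnova,
                    chanceLevel = chanceLevel()),
    exclusions = exclusions)
  if (nzchar(cfg@outputDir)) writeResultBundle(result, cfg)
  result
}

# adaptation analysis across sessions: sequences, window means, trends
runAdaptation <- function(ppList, cfg) {
  perSession <- list()
  for (pp in ppList) {
    fs <- findSequences(pp$trials, minPerSession = 0L)
    if (nrow(fs$sequences) < cfg@minSequencesPerSession) next
    rt <- pp$trials$rt_ms
    early <- windowMeans(pp$epochs, pp$map, fs$sequences, rt, "early",
                         earlyMs = cfg@adaptEarlyMs)
    late <- windowMeans(pp$epochs, pp$map, fs$sequences, rt, "late",
                        lateStartMs = cfg@adaptLateStartMs,
                        lateSaccadeOffsetMs = cfg@adaptLateSaccadeOffsetMs)
    perSession[[pp$id]] <- list(n = early$nSequences, early = early$means,
                                late = late$means)
  }
  if (length(perSession) < 2L)
    return(list(nIncludedSessions = length(perSession), trends = NULL))
  trends <- list()
  for (win in c("early", "late")) {
    for (cp in c("upper", "middle", "deep")) {
      m <- t(vapply(perSession, function(ps) ps[[win]][cp, ],
                    numeric(5L)))
      centered <- centerRows(m)
      trends[[paste(win, cp, sep = "_")]] <-
        adaptationTrend(centered[, 2:5, drop = FALSE])
    }
  }
  list(nIncludedSessions = length(perSession),
       perSession = perSession, trends = trends)
}

# write the result bundle as CSV/JSON files
writeResultBundle <- function(result, cfg) {
  dir.create(cfg@outputDir, recursive = TRUE, showWarnings = FALSE)
  tst <- result$tstTable
  rows <- NULL
  for (cp in dimnames(tst)[[1L]]) for (ctx in dimnames(tst)[[2L]])
    for (q in dimnames(tst)[[3L]])
      rows <- rbind(rows, data.frame(compartment = cp, context = ctx,
                                     quartile = q, tst_ms = tst[cp, ctx, q]))
  utils::write.csv(rows, file.path(cfg@outputDir, "tst_table.csv"),
                   row.names = FALSE)
  deltaJson <- lapply(result$delta, function(d) list(
    te = list(onset_ms = d$te$onsetMs, clusters = d$te$test@clusters),
    ds = list(onset_ms = d$ds$onsetMs, clusters = d$ds$test@clusters)))
  jsonlite::write_json(deltaJson,
                       file.path(cfg@outputDir, "delta_contrasts.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(result$adaptation$trends)) {
    tr <- lapply(result$adaptation$trends, function(p) list(
      L = p@L, p_exact = p@pExact, p_normal = p@pNormal))
    jsonlite::write_json(tr,
                         file.path(cfg@outputDir, "adaptation_trends.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  beh <- result$behavior
  utils::write.csv(
    data.frame(context = names(beh$medianRtMs),
               median_rt_ms = as.numeric(beh$medianRtMs)),
    file.path(cfg@outputDir, "median_rt.csv"), row.names = FALSE)
  invisible(NULL)
}
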