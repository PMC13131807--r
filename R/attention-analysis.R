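# Headline analyses: target selection times, selection profiles, delta
# TE/DS contrasts, between-quartile variability and the CSD condition
# comparison.

# trials x time matrix of the compartment-averaged signal
compartmentTrialMatrix <- function(epochs, map, compartment,
                                   channelOffset = 0L) {
  ch <- compartmentChannels(map, compartment) - channelOffset
  ch <- ch[ch >= 1L & ch <= dim(epochs@data)[2L]]
  if (length(ch) == 0L) stop("no channels of compartment '", compartment,
                             "' inside the array")
  acc <- epochs@data[, ch[1L], ]
  if (length(ch) > 1L) for (c2 in ch[-1L]) acc <- acc + epochs@data[, c2, ]
  if (dim(epochs@data)[1L] == 1L) acc <- matrix(acc, nrow = 1L)
  acc / length(ch)
}

#' Target selection time per compartment and channel
#'
#' The target selection time (TST) is the earliest time after array onset
#' at which the population response to the target in the receptive field
#' significantly exceeds the response to a distractor: the onset of the
#' first surviving cluster of a running rank-sum test (two-sided pointwise
#' p, with cluster membership additionally requiring the target-above-
#' distractor direction). Compartment-level TSTs are computed on
#' compartment-averaged single-trial signals; channel-level TSTs on each
#' channel.
#'
#' @param targetEpochs,distractorEpochs normalized, smoothed
#'   [EpochTensor-class] objects on a common time axis (target-in-RF and
#'   distractor-in-RF trials).
#' @param map a [LaminarMap-class] (needed for compartment-level TSTs).
#' @param alpha pointwise alpha (default 0.01).
#' @param minClusterMs minimum cluster length in ms (default 25).
#' @param windowMs analysis window; the test is restricted to it (default
#'   from array onset to the end of the epoch).
#' @param level "compartment", "channel" or both.
#' @return list with elements `compartment` (named numeric, NA when no
#'   cluster) and/or `channel` (numeric per channel).
#' @export
targetSelectionTime <- function(targetEpochs, distractorEpochs, map = NULL,
                                alpha = 0.01, minClusterMs = 25,
                                windowMs = c(0, Inf),
                                level = c("compartment", "channel")) {
  level <- match.arg(level, several.ok = TRUE)
  ti <- windowIndex(targetEpochs@timeMs, windowMs)
  tm <- targetEpochs@timeMs[ti]
  out <- list()
  if ("compartment" %in% level) {
    if (is.null(map)) stop("a LaminarMap is required for compartment TSTs")
    tst <- c(upper = NA_real_, middle = NA_real_, deep = NA_real_)
    for (cp in names(tst)) {
      A <- compartmentTrialMatrix(targetEpochs, map, cp)[, ti, drop = FALSE]
      B <- compartmentTrialMatrix(distractorEpochs, map, cp)[, ti, drop = FALSE]
      res <- runningRanksumCluster(A, B, tm, alpha, minClusterMs,
                                   direction = "greater")
      tst[[cp]] <- clusterOnset(res, "positive")
    }
    out$compartment <- tst
  }
  if ("channel" %in% level) {
    nC <- dim(targetEpochs@data)[2L]
    tstCh <- rep(NA_real_, nC)
    for (ch in seq_len(nC)) {
      A <- targetEpochs@data[, ch, ti]
      B <- distractorEpochs@data[, ch, ti]
      res <- runningRanksumCluster(A, B, tm, alpha, minClusterMs,
                                   direction = "greater")
      tstCh[ch] <- clusterOnset(res, "positive")
    }
    out$channel <- tstCh
  }
  out
}

#' Selection profile: target minus distractor response
#'
#' The mean target-in-RF response minus the mean distractor-in-RF
#' response over time, per laminar compartment and for the general
#' cortical profile (all compartment channels). With identically
#' distributed inputs the waveform fluctuates around zero.
#'
#' @param targetEpochs,distractorEpochs normalized [EpochTensor-class]
#'   objects on a common time axis.
#' @param map a [LaminarMap-class].
#' @return list with `timeMs`, `all` (general profile) and one waveform
#'   per compartment (`upper`, `middle`, `deep`).
#' @export
selectionProfile <- function(targetEpochs, distractorEpochs, map) {
  out <- list(timeMs = targetEpochs@timeMs)
  allCh <- sort(unlist(lapply(c("upper", "middle", "deep"),
                              function(cp) compartmentChannels(map, cp))))
  meanWave <- function(ep, ch) {
    sub <- ep@data[, ch, , drop = FALSE]
    apply(sub, 3L, mean)
  }
  out$all <- meanWave(targetEpochs, allCh) - meanWave(distractorEpochs, allCh)
  for (cp in c("upper", "middle", "deep")) {
    ch <- compartmentChannels(map, cp)
    out[[cp]] <- meanWave(targetEpochs, ch) - meanWave(distractorEpochs, ch)
  }
  out
}

#' Changes in target enhancement and distractor suppression
#'
#' Delta-TE is the predictable-context minus unpredictable-context mean
#' target response; delta-DS the same contrast for distractor responses
#' (negative delta-DS = suppression). Both contrasts are formed per
#' session on identically normalized data; significance against baseline
#' is assessed with a running rank-sum test between the per-session
#' delta(t) values and the per-session baseline means, with a 20 ms
#' minimum cluster.
#'
#' @param targetPred,targetUnpred,distPred,distUnpred sessions x time
#'   matrices of per-session mean responses for the four context x
#'   stimulus cells.
#' @param timeMs common time axis (ms).
#' @param baselineMs baseline window for the reference sample (ms).
#' @param alpha pointwise alpha (default 0.01).
#' @param minClusterMs minimum cluster length (default 20 ms for the
#'   delta contrasts).
#' @return list with elements `te` and `ds`, each holding `perSession`
#'   (sessions x time), `waveform` (session mean), `test`
#'   ([RunningTestResult-class]) and `onsetMs`.
#' @export
deltaTeDs <- function(targetPred, targetUnpred, distPred, distUnpred,
                      timeMs, baselineMs = c(-250, 0), alpha = 0.01,
                      minClusterMs = 20) {
  mats <- list(targetPred, targetUnpred, distPred, distUnpred)
  if (length(unique(vapply(mats, ncol, integer(1L)))) != 1L ||
      length(unique(vapply(mats, nrow, integer(1L)))) != 1L)
    stop("all four context x stimulus matrices are required, on a common axis")
  contrast <- function(pred, unpred) {
    delta <- pred - unpred
    bi <- windowIndex(timeMs, baselineMs)
    ref <- matrix(rowMeans(delta[, bi, drop = FALSE]), nrow(delta),
                  ncol(delta))
    test <- runningRanksumCluster(delta, ref, timeMs, alpha, minClusterMs)
    list(perSession = delta, waveform = colMeans(delta), test = test,
         onsetMs = clusterOnset(test))
  }
  list(te = contrast(targetPred, targetUnpred),
       ds = contrast(distPred, distUnpred))
}

#' Between-quartile variability profile
#'
#' The sample variance (divisor 3) across the four RT-quartile-average
#' response waveforms at each timepoint; higher values mean greater
#' divergence of neural activity between behavioral outcome groups. The
#' baseline summary is the mean variance over the baseline window.
#'
#' @param quartileWaveforms 4 x time matrix (fastest..slowest mean
#'   waveforms).
#' @param timeMs time axis (ms).
#' @param baselineMs baseline window (default c(-300, 0)).
#' @param context optional context label carried through.
#' @return list with `variance` (per timepoint), `baselineMean`, `timeMs`
#'   and `context`.
#' @export
quartileVariability <- function(quartileWaveforms, timeMs,
                                baselineMs = c(-300, 0), context = NA) {
  quartileWaveforms <- as.matrix(quartileWaveforms)
  if (nrow(quartileWaveforms) != 4L)
    stop("exactly 4 quartile waveforms are required")
  v <- apply(quartileWaveforms, 2L, stats::var)
  bi <- windowIndex(timeMs, baselineMs)
  list(variance = v, baselineMean = mean(v[bi]), timeMs = timeMs,
       context = context)
}

#' Compartment-averaged CSD traces per condition
#'
#' Averages CSD epochs within each laminar compartment (upper/granular/
#' deep) for every condition, for descriptive comparison of putative
#' synaptic activation across conditions.
#'
#' @param csdEpochsByCondition named list of [EpochTensor-class] objects
#'   of CSD (trials x interior channels x time) on a common axis.
#' @param map a [LaminarMap-class] in probe-channel indexing.
#' @param channelOffset offset between CSD rows and probe channels (1 for
#'   the plain interior-channel CSD).
#' @return list with `timeMs` and `traces`: per condition a 3 x time
#'   matrix (rows upper/middle/deep).
#' @export
csdConditionComparison <- function(csdEpochsByCondition, map,
                                   channelOffset = 1L) {
  stopifnot(length(csdEpochsByCondition) >= 1L)
  tm <- csdEpochsByCondition[[1L]]@timeMs
  traces <- lapply(csdEpochsByCondition, function(ep) {
    out <- vapply(c("upper", "middle", "deep"), function(cp)
      colMeans(compartmentTrialMatrix(ep, map, cp, channelOffset)),
      numeric(length(tm)))
    t(out)
  })
  list(timeMs = tm, traces = traces)
}
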