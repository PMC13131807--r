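# Trial-table structure: blocks, predictability context, RF stimulus
# identity, RT quartiles and event-aligned epoch extraction.

#' Parse feature blocks from a trial table
#'
#' Adds `block` and `trial_in_block` columns: a new block starts wherever
#' `target_feature` changes (the target and distractor features swap at
#' block boundaries), and `trial_in_block` restarts at 1.
#'
#' @param trialTable data.frame in temporal order with a `target_feature`
#'   column.
#' @return the table with `block` and `trial_in_block` columns.
#' @export
parseBlocks <- function(trialTable) {
  n <- nrow(trialTable)
  if (n == 0L) {
    trialTable$block <- integer(0)
    trialTable$trial_in_block <- integer(0)
    return(trialTable)
  }
  f <- trialTable$target_feature
  change <- c(TRUE, f[-1L] != f[-n])
  block <- cumsum(change)
  tib <- stats::ave(seq_len(n), block, FUN = seq_along)
  trialTable$block <- as.integer(block)
  trialTable$trial_in_block <- as.integer(tib)
  trialTable
}

#' Predictability context from the trial position in a block
#'
#' Trials 1-2 after a feature change are "unpredictable" (the
#' oddball-defining feature is new), trials 3-15 are "predictable" (the
#' feature has repeated), and later trials are "excluded" from the
#' context contrast.
#'
#' @param trialInBlock 1-based trial count since the last feature swap.
#' @return character vector in {"unpredictable", "predictable", "excluded"}.
#' @export
labelContext <- function(trialInBlock) {
  if (any(trialInBlock < 1L)) stop("trial_in_block must be >= 1")
  out <- rep("excluded", length(trialInBlock))
  out[trialInBlock <= 2L] <- "unpredictable"
  out[trialInBlock >= 3L & trialInBlock <= 15L] <- "predictable"
  out
}

#' Stimulus identity in the receptive field
#'
#' @param targetPosition 0-based array position of the target per trial.
#' @param rfPosition 0-based position at the receptive-field center.
#' @return character vector in {"target_in_rf", "distractor_in_rf"}.
#' @export
labelRfStimulus <- function(targetPosition, rfPosition) {
  ifelse(targetPosition == rfPosition, "target_in_rf", "distractor_in_rf")
}

#' Reaction-time quartile stratification
#'
#' Sorts trials (correct trials of one session x context) ascending by RT
#' and splits them into four contiguous groups, labeled fastest, faster,
#' slower, slowest. When the count is not divisible by four, the extra
#' trials go to the fastest groups; ties are broken stably by trial order.
#'
#' @param rtMs reaction times in ms.
#' @return factor of quartile labels (fastest/faster/slower/slowest), in
#'   the input trial order; NULL-like error for fewer than 4 trials.
#' @export
stratifyRtQuartiles <- function(rtMs) {
  n <- length(rtMs)
  if (n < 4L)
    stop(errorCondition("fewer than 4 trials; quartile stratification skipped",
                        class = c("laminarpop_too_few_trials", "error",
                                  "condition")))
  ord <- order(rtMs)                       # stable: ties keep trial order
  sizes <- rep(n %/% 4L, 4L)
  extra <- n %% 4L
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  lev <- c("fastest", "faster", "slower", "slowest")
  lab <- rep(lev, times = sizes)
  out <- character(n)
  out[ord] <- lab
  factor(out, levels = lev)
}

#' Quartile labels per session and context
#'
#' Convenience wrapper applying [stratifyRtQuartiles()] to the correct
#' trials of each context of one session (or to all correct trials jointly
#' when `perContext = FALSE`). Incorrect trials and contexts with fewer
#' than 4 correct trials get NA.
#'
#' @param trialTable parsed trial table with `context`, `correct`, `rt_ms`.
#' @param perContext quartile within each context separately (default).
#' @return factor vector of quartile labels aligned with the table rows.
#' @export
quartileLabels <- function(trialTable, perContext = TRUE) {
  lev <- c("fastest", "faster", "slower", "slowest")
  out <- factor(rep(NA_character_, nrow(trialTable)), levels = lev)
  grp <- if (perContext) trialTable$context else rep("all", nrow(trialTable))
  for (g in unique(grp)) {
    idx <- which(grp == g & trialTable$correct &
                   trialTable$context %in% c("unpredictable", "predictable"))
    if (length(idx) >= 4L)
      out[idx] <- stratifyRtQuartiles(trialTable$rt_ms[idx])
  }
  out
}

#' Extract event-aligned epochs
#'
#' Cuts one epoch per requested trial out of a continuous signal, aligned
#' to the sample of the chosen event. Trials whose window would exceed the
#' recording bounds are dropped and counted in `metadata$nDroppedBounds`.
#'
#' @param sig a [ContinuousSignal-class].
#' @param eventSample integer sample index of the alignment event per
#'   trial (e.g. `array_onset_sample`).
#' @param windowMs epoch window in ms around the event, e.g. c(-300, 300).
#' @param alignment event name stored with the tensor.
#' @param trialIndex optional ids for dimension 1 (defaults to
#'   seq_along(eventSample)).
#' @return an [EpochTensor-class].
#' @export
epochExtract <- function(sig, eventSample, windowMs = c(-300, 300),
                         alignment = "array_onset",
                         trialIndex = seq_along(eventSample)) {
  stopifnot(is(sig, "ContinuousSignal"))
  fs <- sig@fsHz
  rel <- seq(as.integer(round(windowMs[1L] * fs / 1000)),
             as.integer(round(windowMs[2L] * fs / 1000)))
  nS <- ncol(sig@samples)
  ok <- (eventSample + rel[1L]) >= 1L & (eventSample + rel[length(rel)]) <= nS
  dropped <- sum(!ok)
  ev <- eventSample[ok]
  nC <- nrow(sig@samples)
  data <- array(0, dim = c(length(ev), nC, length(rel)))
  idx <- outer(ev, rel, "+")
  for (ch in seq_len(nC))
    data[, ch, ] <- sig@samples[ch, ][idx]
  new("EpochTensor", data = data, timeMs = rel * 1000 / fs,
      alignment = alignment, baselineMs = c(-250, 0), normalized = FALSE,
      trialIndex = as.integer(trialIndex[ok]),
      metadata = list(nDroppedBounds = dropped))
}
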