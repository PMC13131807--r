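# Distractor adaptation: mine T-D-D-D-D trial sequences, average activity
# in early/late response windows with session centering, and test for a
# monotonic decline.

#' Find target-then-distractor adaptation sequences
#'
#' A qualifying sequence is five consecutive trials in one target-feature
#' block: a target-in-RF trial during the predictable context followed by
#' four consecutive distractor-in-RF trials. By default all five trials
#' must be correct and sequences may not overlap (greedy from the left);
#' both choices can be toggled. Sessions with fewer than `minPerSession`
#' sequences are excluded from downstream trend tests.
#'
#' @param trialTable parsed trial table with columns `session_id`, `block`,
#'   `context`, `rf_stimulus` (or `target_position` + `rf_position`),
#'   `correct`.
#' @param minPerSession inclusion threshold per session (default 15).
#' @param requireCorrect require all five trials correct (default TRUE).
#' @param allowOverlap allow overlapping sequence starts (default FALSE:
#'   greedy non-overlapping from the left).
#' @return list with `sequences` (data.frame: session_id, block, and trial
#'   table row indices p1..p5) and `includedSessions` (session ids meeting
#'   the threshold). `sequences` contains only sequences of included
#'   sessions; `counts` gives the per-session totals before thresholding.
#' @export
findSequences <- function(trialTable, minPerSession = 15L,
                          requireCorrect = TRUE, allowOverlap = FALSE) {
  tt <- trialTable
  if (is.null(tt$rf_stimulus))
    tt$rf_stimulus <- labelRfStimulus(tt$target_position, tt$rf_position)
  if (is.null(tt$context)) tt$context <- labelContext(tt$trial_in_block)
  if (is.null(tt$session_id)) tt$session_id <- "session1"
  res <- NULL
  counts <- integer(0)
  for (sid in unique(tt$session_id)) {
    rows <- which(tt$session_id == sid)
    n <- length(rows)
    found <- integer(0)
    i <- 1L
    while (i <= n - 4L) {
      r <- rows[i:(i + 4L)]
      ok <- tt$rf_stimulus[r[1L]] == "target_in_rf" &&
        tt$context[r[1L]] == "predictable" &&
        all(tt$rf_stimulus[r[-1L]] == "distractor_in_rf") &&
        length(unique(tt$block[r])) == 1L &&
        (!requireCorrect || all(tt$correct[r]))
      if (ok) {
        found <- c(found, i)
        i <- i + (if (allowOverlap) 1L else 5L)
      } else i <- i + 1L
    }
    counts[sid] <- length(found)
    if (length(found) > 0L) {
      m <- t(vapply(found, function(i) rows[i:(i + 4L)], integer(5L)))
      res <- rbind(res, data.frame(session_id = sid,
                                   block = tt$block[m[, 1L]],
                                   p1 = m[, 1L], p2 = m[, 2L], p3 = m[, 3L],
                                   p4 = m[, 4L], p5 = m[, 5L]))
    }
  }
  included <- names(counts)[counts >= minPerSession]
  if (is.null(res))
    res <- data.frame(session_id = character(0), block = integer(0),
                      p1 = integer(0), p2 = integer(0), p3 = integer(0),
                      p4 = integer(0), p5 = integer(0))
  list(sequences = res[res$session_id %in% included, , drop = FALSE],
       includedSessions = included, counts = counts)
}

#' Window means across sequence positions for one session
#'
#' For each of the five sequence positions, averages the
#' compartment-averaged normalized signal inside the response window over
#' all sequences of the session. The "early" window is a fixed 58-78 ms
#' span after array onset (the initial feedforward response); the "late"
#' window runs from 78 ms up to 10 ms before each trial's saccade onset
#' and is therefore trial specific. Trials whose late window is empty
#' (saccade before 88 ms) are excluded and counted.
#'
#' @param epochs normalized (and typically smoothed) [EpochTensor-class]
#'   aligned to array onset, covering all sequence trials; `trialIndex`
#'   must give trial-table row ids.
#' @param map a [LaminarMap-class].
#' @param sequences the `sequences` data.frame of [findSequences()]
#'   (rows of one session).
#' @param rtMs reaction times indexed by trial-table row id.
#' @param window "early" or "late".
#' @param earlyMs early window (ms).
#' @param lateStartMs start of the late window (ms).
#' @param lateSaccadeOffsetMs gap between late-window end and saccade.
#' @return list with `means` (3 compartments x 5 positions matrix of raw
#'   means), `nSequences`, `nExcludedLate`.
#' @export
windowMeans <- function(epochs, map, sequences, rtMs,
                        window = c("early", "late"), earlyMs = c(58, 78),
                        lateStartMs = 78, lateSaccadeOffsetMs = 10) {
  window <- match.arg(window)
  comps <- c("upper", "middle", "deep")
  m <- matrix(NA_real_, 3L, 5L, dimnames = list(comps, paste0("p", 1:5)))
  nExcl <- 0L
  trialMat <- lapply(comps, function(cp) {
    if (length(compartmentChannels(map, cp)) == 0L) return(NULL)
    compartmentTrialMatrix(epochs, map, cp)
  })
  names(trialMat) <- comps
  comps <- comps[!vapply(trialMat, is.null, logical(1L))]
  lookup <- match(as.matrix(sequences[, c("p1", "p2", "p3", "p4", "p5")]),
                  epochs@trialIndex)
  dim(lookup) <- c(nrow(sequences), 5L)
  for (p in 1:5) {
    vals <- lapply(comps, function(cp) numeric(0))
    names(vals) <- comps
    for (s in seq_len(nrow(sequences))) {
      ep <- lookup[s, p]
      if (is.na(ep)) next
      trialRow <- sequences[[paste0("p", p)]][s]
      if (window == "early") {
        wi <- windowIndex(epochs@timeMs, earlyMs)
      } else {
        endMs <- rtMs[trialRow] - lateSaccadeOffsetMs
        if (endMs <= lateStartMs) { nExcl <- nExcl + 1L; next }
        wi <- windowIndex(epochs@timeMs, c(lateStartMs, endMs))
      }
      if (length(wi) == 0L) { nExcl <- nExcl + 1L; next }
      for (cp in comps)
        vals[[cp]] <- c(vals[[cp]], mean(trialMat[[cp]][ep, wi]))
    }
    for (cp in comps) m[cp, p] <- mean(vals[[cp]])
  }
  list(means = m, nSequences = nrow(sequences), nExcludedLate = nExcl)
}

#' Center session rows across sequence positions
#'
#' Subtracts each session's mean across all sequence positions from that
#' session's positions, so each centered row sums to zero.
#'
#' @param m sessions x positions matrix.
#' @return centered matrix.
#' @export
centerRows <- function(m) {
  m <- as.matrix(m)
  m - rowMeans(m)
}

#' Adaptation trend test on the distractor positions
#'
#' Page's L test (predicted decreasing trend) on the session-wise centered
#' means of the four distractor positions of T-D-D-D-D sequences. The
#' leading target position is displayed in summaries but excluded from the
#' trend test (k = 4 distractor conditions).
#'
#' @param centeredDistractorMeans sessions x 4 matrix (distractor
#'   positions 1..4, session-centered).
#' @return a [PageLResult-class].
#' @export
adaptationTrend <- function(centeredDistractorMeans) {
  m <- as.matrix(centeredDistractorMeans)
  if (ncol(m) != 4L) stop("expected the 4 distractor positions")
  pageL(m, direction = "decreasing")
}
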