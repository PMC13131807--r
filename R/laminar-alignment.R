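# Functional laminar alignment: locate the initial granular input sink in
# the stimulus-evoked CSD and assign channels to 0.5 mm compartments.

#' Trial-averaged evoked CSD map
#'
#' Averages stimulus-aligned CSD epochs across trials and subtracts each
#' channel's baseline mean, yielding the channels x time evoked map in
#' which the initial granular sink is identified.
#'
#' @param csdEpochs an [EpochTensor-class] of CSD (trials x interior
#'   channels x time), aligned to array onset.
#' @param baselineMs baseline window (ms) subtracted per channel.
#' @return a channels x time matrix with attributes `timeMs` and
#'   `baselineMs`.
#' @export
evokedCsd <- function(csdEpochs, baselineMs = c(-250, 0)) {
  stopifnot(is(csdEpochs, "EpochTensor"))
  if (dim(csdEpochs@data)[1L] < 10L)
    warning("evoked CSD computed from fewer than 10 trials")
  m <- apply(csdEpochs@data, c(2L, 3L), mean)
  bi <- windowIndex(csdEpochs@timeMs, baselineMs)
  m <- m - rowMeans(m[, bi, drop = FALSE])
  attr(m, "timeMs") <- csdEpochs@timeMs
  attr(m, "baselineMs") <- as.numeric(baselineMs)
  m
}

#' Locate the granular input sink marker
#'
#' Visual stimulation first drives a current sink (negative CSD) in the
#' granular input layer. Among channels whose evoked CSD drops below
#' -k x (that channel's baseline SD) inside the search window, contiguous
#' sink regions are formed and the region with the earliest threshold
#' crossing is taken as the initial feedforward input sink. The marker is
#' the bottom of that sink: its deepest (largest-index) channel.
#' A below-threshold excursion only counts as a crossing when it persists
#' for at least `minDurMs` (default 10 ms): evoked sinks last tens of
#' milliseconds whereas chance 3-SD noise excursions are brief, so the
#' persistence requirement keeps the earliest-crossing rule from being
#' won by noise.
#'
#' @param evoked evoked CSD map from [evokedCsd()] (or any channels x time
#'   matrix with a `timeMs` attribute or an explicit `timeMs` argument).
#' @param timeMs time axis in ms; defaults to `attr(evoked, "timeMs")`.
#' @param searchMs sink search window in ms after array onset.
#' @param k detection threshold in baseline SDs (default 3).
#' @param minDurMs minimum duration (ms) the CSD must stay below threshold
#'   for a crossing to count.
#' @param baselineMs baseline window for the per-channel SD.
#' @param channelOffset offset from CSD row to probe channel index (1 for
#'   a plain interior-channel CSD).
#' @return the marker channel index on the original probe.
#'   Throws an error of class `laminarpop_no_sink` when no channel crosses
#'   the threshold, mirroring the exclusion of sessions without a
#'   discernible CSD profile.
#' @export
findGranularMarker <- function(evoked, timeMs = attr(evoked, "timeMs"),
                               searchMs = c(25, 100), k = 3, minDurMs = 10,
                               baselineMs = c(-250, 0), channelOffset = 1L) {
  if (is.null(timeMs)) stop("timeMs is required")
  bi <- windowIndex(timeMs, baselineMs)
  si <- windowIndex(timeMs, searchMs)
  if (length(bi) < 2L || length(si) < 1L)
    stop("baseline or search window not on the time axis")
  dt <- stats::median(diff(timeMs))
  minRun <- max(1L, as.integer(ceiling(minDurMs / dt)))
  bsd <- apply(evoked[, bi, drop = FALSE], 1L, stats::sd)
  thr <- -k * bsd
  # a crossing counts when the excursion starts inside the search window
  # and stays below threshold for at least minRun samples
  crossing <- vapply(seq_len(nrow(evoked)), function(ch) {
    below <- evoked[ch, ] < thr[ch]
    runs <- trueRuns(below)
    if (nrow(runs) == 0L) return(NA_integer_)
    ok <- runs[, 1L] >= si[1L] & runs[, 1L] <= si[length(si)] &
      (runs[, 2L] - runs[, 1L] + 1L) >= minRun
    if (!any(ok)) return(NA_integer_)
    min(runs[ok, 1L])
  }, integer(1L))
  if (all(is.na(crossing)))
    stop(errorCondition("no sink detected: no channel crosses the CSD threshold",
                        class = c("laminarpop_no_sink", "error", "condition")))
  hit <- !is.na(crossing)
  runs <- trueRuns(hit)
  first <- apply(runs, 1L, function(r) min(crossing[r[1L]:r[2L]], na.rm = TRUE))
  region <- runs[which.min(first), ]
  bottomRow <- region[[2L]]
  as.integer(bottomRow + channelOffset)
}

#' Assign channels to laminar compartments
#'
#' Builds the [LaminarMap-class] around the granular sink marker: "middle"
#' (granular, L4) is the 0.5 mm immediately above and including the marker,
#' "upper" (supragranular, L2/3) the next 0.5 mm above, and "deep"
#' (infragranular, L5/6) the 0.5 mm below. With 0.1 mm spacing each
#' compartment holds 5 channels; compartments running off the array edge
#' are truncated and flagged. Whether the marker channel itself belongs to
#' the middle or the deep compartment is a convention; the default includes
#' it in middle, and `includeMarkerInMiddle = FALSE` places it at the top
#' of deep instead.
#'
#' @param markerChannel sink marker channel from [findGranularMarker()].
#' @param nChannels number of probe channels.
#' @param spacingMm contact spacing in mm.
#' @param includeMarkerInMiddle marker membership toggle (default TRUE).
#' @return a [LaminarMap-class].
#' @export
assignCompartments <- function(markerChannel, nChannels, spacingMm = 0.1,
                               includeMarkerInMiddle = TRUE) {
  cpc <- max(1L, as.integer(round(0.5 / spacingMm)))  # channels per 0.5 mm
  m <- as.integer(markerChannel)
  top <- if (includeMarkerInMiddle) m else m - 1L     # deepest middle channel
  ideal <- list(
    middle = (top - cpc + 1L):top,
    upper  = (top - 2L * cpc + 1L):(top - cpc),
    deep   = (top + 1L):(top + cpc))
  lab <- rep("outside", nChannels)
  truncated <- FALSE
  for (nm in names(ideal)) {
    idx <- ideal[[nm]]
    inRange <- idx[idx >= 1L & idx <= nChannels]
    if (length(inRange) < length(idx)) truncated <- TRUE
    lab[inRange] <- nm
  }
  nMiddle <- sum(lab == "middle")
  if (nMiddle < 3L)
    stop(errorCondition(
      sprintf("marker channel %d leaves only %d middle channels; session unusable",
              m, nMiddle),
      class = c("laminarpop_unusable_alignment", "error", "condition")))
  new("LaminarMap", markerChannel = m, compartments = lab,
      spacingMm = spacingMm, truncated = truncated)
}

#' Channel indices of one compartment
#'
#' @param map a [LaminarMap-class].
#' @param compartment one of "upper", "middle", "deep", or "all" for the
#'   union of the three compartments.
#' @return integer channel indices.
#' @export
compartmentChannels <- function(map, compartment) {
  stopifnot(is(map, "LaminarMap"))
  compartment <- match.arg(compartment,
                           c("upper", "middle", "deep", "all"))
  if (compartment == "all")
    return(which(map@compartments != "outside"))
  which(map@compartments == compartment)
}

#' Serialize a laminar map to CSV
#'
#' Writes one row per channel: channel, depth_mm_rel_marker (positive
#' below/deeper than the marker), compartment.
#'
#' @param map a [LaminarMap-class].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeLaminarMap <- function(map, path) {
  stopifnot(is(map, "LaminarMap"))
  ch <- seq_along(map@compartments)
  df <- data.frame(channel = ch,
                   depth_mm_rel_marker = (ch - map@markerChannel) * map@spacingMm,
                   compartment = map@compartments)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
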