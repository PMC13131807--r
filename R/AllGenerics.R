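# Accessor generics and show methods.

#' Extract the sample matrix or array
#' @param x a ContinuousSignal, CsdMatrix or EpochTensor.
#' @return The underlying numeric matrix/array.
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' @describeIn samples channels x time matrix.
#' @export
setMethod("samples", "ContinuousSignal", function(x) x@samples)

#' @describeIn samples interior-channels x time CSD matrix.
#' @export
setMethod("samples", "CsdMatrix", function(x) x@samples)

#' @describeIn samples trials x channels x time array.
#' @export
setMethod("samples", "EpochTensor", function(x) x@data)

#' Sampling rate accessor
#' @param x an object with a sampling rate.
#' @return sampling rate in Hz.
#' @export
setGeneric("fsHz", function(x) standardGeneric("fsHz"))

#' @describeIn fsHz sampling rate of a continuous signal.
#' @export
setMethod("fsHz", "ContinuousSignal", function(x) x@fsHz)

#' @describeIn fsHz sampling rate of a CSD matrix.
#' @export
setMethod("fsHz", "CsdMatrix", function(x) x@fsHz)

#' Time axis accessor
#' @param x an EpochTensor or RunningTestResult.
#' @return time axis in ms.
#' @export
setGeneric("timeMs", function(x) standardGeneric("timeMs"))

#' @describeIn timeMs epoch time axis.
#' @export
setMethod("timeMs", "EpochTensor", function(x) x@timeMs)

#' @describeIn timeMs test time axis.
#' @export
setMethod("timeMs", "RunningTestResult", function(x) x@timeMs)

#' Surviving clusters of a running test
#' @param x a RunningTestResult.
#' @return data.frame with start_ms and end_ms per surviving cluster.
#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))

#' @describeIn clusters cluster table.
#' @export
setMethod("clusters", "RunningTestResult", function(x) x@clusters)

#' Compartment labels of a laminar map
#' @param x a LaminarMap.
#' @return character vector of per-channel compartment labels.
#' @export
setGeneric("compartments", function(x) standardGeneric("compartments"))

#' @describeIn compartments per-channel labels.
#' @export
setMethod("compartments", "LaminarMap", function(x) x@compartments)

#' Granular sink marker channel
#' @param x a LaminarMap.
#' @return integer channel index of the bottom of the initial sink.
#' @export
setGeneric("markerChannel", function(x) standardGeneric("markerChannel"))

#' @describeIn markerChannel marker accessor.
#' @export
setMethod("markerChannel", "LaminarMap", function(x) x@markerChannel)

#' Trial table of a session
#' @param x a LaminarSession.
#' @return the per-trial event data.frame.
#' @export
setGeneric("trials", function(x) standardGeneric("trials"))

#' @describeIn trials trial table accessor.
#' @export
setMethod("trials", "LaminarSession", function(x) x@trials)

setMethod("show", "ContinuousSignal", function(object) {
  d <- dim(object@samples)
  cat(sprintf("ContinuousSignal: %d channels x %d samples @ %g Hz [%s]\n",
              d[1L], d[2L], object@fsHz, object@unit))
})

setMethod("show", "CsdMatrix", function(object) {
  d <- dim(object@samples)
  cat(sprintf(
    "CsdMatrix: %d interior channels x %d samples (sigma = %g S/m)\n",
    d[1L], d[2L], object@sigma))
})

setMethod("show", "EpochTensor", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "EpochTensor: %d trials x %d channels x %d samples, %g..%g ms (%s)%s\n",
    d[1L], d[2L], d[3L], min(object@timeMs), max(object@timeMs),
    object@alignment, if (object@normalized) ", normalized" else ""))
})

setMethod("show", "LaminarMap", function(object) {
  tab <- table(factor(object@compartments,
                      levels = c("upper", "middle", "deep", "outside")))
  cat(sprintf(
    "LaminarMap: marker channel %d; upper %d / middle %d / deep %d channels%s\n",
    object@markerChannel, tab[["upper"]], tab[["middle"]], tab[["deep"]],
    if (object@truncated) " (truncated at array edge)" else ""))
})

setMethod("show", "RunningTestResult", function(object) {
  cat(sprintf(
    "RunningTestResult (%s): %d timepoints, alpha = %g, min cluster %g ms, %d cluster(s)\n",
    object@test, length(object@timeMs), object@alpha, object@minClusterMs,
    nrow(object@clusters)))
  if (nrow(object@clusters) > 0L)
    cat(sprintf("  clusters: %s\n",
                paste(sprintf("[%g, %g] ms", object@clusters$start_ms,
                              object@clusters$end_ms), collapse = ", ")))
})

setMethod("show", "PageLResult", function(object) {
  cat(sprintf(
    "Page's L = %g (n = %d subjects, k = %d conditions, %s trend)\n",
    object@L, object@n, object@k, object@direction))
  cat(sprintf("  mu = %g, sigma^2 = %.4g, z = %.3f\n",
              object@mu, object@sigma2, object@z))
  cat(sprintf("  one-sided p: exact = %s, normal = %.4g (method: %s)\n",
              if (is.na(object@pExact)) "NA" else
                format(object@pExact, digits = 4),
              object@pNormal, object@method))
})

setMethod("show", "AnovaResult", function(object) {
  cat(sprintf("Repeated-measures ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              object@dfEffect, object@dfError, object@statistic, object@p))
})

setMethod("show", "LaminarSession", function(object) {
  cat(sprintf(
    "LaminarSession '%s': %d channels (%g mm), %d trials, signals: %s\n",
    object@id, object@nChannels, object@spacingMm, nrow(object@trials),
    paste(names(object@signals), collapse = ", ")))
})
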