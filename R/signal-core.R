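# Deterministic signal transformations: MUA envelope extraction, current
# source density, zero-phase smoothing and single-trial baseline
# normalization.

#' Extract the multiunit activity (MUA) envelope
#'
#' Estimates aggregate population spiking power from a broadband
#' extracellular recording with the classic filter-rectify-filter chain:
#' 4th-order Butterworth band-pass 500-5000 Hz (the predominant spiking
#' band), full-wave rectification, then a 4th-order Butterworth low-pass at
#' 250 Hz (half the original high-pass edge). All filtering is zero-phase
#' (applied forward and backward over reflection-padded data) so the
#' envelope carries no systematic latency shift, which matters because
#' selection-time estimates are read off this signal. The 250 Hz low-pass
#' doubles as the anti-alias filter for the optional integer-factor
#' decimation to the analysis rate.
#'
#' @param raw a [ContinuousSignal-class] sampled at >= 12 kHz (the 5 kHz
#'   band edge must be comfortably below Nyquist).
#' @param decimateToHz target analysis rate; the signal is decimated by
#'   round(fsHz/decimateToHz) so the realized rate can differ slightly from
#'   the target when the ratio is not an integer (e.g. 24414 Hz / 24 =
#'   1017.25 Hz). Use NULL to keep the full rate.
#' @param bandHz spike-band edges in Hz.
#' @param lowpassHz rectified-signal low-pass edge in Hz.
#' @return a [ContinuousSignal-class] envelope (unit "a.u."), nonnegative
#'   in the mean.
#' @export
extractMuaEnvelope <- function(raw, decimateToHz = 1000,
                               bandHz = c(500, 5000), lowpassHz = 250) {
  stopifnot(is(raw, "ContinuousSignal"))
  fs <- raw@fsHz
  if (fs < 12000)
    stop("sampling rate ", fs, " Hz is too low for the ", bandHz[2L],
         " Hz band edge; need at least 12 kHz")
  x <- raw@samples
  nyq <- fs / 2
  bp <- signal::butter(4, bandHz / nyq, type = "pass")
  lp <- signal::butter(4, lowpassHz / nyq, type = "low")
  pad <- min(ncol(x) - 1L, as.integer(round(0.05 * fs)))
  spike <- filtfiltRows(x, bp, pad)
  env <- filtfiltRows(abs(spike), lp, pad)
  outFs <- fs
  if (!is.null(decimateToHz)) {
    fac <- max(1L, as.integer(round(fs / decimateToHz)))
    if (fac > 1L) {
      env <- env[, seq(1L, ncol(env), by = fac), drop = FALSE]
      outFs <- fs / fac
    }
  }
  ContinuousSignal(env, outFs, raw@spacingMm, unit = "a.u.")
}

#' Band-pass filter a continuous signal
#'
#' Zero-phase 4th-order Butterworth band-pass, used to isolate the
#' evoked local field potential (default 1-100 Hz) before CSD computation.
#'
#' @param x a [ContinuousSignal-class].
#' @param bandHz band edges in Hz.
#' @return a filtered [ContinuousSignal-class].
#' @export
filterBand <- function(x, bandHz = c(1, 100)) {
  stopifnot(is(x, "ContinuousSignal"))
  nyq <- x@fsHz / 2
  if (bandHz[2L] >= nyq) stop("band edge at or above Nyquist")
  bp <- signal::butter(4, bandHz / nyq, type = "pass")
  pad <- min(ncol(x@samples) - 1L,
             as.integer(round(2 * x@fsHz / bandHz[1L])))
  ContinuousSignal(filtfiltRows(x@samples, bp, pad), x@fsHz, x@spacingMm,
                   unit = x@unit)
}

#' Current source density by the second spatial derivative
#'
#' For each interior contact d of a uniformly spaced laminar probe,
#' CSD(t, d) = -sigma * (x(t, d - z) + x(t, d + z) - 2 x(t, d)) / z^2,
#' where z is the inter-electrode distance and sigma the cortical
#' conductivity. Under this convention current sinks (net inward,
#' depolarizing current) are negative; note that published color maps often
#' invert this sign for display. The two outermost channels, which lack a
#' neighbor, are dropped.
#'
#' @param lfp a [ContinuousSignal-class] with at least 3 channels; the
#'   caller is expected to have band-limited it to the LFP range (see
#'   [filterBand()]).
#' @param sigma cortical conductivity in S/m (default 0.4).
#' @return a [CsdMatrix-class] with (channels - 2) rows; row i corresponds
#'   to input channel i + 1. Units: uV * S / (m * mm^2) when the input is in
#'   uV and spacing in mm.
#' @export
computeCsd <- function(lfp, sigma = 0.4) {
  stopifnot(is(lfp, "ContinuousSignal"))
  x <- lfp@samples
  n <- nrow(x)
  if (n < 3L) stop("CSD needs at least 3 channels")
  z <- lfp@spacingMm
  d2 <- x[1:(n - 2L), , drop = FALSE] + x[3:n, , drop = FALSE] -
    2 * x[2:(n - 1L), , drop = FALSE]
  new("CsdMatrix", samples = -sigma * d2 / z^2, sigma = sigma,
      channelOffset = 1L, fsHz = lfp@fsHz, spacingMm = z)
}

#' Bidirectional moving-average smoothing
#'
#' A boxcar of `windowMs` applied forward and then backward in time
#' (zero-phase; the effective kernel is triangular with unit DC gain).
#' Edges are handled by reflection. A centered single-pass boxcar is
#' available as an alternative interpretation of a "bidirectional" moving
#' average.
#'
#' @param x a numeric vector, a channels x time matrix, a
#'   [ContinuousSignal-class] or an [EpochTensor-class].
#' @param windowMs window length in ms (default 15).
#' @param fsHz sampling rate; required for vectors and matrices, taken from
#'   the object otherwise.
#' @param mode "bidirectional" (forward-then-backward, the default) or
#'   "centered" (single centered pass).
#' @return an object of the same shape/class as `x`.
#' @export
smoothBidirectional <- function(x, windowMs = 15, fsHz = NULL,
                                mode = c("bidirectional", "centered")) {
  mode <- match.arg(mode)
  if (is(x, "ContinuousSignal")) {
    out <- smoothRows(x@samples, windowMs, x@fsHz, mode)
    return(ContinuousSignal(out, x@fsHz, x@spacingMm, x@unit))
  }
  if (is(x, "EpochTensor")) {
    fs <- epochFs(x)
    d <- dim(x@data)
    flat <- matrix(x@data, d[1L] * d[2L], d[3L])
    sm <- smoothRows(flat, windowMs, fs, mode)
    out <- x
    out@data <- array(sm, d)
    return(out)
  }
  if (is.null(fsHz)) stop("fsHz is required for plain vectors/matrices")
  if (is.matrix(x)) return(smoothRows(x, windowMs, fsHz, mode))
  drop(smoothRows(matrix(x, 1L), windowMs, fsHz, mode))
}

# causal (trailing) moving average along rows via cumulative sums;
# the first w-1 columns are only valid after padding
causalMeanRows <- function(x, w) {
  cs <- x
  for (j in 2:ncol(x)) cs[, j] <- cs[, j - 1L] + x[, j]
  out <- x
  out[, w:ncol(x)] <- (cs[, w:ncol(x), drop = FALSE] -
    cbind(0, cs[, 1:(ncol(x) - w), drop = FALSE])) / w
  out[, 1:(w - 1L)] <- NA_real_
  out
}

# boxcar smoothing of the rows of a matrix
smoothRows <- function(x, windowMs, fsHz, mode) {
  w <- max(1L, as.integer(round(windowMs * fsHz / 1000)))
  if (w >= ncol(x)) stop("smoothing window longer than the series")
  if (w == 1L) return(x)
  pad <- 2L * w
  xp <- reflectPad(x, pad)
  if (mode == "centered") {
    f <- causalMeanRows(xp, w)
    half <- w %/% 2L
    f <- cbind(f[, (half + 1L):ncol(f), drop = FALSE],
               matrix(NA_real_, nrow(f), half))   # re-center the kernel
  } else {
    f <- causalMeanRows(xp, w)                         # forward pass
    f <- f[, ncol(f):1L, drop = FALSE]
    f <- causalMeanRows(f, w)                          # backward pass
    f <- f[, ncol(f):1L, drop = FALSE]
  }
  f[, (pad + 1L):(pad + ncol(x)), drop = FALSE]
}

# sampling rate implied by an epoch time axis
epochFs <- function(epochs) {
  dt <- diff(epochs@timeMs)
  1000 / stats::median(dt)
}

#' Single-trial baseline z-normalization
#'
#' For every trial x channel, each sample is divided by the standard
#' deviation of the pre-stimulus baseline window and the (post-division)
#' baseline mean is then subtracted, so the baseline of every trial x
#' channel has mean 0 and SD 1. Trials in which any channel has zero
#' baseline variance cannot be scaled and are excluded; the exclusion count
#' is stored in `metadata$nExcludedZeroVar` of the result.
#'
#' @param epochs an unnormalized [EpochTensor-class] whose time axis
#'   contains the baseline window.
#' @param baselineMs closed baseline interval in ms (default c(-250, 0)).
#' @return a normalized [EpochTensor-class] (excluded trials removed).
#' @export
zNormalize <- function(epochs, baselineMs = c(-250, 0)) {
  stopifnot(is(epochs, "EpochTensor"))
  if (epochs@normalized) stop("epochs are already normalized")
  bi <- windowIndex(epochs@timeMs, baselineMs)
  if (length(bi) < 2L) stop("baseline window not on the epoch time axis")
  d <- dim(epochs@data)
  base <- epochs@data[, , bi, drop = FALSE]
  nB <- length(bi)
  bm <- rowMeans(base, dims = 2L)
  bs <- (rowSums(base^2, dims = 2L) - nB * bm^2) / (nB - 1L)
  bs[bs < 0] <- 0
  bs <- sqrt(bs)
  bad <- apply(bs == 0, 1L, any)
  keep <- which(!bad)
  if (length(keep) == 0L) stop("all trials have zero-variance baselines")
  sc <- array(bs[keep, , drop = FALSE], dim = c(length(keep), d[2L], d[3L]))
  ctr <- array(bm[keep, , drop = FALSE], dim = c(length(keep), d[2L], d[3L]))
  out <- epochs
  out@data <- (epochs@data[keep, , , drop = FALSE] - ctr) / sc
  out@trialIndex <- epochs@trialIndex[keep]
  out@baselineMs <- as.numeric(baselineMs)
  out@normalized <- TRUE
  out@metadata$nExcludedZeroVar <- sum(bad)
  out
}
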