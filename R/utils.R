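# Internal numerical helpers.

# Run f with a private RNG stream seeded by `seed`; the caller's
# .Random.seed is untouched.
withSeed <- function(seed, f) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  f()
}

# Reflection-pad each row of a channels x time matrix by `pad` samples on
# both sides. Reflection (not zero padding) keeps zero-phase filters free of
# onset transients inside the pre-stimulus baseline.
reflectPad <- function(x, pad) {
  n <- ncol(x)
  if (pad >= n) stop("padding longer than the series")
  left <- x[, pad:1, drop = FALSE]
  right <- x[, n:(n - pad + 1L), drop = FALSE]
  cbind(left, x, right)
}

# Zero-phase (forward-backward) IIR filtering of each row with reflection
# padding. filt is a signal::Arma/butter filter object.
filtfiltRows <- function(x, filt, pad) {
  xp <- reflectPad(x, pad)
  out <- matrix(0, nrow(x), ncol(x))
  keep <- (pad + 1L):(pad + ncol(x))
  for (i in seq_len(nrow(x)))
    out[i, ] <- signal::filtfilt(filt, xp[i, ])[keep]
  out
}

# Contiguous runs of TRUE in a logical vector -> matrix of (start, end)
# indices.
trueRuns <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

# Index range of a closed ms window on a time axis.
windowIndex <- function(timeMs, windowMs) {
  which(timeMs >= windowMs[1L] & timeMs <= windowMs[2L])
}

# All permutations of 1..k as a k! x k matrix (k <= 8 in practice).
permutationsOf <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutationsOf(k - 1L)
  out <- matrix(0L, nrow(sub) * k, k)
  row <- 1L
  for (i in seq_len(k)) {
    block <- cbind(i, ifelse(sub >= i, sub + 1L, sub))
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  out
}
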