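# Page's L trend test with an exact convolution null and the normal
# approximation.

#' Exact null distribution of Page's L
#'
#' Under the null, each subject's ranks are an independent uniform
#' permutation of 1..k. The single-subject statistic sum_j j * rank_j is
#' enumerated over all k! permutations and the n-subject distribution is
#' obtained by convolving that distribution n times. Feasible for k <= 8.
#'
#' @param n number of subjects.
#' @param k number of ordered conditions.
#' @return data.frame with columns `L` (integer support) and `prob`.
#' @export
pageLNullDistribution <- function(n, k) {
  if (k > 8L) stop("exact null restricted to k <= 8")
  pm <- permutationsOf(as.integer(k))
  L1 <- as.vector(pm %*% seq_len(k))
  maxL1 <- k * (k + 1) * (2 * k + 1) / 6
  pmf <- tabulate(L1, nbins = maxL1) / nrow(pm)   # index = L1 value
  dens <- pmf
  if (n > 1L) for (i in 2:n) {
    out <- numeric(length(dens) + length(pmf) - 1L)
    nz <- which(pmf > 0)
    for (j in nz) out[j + seq_along(dens) - 1L] <-
        out[j + seq_along(dens) - 1L] + pmf[j] * dens
    dens <- out
  }
  L <- seq_along(dens) + (n - 1L)   # each convolution shifts the index by -1
  keep <- dens > 0
  data.frame(L = L[keep], prob = dens[keep])
}

#' Page's L trend test
#'
#' Rank-based test for a predicted monotone ordering of k conditions
#' across n independent subjects. Each subject's row is ranked 1..k
#' (average ranks on ties); for a predicted decreasing trend the column
#' order is reversed before scoring, so a decline in the data maps to the
#' upper tail. The statistic is L = sum_j j * R_j with R_j the rank sum of
#' (reordered) condition j. Two one-sided upper-tail p-values are
#' computed: `pExact` from the exact convolution null (see
#' [pageLNullDistribution()]; skipped for k > 8) and `pNormal` from the
#' large-sample normal approximation z = (L - mu)/sigma with
#' mu = n k (k+1)^2 / 4 and sigma^2 = n k^2 (k+1) (k^2 - 1) / 144. The
#' exact null assumes tie-free rankings; with tied data it is an
#' approximation, as is the normal curve.
#'
#' @param data subjects x conditions matrix, condition columns in their
#'   predicted order; no missing cells.
#' @param direction predicted trend across the columns: "decreasing"
#'   (default; e.g. response attenuation with stimulus repetition) or
#'   "increasing".
#' @return a [PageLResult-class].
#' @export
pageL <- function(data, direction = c("decreasing", "increasing")) {
  direction <- match.arg(direction)
  data <- as.matrix(data)
  if (any(!is.finite(data))) stop("missing cells are not allowed")
  n <- nrow(data); k <- ncol(data)
  if (k < 3L) stop("Page's test needs at least 3 ordered conditions")
  if (direction == "decreasing") data <- data[, k:1L, drop = FALSE]
  ranks <- t(apply(data, 1L, rank))
  L <- sum(colSums(ranks) * seq_len(k))
  mu <- n * k * (k + 1)^2 / 4
  sigma2 <- n * k^2 * (k + 1) * (k^2 - 1) / 144
  z <- (L - mu) / sqrt(sigma2)
  pNormal <- stats::pnorm(z, lower.tail = FALSE)
  if (k <= 8L) {
    null <- pageLNullDistribution(n, k)
    pExact <- sum(null$prob[null$L >= L])
    method <- "exact"
  } else {
    pExact <- NA_real_
    method <- "normal"
  }
  new("PageLResult", L = L, n = as.integer(n), k = as.integer(k), mu = mu,
      sigma2 = sigma2, z = z, pNormal = pNormal, pExact = pExact,
      method = method, direction = direction)
}
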