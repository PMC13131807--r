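# Running nonparametric tests with minimum-cluster thresholding, plus a
# one-way repeated-measures ANOVA and a paired t utility.

# Per-timepoint two-group Wilcoxon rank-sum z (normal approximation with
# tie correction). Returns list(z, p) over columns of A (nA x T) vs B.
ranksumSeries <- function(A, B) {
  nA <- nrow(A); nB <- nrow(B); N <- nA + nB
  zs <- vapply(seq_len(ncol(A)), function(t) {
    v <- c(A[, t], B[, t])
    r <- rank(v)
    W <- sum(r[seq_len(nA)])
    mu <- nA * (N + 1) / 2
    lens <- rle(sort(v))$lengths
    tie <- sum(lens^3 - lens)
    v2 <- nA * nB / 12 * ((N + 1) - tie / (N * (N - 1)))
    if (v2 <= 0) 0 else (W - mu) / sqrt(v2)
  }, numeric(1L))
  list(z = zs, p = 2 * stats::pnorm(-abs(zs)))
}

# Per-timepoint Kruskal-Wallis H with tie correction; chi-square p with
# k - 1 df. groups: list of n_i x T matrices.
kruskalSeries <- function(groups) {
  k <- length(groups)
  ns <- vapply(groups, nrow, integer(1L))
  N <- sum(ns)
  Tn <- ncol(groups[[1L]])
  idx <- rep(seq_len(k), ns)
  H <- vapply(seq_len(Tn), function(t) {
    v <- unlist(lapply(groups, function(g) g[, t]), use.names = FALSE)
    r <- rank(v)
    rbar <- tapply(r, idx, mean)
    h <- 12 / (N * (N + 1)) * sum(ns * (rbar - (N + 1) / 2)^2)
    lens <- rle(sort(v))$lengths
    C <- 1 - sum(lens^3 - lens) / (N^3 - N)
    if (C <= 0) 0 else h / C
  }, numeric(1L))
  list(H = H, p = stats::pchisq(H, df = k - 1, lower.tail = FALSE))
}

# Build the surviving-cluster table from a pointwise significance mask.
# signSeries restricts clusters to runs of consistent sign (all-zero for
# the k-group test, where any significant run qualifies).
clusterize <- function(timeMs, sig, signSeries, minClusterMs) {
  dt <- stats::median(diff(timeMs))
  minLen <- as.integer(ceiling(minClusterMs / dt))
  mask <- rep(FALSE, length(sig))
  cl <- data.frame(start_ms = numeric(0), end_ms = numeric(0),
                   sign = numeric(0))
  for (s in if (all(signSeries == 0)) 0 else c(1, -1)) {
    cand <- if (s == 0) sig else sig & (sign(signSeries) == s)
    if (!any(cand)) next
    runs <- trueRuns(cand)
    for (i in seq_len(nrow(runs))) {
      a <- runs[i, 1L]; b <- runs[i, 2L]
      if (b - a + 1L >= minLen) {
        mask[a:b] <- TRUE
        cl <- rbind(cl, data.frame(start_ms = timeMs[a], end_ms = timeMs[b],
                                   sign = s))
      }
    }
  }
  cl <- cl[order(cl$start_ms), , drop = FALSE]
  rownames(cl) <- NULL
  list(mask = mask, clusters = cl)
}

#' Running Wilcoxon rank-sum test with cluster thresholding
#'
#' At every timepoint, a two-sided Wilcoxon rank-sum test (normal
#' approximation with tie correction) compares the two groups. Timepoints
#' with p below `alpha` and a consistent direction form candidate
#' clusters; clusters shorter than `minClusterMs` are discarded. The
#' minimum length is converted to samples by rounding up at the analysis
#' rate. Restricting significant samples to contiguous runs of at least
#' 25 ms controls spurious brief detections in the running test.
#'
#' @param groupA,groupB observations x time matrices on a common time axis
#'   (>= 2 observations each).
#' @param timeMs common time axis in ms.
#' @param alpha pointwise significance level (default 0.01).
#' @param minClusterMs minimum cluster duration in ms (default 25).
#' @param direction "any" keeps clusters of either sign; "greater" keeps
#'   only clusters where group A exceeds group B; "less" the reverse.
#' @return a [RunningTestResult-class].
#' @export
runningRanksumCluster <- function(groupA, groupB, timeMs, alpha = 0.01,
                                  minClusterMs = 25,
                                  direction = c("any", "greater", "less")) {
  direction <- match.arg(direction)
  groupA <- as.matrix(groupA); groupB <- as.matrix(groupB)
  if (nrow(groupA) < 2L || nrow(groupB) < 2L)
    stop("both groups need at least 2 observations")
  if (ncol(groupA) != ncol(groupB) || ncol(groupA) != length(timeMs))
    stop("groups must share the time axis")
  rs <- ranksumSeries(groupA, groupB)
  sig <- rs$p < alpha
  if (direction == "greater") sig <- sig & rs$z > 0
  if (direction == "less") sig <- sig & rs$z < 0
  cz <- clusterize(timeMs, sig, rs$z, minClusterMs)
  new("RunningTestResult", timeMs = as.numeric(timeMs), statistic = rs$z,
      p = rs$p, sign = sign(rs$z), mask = cz$mask, clusters = cz$clusters,
      alpha = alpha, minClusterMs = minClusterMs, test = "ranksum")
}

#' Running Kruskal-Wallis test with cluster thresholding
#'
#' The k-group analogue of [runningRanksumCluster()]: a tie-corrected
#' Kruskal-Wallis test at every timepoint, with significant samples kept
#' only when they form runs of at least `minClusterMs`. There is no
#' direction sign for k groups.
#'
#' @param groups list of observations x time matrices (>= 2 groups, >= 2
#'   observations each) on a common time axis.
#' @param timeMs common time axis in ms.
#' @param alpha pointwise significance level (default 0.01).
#' @param minClusterMs minimum cluster duration in ms (default 25).
#' @return a [RunningTestResult-class].
#' @export
runningKruskalCluster <- function(groups, timeMs, alpha = 0.01,
                                  minClusterMs = 25) {
  groups <- lapply(groups, as.matrix)
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(vapply(groups, nrow, integer(1L)) < 2L))
    stop("every group needs at least 2 observations")
  if (any(vapply(groups, ncol, integer(1L)) != length(timeMs)))
    stop("groups must share the time axis")
  kw <- kruskalSeries(groups)
  sig <- kw$p < alpha
  cz <- clusterize(timeMs, sig, rep(0, length(timeMs)), minClusterMs)
  new("RunningTestResult", timeMs = as.numeric(timeMs), statistic = kw$H,
      p = kw$p, sign = rep(0, length(timeMs)), mask = cz$mask,
      clusters = cz$clusters, alpha = alpha, minClusterMs = minClusterMs,
      test = "kruskal")
}

#' Onset of the earliest surviving cluster
#'
#' @param result a [RunningTestResult-class].
#' @param requireSign "any", "positive" (group A above group B) or
#'   "negative"; clusters of the wrong sign are ignored.
#' @return onset in ms (start of the earliest qualifying cluster), or NA
#'   when no cluster qualifies.
#' @export
clusterOnset <- function(result,
                         requireSign = c("any", "positive", "negative")) {
  requireSign <- match.arg(requireSign)
  cl <- result@clusters
  if (requireSign == "positive") cl <- cl[cl$sign > 0, , drop = FALSE]
  if (requireSign == "negative") cl <- cl[cl$sign < 0, , drop = FALSE]
  if (nrow(cl) == 0L) return(NA_real_)
  min(cl$start_ms)
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject one-way ANOVA by direct partitioning of sums of squares:
#' SS_effect (conditions), SS_subject, and SS_error = SS_total -
#' SS_effect - SS_subject; F = MS_effect / MS_error with (k - 1) and
#' (n - 1)(k - 1) degrees of freedom.
#'
#' @param data complete subjects x conditions matrix.
#' @return an [AnovaResult-class].
#' @export
rmAnova <- function(data) {
  data <- as.matrix(data)
  if (any(!is.finite(data))) stop("missing cells are not allowed")
  n <- nrow(data); k <- ncol(data)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 conditions")
  grand <- mean(data)
  ssEffect <- n * sum((colMeans(data) - grand)^2)
  ssSubject <- k * sum((rowMeans(data) - grand)^2)
  ssTotal <- sum((data - grand)^2)
  ssError <- ssTotal - ssEffect - ssSubject
  dfE <- k - 1L
  dfErr <- (n - 1L) * (k - 1L)
  Fv <- (ssEffect / dfE) / (ssError / dfErr)
  new("AnovaResult", statistic = Fv, dfEffect = as.integer(dfE),
      dfError = as.integer(dfErr),
      p = stats::pf(Fv, dfE, dfErr, lower.tail = FALSE),
      ss = c(effect = ssEffect, subject = ssSubject, error = ssError))
}

#' Paired t-test utility
#'
#' Thin wrapper around [stats::t.test()] with `paired = TRUE`; provided
#' for descriptive cross-context comparisons of selection times.
#'
#' @param x,y paired samples.
#' @param ... passed to [stats::t.test()].
#' @return an object of class "htest".
#' @export
pairedT <- function(x, y, ...) stats::t.test(x, y, paired = TRUE, ...)
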