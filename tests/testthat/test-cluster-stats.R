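# Running cluster tests, Page's L, repeated-measures ANOVA.

smoothNull <- function(n, Tn, seed) {
  withr::with_seed(seed, smoothBidirectional(matrix(rnorm(n * Tn), n), 15,
                                             fsHz = 1000))
}

test_that("identical groups yield zero clusters", {
  A <- matrix(rep(1:10, 50), 10)
  res <- runningRanksumCluster(A, A, seq_len(50))
  expect_equal(nrow(clusters(res)), 0)
  expect_false(any(res@mask))
  kres <- runningKruskalCluster(list(A, A, A), seq_len(50))
  expect_equal(nrow(clusters(kres)), 0)
})

test_that("a sustained offset produces one cluster with the right onset", {
  tMs <- 0:299
  A <- smoothNull(20, 300, 1)
  B <- smoothNull(20, 300, 2)
  B[, tMs >= 100] <- B[, tMs >= 100] + 5     # high SNR step at 100 ms
  res <- runningRanksumCluster(B, A, tMs, direction = "greater")
  expect_gte(nrow(clusters(res)), 1)
  # onset within the smoothing half-width + 2 ms of the step
  expect_lte(abs(clusterOnset(res, "positive") - 100), 17)
  expect_true(all(clusters(res)$sign == 1))
  # 4 staircase groups diverge from the same time
  G <- lapply(0:3, function(k) {
    g <- smoothNull(12, 300, 10 + k)
    g[, tMs >= 100] <- g[, tMs >= 100] + 5 * k
    g
  })
  kres <- runningKruskalCluster(G, tMs)
  expect_lte(abs(clusterOnset(kres) - 100), 17)
})

test_that("pointwise p-values match the reference implementations", {
  withr::with_seed(3, {
    A <- matrix(rnorm(12 * 8), 12)
    B <- matrix(rnorm(15 * 8), 15)
    B[2, ] <- A[5, ]                          # inject ties
  })
  res <- runningRanksumCluster(A, B, 1:8, alpha = 0.5, minClusterMs = 1)
  ref <- vapply(1:8, function(t)
    stats::wilcox.test(A[, t], B[, t], exact = FALSE,
                       correct = FALSE)$p.value, numeric(1))
  expect_equal(res@p, ref, tolerance = 1e-12)
  G <- list(A, B, matrix(rnorm(10 * 8), 10))
  kres <- runningKruskalCluster(G, 1:8, alpha = 0.5, minClusterMs = 1)
  refk <- vapply(1:8, function(t)
    stats::kruskal.test(lapply(G, function(g) g[, t]))$p.value, numeric(1))
  expect_equal(kres@p, refk, tolerance = 1e-12)
})

test_that("two-group Kruskal-Wallis matches the rank-sum cluster membership", {
  tMs <- 0:199
  A <- smoothNull(10, 200, 4)
  B <- smoothNull(10, 200, 5)
  B[, tMs >= 80] <- B[, tMs >= 80] + 3
  rs <- runningRanksumCluster(A, B, tMs, alpha = 0.01)
  kw <- runningKruskalCluster(list(A, B), tMs, alpha = 0.01)
  # H = z^2 without ties, so the pointwise decisions coincide
  expect_equal(kw@mask, rs@mask)
})

test_that("running tests are invariant to monotone transforms", {
  tMs <- 0:99
  A <- abs(smoothNull(8, 100, 6)) + 1
  B <- abs(smoothNull(8, 100, 7)) + 1
  r1 <- runningRanksumCluster(A, B, tMs, alpha = 0.2, minClusterMs = 5)
  r2 <- runningRanksumCluster(exp(2 * A), exp(2 * B), tMs, alpha = 0.2,
                              minClusterMs = 5)
  expect_equal(r1@p, r2@p)
  expect_equal(clusters(r1), clusters(r2))
})

test_that("lowering alpha never creates a new cluster", {
  tMs <- 0:199
  for (sd in 1:10) {
    A <- smoothNull(10, 200, 100 + sd)
    B <- smoothNull(10, 200, 200 + sd)
    B[, tMs >= 120] <- B[, tMs >= 120] + 1.2
    loose <- runningRanksumCluster(A, B, tMs, alpha = 0.05)
    strict <- runningRanksumCluster(A, B, tMs, alpha = 0.01)
    expect_true(all(!strict@mask | loose@mask))
  }
})

test_that("cluster onset honors direction and ordering", {
  res <- new("RunningTestResult", timeMs = 0:299, statistic = numeric(300),
             p = rep(1, 300), sign = numeric(300), mask = rep(FALSE, 300),
             clusters = data.frame(start_ms = c(80, 140),
                                   end_ms = c(110, 170), sign = c(1, -1)),
             alpha = 0.01, minClusterMs = 25, test = "ranksum")
  expect_equal(clusterOnset(res), 80)
  expect_equal(clusterOnset(res, "negative"), 140)
  empty <- new("RunningTestResult", timeMs = 0:9, statistic = numeric(10),
               p = rep(1, 10), sign = numeric(10), mask = rep(FALSE, 10),
               clusters = data.frame(start_ms = numeric(0),
                                     end_ms = numeric(0),
                                     sign = numeric(0)),
               alpha = 0.01, minClusterMs = 25, test = "ranksum")
  expect_true(is.na(clusterOnset(empty)))
})

test_that("Page's L null distribution has the stated moments and range", {
  d <- pageLNullDistribution(8, 4)
  expect_equal(sum(d$prob), 1, tolerance = 1e-12)
  expect_equal(sum(d$L * d$prob), 200)              # mu = n k (k+1)^2 / 4
  expect_equal(range(d$L), c(160, 240))
  expect_equal(sum(d$L^2 * d$prob) - 200^2, 8 * 16 * 5 * 15 / 144,
               tolerance = 1e-9)
})

test_that("Page's L scores perfect orderings at the extremes", {
  perfect <- matrix(rep(4:1, 8), 8, byrow = TRUE)    # decreasing rows
  res <- pageL(perfect, "decreasing")
  expect_equal(res@L, 240)                           # n * sum(j^2)
  expect_equal(res@pExact, (1 / 24)^8, tolerance = 1e-12)
  # reversing the predicted direction maps L to 2 mu - L on tie-free data
  rev <- pageL(perfect, "increasing")
  expect_equal(rev@L, 2 * 200 - 240)
})

test_that("exact p agrees with a small-case enumeration oracle", {
  # n = 2, k = 3: enumerate all 36 rank-matrix pairs directly
  pm <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
              c(3, 2, 1))
  L2 <- as.vector(outer(pm %*% 1:3, pm %*% 1:3, "+"))
  for (L in 18:28) {
    res <- pageL(rbind(c(3, 2, 1), c(3, 2, 1)), "decreasing")
    d <- pageLNullDistribution(2, 3)
    expect_equal(sum(d$prob[d$L >= L]), mean(L2 >= L), tolerance = 1e-12)
  }
})

test_that("exact p matches Monte-Carlo draws from the permutation null", {
  pm <- laminarpop:::permutationsOf(4L)
  L1 <- as.vector(pm %*% 1:4)
  draws <- withr::with_seed(9, matrix(sample(L1, 8 * 1e5, replace = TRUE), 8))
  Lmc <- colSums(draws)
  d <- pageLNullDistribution(8, 4)
  for (L in c(180, 200, 210, 221, 230)) {
    pe <- sum(d$prob[d$L >= L])
    pm_ <- mean(Lmc >= L)
    se <- sqrt(pe * (1 - pe) / 1e5)
    expect_lte(abs(pe - pm_), 3 * max(se, 1e-5))
  }
  # E[L] under the permutation null equals mu
  expect_lte(abs(mean(Lmc) - 200), 3 * sd(Lmc) / sqrt(1e5))
})

test_that("ties get average ranks and k > 8 falls back to the normal p", {
  res <- pageL(rbind(c(2, 1, 1), c(3, 2, 1)), "decreasing")
  expect_equal(res@method, "exact")
  big <- matrix(rnorm(2 * 9), 2)
  res9 <- pageL(big)
  expect_equal(res9@method, "normal")
  expect_true(is.na(res9@pExact))
  expect_error(pageL(matrix(1, 2, 2)), "at least 3")
})

test_that("repeated-measures ANOVA partitions sums of squares correctly", {
  m <- rbind(c(1, 2, 3), c(2, 3, 5), c(0, 1, 2))
  res <- rmAnova(m)
  # independent oracle: aov with an explicit subject error stratum
  df <- data.frame(y = as.vector(m),
                   subj = factor(rep(1:3, 3)),
                   cond = factor(rep(1:3, each = 3)))
  fit <- summary(stats::aov(y ~ cond + Error(subj), data = df))
  tab <- fit[["Error: Within"]][[1]]
  expect_equal(res@statistic, tab["cond", "F value"], tolerance = 1e-10)
  expect_equal(res@p, tab["cond", "Pr(>F)"], tolerance = 1e-10)
  expect_equal(unname(res@ss["error"]), tab["Residuals", "Sum Sq"],
               tolerance = 1e-10)
  # identical condition means -> F = 0
  flat <- rbind(c(1, 1, 1), c(5, 5, 5), c(2, 2, 2))
  expect_equal(rmAnova(flat)@statistic, 0)
  expect_error(rmAnova(rbind(c(1, NA), c(2, 3))), "missing")
})

test_that("the ANOVA p approximates a within-subject permutation null", {
  m <- withr::with_seed(13, matrix(rnorm(15), 5, 3) +
                          matrix(rep(c(0, 0.5, 1.4), each = 5), 5))
  obs <- rmAnova(m)
  perm <- withr::with_seed(14, replicate(800, {
    shuffled <- t(apply(m, 1, sample))
    rmAnova(shuffled)@statistic
  }))
  pPerm <- mean(perm >= obs@statistic)
  se <- sqrt(max(pPerm * (1 - pPerm), 1e-3) / 800)
  expect_lte(abs(pPerm - obs@p), 4 * se + 0.02)
})
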