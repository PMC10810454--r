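test_that("rank-sum statistic and p behave at the extremes", {
  res <- mannWhitneyTest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)           # complete separation
  expect_equal(res$statistic_label, "W")
  same <- mannWhitneyTest(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gt(same$p_value, 0.9)
  expect_error(mannWhitneyTest(c(2, 2), c(2, 2)), "tied")
})

test_that("rank-sum p agrees with full permutation enumeration at n = 8+8", {
  set.seed(41)
  a <- rnorm(8); b <- rnorm(8, 0.5)
  res <- mannWhitneyTest(a, b)
  pooled <- c(a, b)
  rk <- rank(pooled)
  uOf <- function(idx) sum(rk[idx]) - 8 * 9 / 2
  uAll <- combn(16, 8, uOf)
  uObs <- uOf(1:8)
  pOracle <- if (uObs > 32) 2 * mean(uAll >= uObs) else 2 * mean(uAll <= uObs)
  pOracle <- min(1, pOracle)
  expect_equal(res$p_value, pOracle, tolerance = 5e-4)
  expect_equal(res$statistic, uObs)
})

test_that("signed-rank statistic at the extremes and under symmetry", {
  res <- wilcoxonSignedRankTest(c(0.3, 1.1, 0.5, 2, 0.9))
  expect_equal(res$statistic, 15)          # all positive, n = 5
  sym <- wilcoxonSignedRankTest(c(-2, 2, -1, 1, -3, 3))
  expect_equal(sym$statistic, 6 * 7 / 4)   # V at its null expectation
  expect_gt(sym$p_value, 0.9)
  expect_error(wilcoxonSignedRankTest(c(0, 0)), "all differences are zero")
})

test_that("signed-rank p agrees with exhaustive sign-flip enumeration at n = 10", {
  set.seed(43)
  d <- rnorm(10, 0.4)
  res <- wilcoxonSignedRankTest(d)
  rk <- rank(abs(d))
  vObs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 10)))
  vAll <- as.vector(signs %*% rk)
  pOracle <- min(1, if (vObs > 10 * 11 / 4) 2 * mean(vAll >= vObs)
                    else 2 * mean(vAll <= vObs))
  expect_equal(res$p_value, pOracle, tolerance = 5e-4)
  expect_equal(res$statistic, vObs)
})

test_that("Friedman statistic is maximal for unanimous rankings", {
  mat <- matrix(rep(c(1, 5, 9), each = 10), 10, 3) +
    matrix(runif(30, 0, 0.5), 10, 3)
  res <- friedmanRankTest(mat)
  # closed form at identical within-block rankings: chi^2 = b(k-1) = 20
  expect_equal(res$statistic, 20)
  expect_equal(res$df, 2)
})

test_that("Friedman is invariant to condition permutation", {
  set.seed(47)
  mat <- matrix(rnorm(30), 10, 3)
  expect_equal(friedmanRankTest(mat)$statistic,
               friedmanRankTest(mat[, c(3, 1, 2)])$statistic)
})

test_that("exact Friedman p agrees with within-block permutation enumeration", {
  set.seed(53)
  mat <- matrix(rnorm(12), 4, 3)
  res <- friedmanRankTest(mat, exact = TRUE)
  # independent oracle: compute the statistic from the rank formula and
  # enumerate all (3!)^4 within-block rearrangements
  statOf <- function(m) {
    R <- t(apply(m, 1, rank))
    12 / (4 * 3 * 4) * sum(colSums(R)^2) - 3 * 4 * 4
  }
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  s0 <- statOf(mat)
  count <- 0; total <- 0
  for (p1 in perms) for (p2 in perms) for (p3 in perms) for (p4 in perms) {
    m <- rbind(mat[1, p1], mat[2, p2], mat[3, p3], mat[4, p4])
    total <- total + 1
    if (statOf(m) >= s0 - 1e-12) count <- count + 1
  }
  expect_equal(res$p_value, count / total, tolerance = 5e-4)
  expect_equal(res$statistic, s0)
  expect_error(friedmanRankTest(matrix(rnorm(40), 20, 2), exact = TRUE,
                                maxPerms = 100), "exceeds maxPerms")
  expect_error(friedmanRankTest(matrix(c(1, NA, 2, 3), 2, 2)), "missing cells")
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroniAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.06, 0.09))
  expect_equal(bonferroniAdjust(c(0.5, 0.6)), c(1, 1))
  expect_equal(bonferroniAdjust(0.2), 0.2)
  expect_error(bonferroniAdjust(c(0.5, 1.2)))
})

test_that("rank statistics are shift invariant", {
  set.seed(59)
  a <- rnorm(12); b <- rnorm(10)
  expect_equal(mannWhitneyTest(a, b)$p_value,
               mannWhitneyTest(a + 100, b + 100)$p_value)
  d <- rnorm(9, 0.3)
  expect_equal(wilcoxonSignedRankTest(d)$statistic,
               wilcoxonSignedRankTest(d * 2)$statistic)
  mat <- matrix(rnorm(30), 10, 3)
  expect_equal(friedmanRankTest(mat)$p_value,
               friedmanRankTest(mat + 7)$p_value)
})

test_that("paired seasonal permutation test is calibrated and directional", {
  set.seed(61)
  warm <- rnorm(15, 2); cold <- rnorm(15)
  res <- seasonalPermutationTest(warm, cold, nPerm = 2000, seed = 1)
  expect_lt(res$p_value, 0.01)
  expect_equal(res$statistic, mean(warm - cold))
  null <- seasonalPermutationTest(rnorm(15), rnorm(15), nPerm = 2000, seed = 2)
  expect_gt(null$p_value, 0.05)
})

test_that("observed-vs-expected feature tests flag a strongly preferred feature", {
  map <- table1Exhibit()
  set.seed(67)
  # cohort that spends ~60% of scans on B2 (availability 7.35%)
  rec <- do.call(rbind, lapply(sprintf("id%02d", 1:12), function(id) {
    n <- 40
    onB2 <- runif(n) < 0.6
    x <- ifelse(onB2, runif(n, 1.71, 3.98), runif(n, 4.8, 13.8))
    data.frame(individual_id = id, x = x, y = runif(n, 0.5, 19.5),
               stringsAsFactors = FALSE)
  }))
  usage <- observedUse(rec, map, stratifyBy = "overall")
  tests <- featurePreferenceTests(usage, map)
  b2 <- tests[tests$feature == "B2", ]
  expect_lt(b2$p_adjusted, 0.001)
  expect_gt(b2$mean_observed_pct, b2$expected_pct)
  expect_true(all(tests$p_adjusted >= tests$p_raw, na.rm = TRUE))
})
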