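test_that("identical uniform UDs over a shared region give UDOI = 1", {
  u <- makeUD(matrix(1, 8, 8), cellSize = 0.5)
  r <- makeRange(u)
  res <- udoi(u, u, r, r)
  expect_equal(res$udoi, 1, tolerance = 1e-9)
  expect_equal(res$intersection_m2, 64 * 0.25)
})

test_that("disjoint range masks give UDOI exactly 0", {
  u1 <- makeUD(matrix(1, 4, 4))
  m1 <- matrix(FALSE, 4, 4); m1[, 1:2] <- TRUE
  m2 <- matrix(FALSE, 4, 4); m2[, 3:4] <- TRUE
  res <- udoi(u1, u1, makeRange(u1, m1), makeRange(u1, m2))
  expect_identical(res$udoi, 0)
})

test_that("hand-built 4x4 grids match brute-force cell enumeration", {
  set.seed(13)
  d1 <- matrix(rexp(16), 4, 4)
  d2 <- matrix(runif(16), 4, 4)
  cs <- 0.7
  u1 <- makeUD(d1, cellSize = cs); u2 <- makeUD(d2, cellSize = cs)
  m1 <- matrix(c(TRUE, TRUE, FALSE, TRUE), 4, 4)
  m2 <- matrix(c(TRUE, FALSE, TRUE, TRUE), 4, 4, byrow = TRUE)
  res <- udoi(u1, u2, makeRange(u1, m1), makeRange(u2, m2))
  # spreadsheet-style oracle: loop every cell
  A <- 0; integral <- 0
  for (i in 1:4) for (j in 1:4) {
    if (m1[i, j] && m2[i, j]) A <- A + cs^2
    vi <- if (m1[i, j]) udDensity(u1)[i, j] else 0
    vj <- if (m2[i, j]) udDensity(u2)[i, j] else 0
    integral <- integral + vi * vj * cs^2
  }
  expect_equal(res$udoi, A * integral, tolerance = 1e-10)
  expect_equal(res$intersection_m2, A, tolerance = 1e-10)
})

test_that("mismatched grids are rejected", {
  u1 <- makeUD(matrix(1, 4, 4), cellSize = 1)
  u2 <- makeUD(matrix(1, 4, 4), cellSize = 0.4)
  expect_error(udoi(u1, u2, makeRange(u1), makeRange(u2)), "different grids")
})

test_that("UDOI can exceed 1 for concentrated co-located distributions", {
  d <- matrix(1e-6, 9, 9); d[5, 5] <- 1
  u <- makeUD(d, cellSize = 1)
  r <- makeRange(u)
  expect_gt(udoi(u, u, r, r)$udoi, 1)
})

test_that("renormalized truncation rescales the product integral", {
  set.seed(21)
  u <- makeUD(matrix(rexp(36), 6, 6))
  hr <- isopleth(u, 0.95)
  raw <- udoi(u, u, hr, hr, renormalize = FALSE)
  ren <- udoi(u, u, hr, hr, renormalize = TRUE)
  mass <- sum(udDensity(u)[rangeMask(hr)])
  expect_equal(ren$udoi, raw$udoi / mass^2, tolerance = 1e-9)
})

test_that("degree counts conspecifics above threshold, by level semantics", {
  ov <- data.frame(
    id_i = c("A", "A", "B"), id_j = c("B", "C", "C"),
    period = "Cold Season 1", level = "HR-HR",
    intersection_m2 = 1, udoi = c(0.2, 0.02, 0.001),
    stringsAsFactors = FALSE)
  deg <- degreeTable(ov)
  expect_equal(deg$degree[match(c("A", "B", "C"), deg$individual_id)],
               c(2L, 1L, 1L))
  # below threshold everywhere -> all zero
  ov0 <- ov; ov0$udoi <- c(0.005, 0.009, 0.0001)
  expect_true(all(degreeTable(ov0)$degree == 0))
  expect_error(degreeTable(rbind(ov, ov[1, ])), "duplicate dyad")
})

test_that("HR-CA degree is directional: home ranges onto an individual's core", {
  # hand-enumerated incidence: HRs of A and B overlap C's core; only A's core
  # is overlapped (by B's home range)
  ov <- data.frame(
    id_i = c("A", "A", "B", "B", "C", "C"),
    id_j = c("B", "C", "A", "C", "A", "B"),
    period = "p", level = "HR-CA", intersection_m2 = 1,
    udoi = c(0.001, 0.05, 0.03, 0.2, 0.002, 0.004),
    stringsAsFactors = FALSE)
  deg <- degreeTable(ov)
  expect_equal(deg$degree[match(c("A", "B", "C"), deg$individual_id)],
               c(1L, 0L, 2L))
})

test_that("a single shared UD yields equal overlap means at all levels", {
  u <- makeUD(matrix(1, 10, 10))
  r <- makeRange(u)
  rows <- list()
  for (pair in list(c("A", "B"), c("A", "C"), c("B", "C"))) {
    for (lv in c("HR-HR", "HR-CA", "CA-CA")) {
      res <- udoi(u, u, r, r)
      rows[[length(rows) + 1]] <- data.frame(
        id_i = pair[1], id_j = pair[2], period = "Cold Season 1",
        level = lv, intersection_m2 = res$intersection_m2,
        udoi = res$udoi, stringsAsFactors = FALSE)
    }
  }
  prof <- territorialityProfile(do.call(rbind, rows))
  expect_equal(length(unique(prof$summary$mean_udoi)), 1)
  expect_false(any(prof$territorial))
})

test_that("CA-CA degree never exceeds HR-HR degree when cores nest in homes", {
  rec <- syntheticRecords(seed = 17, n = 5, days = 240)
  fit <- estimateRanges(rec, table1Exhibit(), cellSize = 0.4)
  ov <- udoiTable(fit)
  deg <- degreeTable(ov)
  for (per in unique(deg$period)) for (id in unique(deg$individual_id)) {
    dHH <- deg$degree[deg$period == per & deg$individual_id == id &
                      deg$level == "HR-HR"]
    dCC <- deg$degree[deg$period == per & deg$individual_id == id &
                      deg$level == "CA-CA"]
    if (length(dHH) && length(dCC)) expect_lte(dCC, dHH)
  }
  # symmetric-level UDOI values are non-negative everywhere
  expect_true(all(ov$udoi >= 0))
  expect_true(all(ov$udoi[ov$intersection_m2 == 0] == 0))
})

test_that("seasonal edge lists average periods and apply the binary threshold", {
  ov <- data.frame(
    id_i = "A", id_j = "B",
    period = c("Cold Season 1", "Cold Season 2",
               "Warm Season 1", "Warm Season 2"),
    level = "HR-HR", intersection_m2 = 1,
    udoi = c(0.1, 0.3, 0.004, 0.006), stringsAsFactors = FALSE)
  e <- edgeList(ov)
  cold <- e[e$season == "cold", ]
  warm <- e[e$season == "warm", ]
  expect_equal(cold$weight, 0.2)
  expect_true(cold$edge)
  expect_equal(warm$weight, 0.005)
  expect_false(warm$edge)     # below threshold in both years -> no edge
  expect_equal(cold$n_periods, 2L)
})

test_that("edge counts equal a recount of dyads at or above threshold", {
  rec <- syntheticRecords(seed = 23, n = 5, days = 730)
  fit <- estimateRanges(rec, table1Exhibit(), cellSize = 0.4)
  ov <- udoiTable(fit)
  e <- edgeList(ov, threshold = 0.01)
  s <- ov[ov$level == "HR-HR", ]
  s$season <- ifelse(grepl("^Cold", s$period), "cold", "warm")
  agg <- aggregate(udoi ~ id_i + id_j + season, data = s, FUN = mean)
  expect_equal(sum(e$edge), sum(agg$udoi >= 0.01))
})
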