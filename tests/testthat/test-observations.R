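test_that("readLocations drops rows with missing coordinates and counts them", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("individual_id,date,time_block,x,y",
               "a,2020-11-01,morning,1.0,2.0",
               "b,2020-11-01,morning,,2.0",
               "a,2020-11-02,midday,3.5,0.5",
               "c,2020-11-02,afternoon,2.0,2.5"), f)
  rec <- readLocations(f)
  expect_equal(nrow(rec), 3)
  expect_equal(attr(rec, "dropped"), 1)
  expect_s3_class(rec$date, "Date")
  expect_equal(rec$scan_id[1], "2020-11-01_morning")
})

test_that("readLocations handles empty files, schema and date errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("individual_id,date,time_block,x,y", f)
  rec <- readLocations(f)
  expect_equal(nrow(rec), 0)
  expect_equal(attr(rec, "dropped"), 0)

  writeLines(c("id,when,x,y", "a,2020-11-01,1,2"), f)
  expect_error(readLocations(f), "schema error")
  rec2 <- readLocations(f, schema = list(id = "id", date = "when",
                                         x = "x", y = "y"))
  expect_equal(rec2$individual_id, "a")

  writeLines(c("individual_id,date,time_block,x,y",
               "a,not-a-date,morning,1,2"), f)
  expect_error(readLocations(f), "unparseable date")
})

test_that("clock times map to the three scan blocks, snapping to nearest", {
  expect_equal(assignTimeBlock(c("06:30", "08:59", "10:00", "12:30", "16:20")),
               c("morning", "morning", "midday", "midday", "afternoon"))
  # 09:20 is 20 min past morning, 40 min before midday -> morning
  expect_warning(b <- assignTimeBlock("09:20"), "outside the scan windows")
  expect_equal(b, "morning")
})

test_that("affine transforms apply exactly and refit recovers coefficients", {
  ident <- fitAffine(cbind(c(0, 1, 0, 1), c(0, 0, 1, 1)),
                     cbind(c(0, 1, 0, 1), c(0, 0, 1, 1)))
  expect_equal(unname(applyAffine(ident, cbind(100, 200))),
               cbind(100, 200), tolerance = 1e-12)

  tr <- structure(list(a = 2, b = 0, c = 1, d = 0, e = 2, f = -1),
                  class = "affineTransform")
  expect_equal(unname(applyAffine(tr, cbind(3, 4))), cbind(7, 7))

  # generate-and-refit oracle: 4 control points under a known map, zero noise
  gen <- structure(list(a = 0.05, b = -0.01, c = 3, d = 0.02, e = -0.055, f = 31),
                   class = "affineTransform")
  src <- cbind(c(0, 600, 0, 455), c(0, 0, 600, 137))
  fit <- fitAffine(src, applyAffine(gen, src))
  expect_equal(fit[c("a", "b", "c", "d", "e", "f")],
               gen[c("a", "b", "c", "d", "e", "f")], tolerance = 1e-9)

  expect_error(fitAffine(cbind(c(0, 1, 2), c(0, 1, 2)),
                         cbind(c(0, 1, 2), c(0, 2, 4))), "collinear")
})

test_that("fitted affine round-trips its own control points", {
  set.seed(7)
  src <- cbind(runif(6, 0, 600), runif(6, 0, 600))
  gen <- structure(list(a = 0.04, b = 0.003, c = -2, d = -0.001, e = 0.042, f = 5),
                   class = "affineTransform")
  dst <- applyAffine(gen, src)
  fit <- fitAffine(src, dst)
  expect_equal(applyAffine(fit, src), dst, tolerance = 1e-9)
})

test_that("dates label into four season-by-year sampling periods", {
  lab <- labelPeriod(as.Date(c("2020-11-15", "2021-04-01", "2022-03-31")),
                     as.Date("2020-10-01"))
  expect_equal(lab$period,
               c("Cold Season 1", "Warm Season 1", "Cold Season 2"))
  expect_equal(lab$season, c("cold", "warm", "cold"))
  expect_error(labelPeriod(as.Date("2023-01-01"), as.Date("2020-10-01")),
               "outside the study window")
})

test_that("every retained record is labelled and period counts sum to total", {
  rec <- syntheticRecords(seed = 3, n = 4, days = 730)
  map <- table1Exhibit()
  norm <- normalizeLocations(rec[c("individual_id", "scan_id", "date",
                                   "time_block", "x", "y")], map,
                             studyStart = as.Date("2020-10-01"))
  expect_false(anyNA(norm$season))
  expect_false(anyNA(norm$period))
  expect_false(anyNA(norm$time_block))
  expect_equal(sum(table(norm$period)), nrow(norm))
  expect_setequal(unique(norm$period),
                  c("Cold Season 1", "Warm Season 1",
                    "Cold Season 2", "Warm Season 2"))
})

test_that("out-of-bounds points snap within tolerance and drop beyond it", {
  map <- twoFeatureMap()
  rec <- data.frame(individual_id = c("a", "a", "a"),
                    scan_id = "s", date = as.Date("2020-10-02"),
                    time_block = "morning",
                    x = c(0.5, 1.0005, 5), y = c(0.5, 0.5, 0.5),
                    stringsAsFactors = FALSE)
  norm <- normalizeLocations(rec, map, snapTolerance = 0.01)
  expect_equal(nrow(norm), 2)
  expect_equal(attr(norm, "snapped"), 1)
  expect_equal(attr(norm, "dropped_oob"), 1)
  expect_true(all(pracma::inpolygon(norm$x, norm$y,
                                    boundary(map)[, 1], boundary(map)[, 2],
                                    boundary = TRUE)))
})
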