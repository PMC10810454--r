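#' @include exhibit-map.R observations.R
NULL

#' Synthetic-cohort configuration
#'
#' Parameters of the scan-data generator.  Defaults emulate the study
#' conditions the analysis is designed for: 18 adult individuals scanned in
#' three daily blocks over a 730-day (two seasonal cycles) window at about
#' 1.8 scans per day, with individual activity centres inside a bounded
#' exhibit, a shared attraction to one land (basking) feature, and
#' per-scan invisibility.
#'
#' Two scenarios are generated.  In the `territorial` scenario each
#' individual has its own activity centre, centres pairwise separated by at
#' least three dispersion lengths, so core areas barely overlap.  In the
#' `nonterritorial` scenario all individuals draw from one shared pool of
#' centres, so utilization distributions coincide at every space-use level.
#'
#' @param scenario "territorial" or "nonterritorial".
#' @param nIndividuals number of individuals (default 18).
#' @param studyStart first study day (Date); default "2020-10-01", the start
#'   of a cold season.
#' @param studyDays study length in days (default 730, two seasonal cycles).
#' @param scansPerDayTarget mean realised scans per day out of the 3
#'   scheduled blocks (default 1.8).
#' @param dispersionWithin Gaussian spread (m) around an individual's own
#'   centre (default 2).
#' @param dispersionShared spread (m) around shared pool centres in the
#'   nonterritorial scenario (default 3).
#' @param landAttraction probability a draw is redirected to the designated
#'   land feature's centroid (default 0.3 — basking pull).
#' @param landFeature feature code of the attraction target (default "B2").
#' @param missingness per-scan probability an individual is not visible
#'   (default 0.2).
#' @param seasonalShrink multiplier on dispersion in the cold season
#'   (default 0.9, giving slightly smaller cold-season ranges).
#' @param seed RNG seed.
#' @return a `"simulationConfig"` list.
#' @export
simulationConfig <- function(scenario = c("territorial", "nonterritorial"),
                             nIndividuals = 18,
                             studyStart = as.Date("2020-10-01"),
                             studyDays = 730,
                             scansPerDayTarget = 1.8,
                             dispersionWithin = 2,
                             dispersionShared = 3,
                             landAttraction = 0.3,
                             landFeature = "B2",
                             missingness = 0.2,
                             seasonalShrink = 0.9,
                             seed = 1) {
  cfg <- list(scenario = match.arg(scenario), nIndividuals = nIndividuals,
              studyStart = as.Date(studyStart), studyDays = studyDays,
              scansPerDayTarget = scansPerDayTarget,
              dispersionWithin = dispersionWithin,
              dispersionShared = dispersionShared,
              landAttraction = landAttraction, landFeature = landFeature,
              missingness = missingness, seasonalShrink = seasonalShrink,
              seed = seed)
  class(cfg) <- "simulationConfig"
  cfg
}

# hexagonal lattice of candidate activity centres inside the boundary,
# spacing >= 3 * dispersion (the territorial separation invariant)
.territorialCenters <- function(map, n, dispersion) {
  bnd <- boundary(map)
  bb <- apply(bnd, 2, range)
  # a floor on the lattice spacing keeps the construction sane as
  # dispersion -> 0 while still satisfying the >= 3 dispersions invariant
  spacing <- max(3 * dispersion, 3)
  margin <- max(1.5, dispersion)
  rowStep <- spacing * sqrt(3) / 2
  ys <- seq(bb[1, 2] + margin, bb[2, 2] - margin, by = rowStep)
  pts <- NULL
  for (i in seq_along(ys)) {
    off <- if (i %% 2 == 0) spacing / 2 else 0
    xs <- seq(bb[1, 1] + margin + off, bb[2, 1] - margin, by = spacing)
    pts <- rbind(pts, cbind(xs, ys[i]))
  }
  keep <- pointsInPolygon(pts[, 1], pts[, 2], bnd)
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) < n)
    stop(sprintf("cannot place %d centres at >= %.1f m separation; reduce dispersion or group size",
                 n, spacing))
  # spread the selection across the lattice rather than filling row by row
  pts[round(seq(1, nrow(pts), length.out = n)), , drop = FALSE]
}

#' Simulate a scan-sampled cohort
#'
#' Generates location records with the statistical structure the analysis
#' assumes: for each scheduled scan (3 daily blocks thinned to the target
#' scan rate) and each visible individual, a location is drawn from a
#' truncated Gaussian centred either on the designated land feature's
#' centroid (with probability `landAttraction`) or on the individual's own
#' seasonal activity centre (territorial) / a shared pool centre
#' (nonterritorial).  Points are rejection-resampled until inside the
#' boundary, so nothing is clipped onto walls.  Fully reproducible under
#' the config seed.
#'
#' @param config a [simulationConfig()].
#' @param map an [ExhibitMap-class]; default the packaged exhibit.
#' @return data.frame of records (individual_id, scan_id, date, time_block,
#'   x, y, season, period) with attribute `"truth"`: list(centers, config).
#' @export
simulateCohort <- function(config, map = table1Exhibit()) {
  stopifnot(inherits(config, "simulationConfig"))
  set.seed(config$seed)
  bnd <- boundary(map)
  ids <- sprintf("croc%02d", seq_len(config$nIndividuals))
  if (config$scenario == "territorial") {
    centers <- .territorialCenters(map, config$nIndividuals,
                                   config$dispersionWithin)
    rownames(centers) <- ids
    dispersion <- config$dispersionWithin
  } else {
    bb <- apply(bnd, 2, range)
    pool <- cbind(
      stats::runif(3, bb[1, 1] + 0.25 * diff(bb[, 1]),
                   bb[2, 1] - 0.25 * diff(bb[, 1])),
      stats::runif(3, bb[1, 2] + 0.25 * diff(bb[, 2]),
                   bb[2, 2] - 0.25 * diff(bb[, 2])))
    centers <- pool
    dispersion <- config$dispersionShared
  }
  if (!all(pointsInPolygon(centers[, 1], centers[, 2], bnd)))
    stop("config error: activity centre outside the boundary")
  landC <- polygonCentroid(features(map)[[config$landFeature]])

  blocks <- c("morning", "midday", "afternoon")
  days <- rep(seq_len(config$studyDays), each = 3)
  blk <- rep(blocks, times = config$studyDays)
  held <- stats::runif(length(days)) < config$scansPerDayTarget / 3
  days <- days[held]; blk <- blk[held]
  nScan <- length(days)

  visible <- matrix(stats::runif(nScan * config$nIndividuals) >=
                      config$missingness, nScan, config$nIndividuals)
  scanIdx <- rep(seq_len(nScan), times = config$nIndividuals)
  indIdx <- rep(seq_len(config$nIndividuals), each = nScan)
  keep <- as.vector(visible)
  scanIdx <- scanIdx[keep]; indIdx <- indIdx[keep]
  nRec <- length(scanIdx)

  dates <- config$studyStart + (days[scanIdx] - 1)
  season <- labelPeriod(dates, config$studyStart, config$studyDays)
  sd0 <- rep(dispersion, nRec)
  sd0[season$season == "cold"] <- sd0[season$season == "cold"] *
    config$seasonalShrink

  toLand <- stats::runif(nRec) < config$landAttraction
  if (config$scenario == "territorial") {
    cx <- centers[indIdx, 1]; cy <- centers[indIdx, 2]
  } else {
    pick <- sample.int(nrow(centers), nRec, replace = TRUE)
    cx <- centers[pick, 1]; cy <- centers[pick, 2]
  }
  cx[toLand] <- landC[1]; cy[toLand] <- landC[2]

  x <- stats::rnorm(nRec, cx, sd0)
  y <- stats::rnorm(nRec, cy, sd0)
  for (it in seq_len(1000)) {
    bad <- !pointsInPolygon(x, y, bnd)
    if (!any(bad)) break
    x[bad] <- stats::rnorm(sum(bad), cx[bad], sd0[bad])
    y[bad] <- stats::rnorm(sum(bad), cy[bad], sd0[bad])
  }
  if (any(bad)) stop("rejection sampling failed to place all points in bounds")

  out <- data.frame(
    individual_id = ids[indIdx],
    scan_id = paste(format(dates), blk[scanIdx], sep = "_"),
    date = dates,
    time_block = blk[scanIdx],
    x = x, y = y,
    season = season$season,
    period = season$period,
    stringsAsFactors = FALSE)
  out <- out[order(out$date, out$time_block, out$individual_id), ]
  rownames(out) <- NULL
  attr(out, "truth") <- list(centers = centers, config = config)
  out
}

#' Write a simulated cohort to disk
#'
#' Writes the locations CSV in the dialect [readLocations()] reads, and the
#' ground truth (activity centres + config echo) as JSON.
#'
#' @param cohort data.frame from [simulateCohort()].
#' @param locationsPath CSV output path.
#' @param truthPath optional JSON output path.
#' @export
writeCohort <- function(cohort, locationsPath, truthPath = NULL) {
  utils::write.csv(
    cohort[c("individual_id", "date", "time_block", "x", "y")],
    locationsPath, row.names = FALSE)
  if (!is.null(truthPath)) {
    truth <- attr(cohort, "truth")
    jsonlite::write_json(
      list(centers = as.data.frame(truth$centers),
           config = unclass(truth$config)),
      truthPath, auto_unbox = TRUE, digits = NA)
  }
  invisible(locationsPath)
}

#' Parameter-recovery report for a simulated cohort
#'
#' Runs the full pipeline on a simulated cohort and checks that the
#' analysis recovers the generator's structure: (1) in the territorial
#' scenario, mean UDOI decreases strictly HR-HR > HR-CA > CA-CA in every
#' season; (2) the CA-CA/HR-HR mean-UDOI ratio (territoriality contrast
#' against a nonterritorial run is up to the caller); (3) every estimated
#' home range contains the individual's true activity centre; (4) the land
#' attraction feature has the highest group-mean electivity.
#'
#' @param cohort data.frame from [simulateCohort()] (with its truth attribute).
#' @param map the [ExhibitMap-class] used to simulate.
#' @param cellSize analysis grid resolution (m).
#' @return list: checks (named logicals), caRatio (mean CA-CA / mean HR-HR),
#'   profile (from [territorialityProfile()]), areas, electivitySummary.
#' @export
recoveryReport <- function(cohort, map = table1Exhibit(), cellSize = 0.25) {
  truth <- attr(cohort, "truth")
  fit <- estimateRanges(cohort, map, cellSize = cellSize)
  ov <- udoiTable(fit)
  deg <- degreeTable(ov)
  prof <- territorialityProfile(ov, deg)
  caRatio <- mean(ov$udoi[ov$level == "CA-CA"]) /
             mean(ov$udoi[ov$level == "HR-HR"])

  # (3) home range contains the true centre, for every individual-period HR
  centerInHR <- TRUE
  if (truth$config$scenario == "territorial") {
    for (key in names(fit$ranges)) {
      parts <- strsplit(key, "|", fixed = TRUE)[[1]]
      if (as.numeric(parts[3]) != 0.95) next
      re <- fit$ranges[[key]]
      ctr <- truth$centers[parts[1], ]
      ix <- ceiling((ctr[1] - re@origin[1]) / re@cellSize)
      iy <- ceiling((ctr[2] - re@origin[2]) / re@cellSize)
      if (!re@mask[iy, ix]) centerInHR <- FALSE
    }
  }

  usage <- observedUse(cohort, map, stratifyBy = "overall")
  elect <- electivityTable(usage, map)
  esum <- groupPreferenceSummary(elect)
  topFeature <- esum$feature[which.max(esum$mean)]

  checks <- c(
    monotone_overlap_decrease = all(prof$territorial),
    center_in_home_range = centerInHR,
    land_feature_preferred = topFeature == truth$config$landFeature)
  list(checks = checks, caRatio = caRatio, profile = prof,
       areas = fit$areas, electivitySummary = esum,
       topFeature = topFeature)
}
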