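#' @include homerange.R
NULL

#' Utilization distribution overlap index for one dyad
#'
#' Computes \eqn{UDOI = A_{i,j} \int\int UD_i(x,y) \times UD_j(x,y)}, where
#' each UD is first restricted to its own isopleth region (home range or
#' core area) and \eqn{A_{i,j}} is the area of intersection of the two
#' regions.  UDOI is 0 for non-overlapping ranges, about 1 for two uniform
#' distributions overlapping completely, and can exceed 1 when both animals
#' concentrate use in the same place.
#'
#' By default the restricted UDs keep their truncated mass (95% or 50%) —
#' they are not renormalised; set `renormalize = TRUE` to rescale each
#' restricted UD back to unit mass before the product integral.
#'
#' @param udI,udJ [UtilizationDistribution-class] objects on the same grid.
#' @param regionI,regionJ [RangeEstimate-class] masks for each UD (e.g.
#'   i's home range and j's core area for the HR-CA level).
#' @param renormalize logical; see Details.
#' @return list with elements `udoi` and `intersection_m2`.
#' @export
udoi <- function(udI, udJ, regionI, regionJ, renormalize = FALSE) {
  if (!isTRUE(all.equal(udI@origin, udJ@origin)) ||
      udI@cellSize != udJ@cellSize ||
      !identical(dim(udI@density), dim(udJ@density)))
    stop("utilization distributions are on different grids")
  cs2 <- udI@cellSize^2
  di <- udI@density * regionI@mask
  dj <- udJ@density * regionJ@mask
  if (renormalize) {
    di <- di / (sum(di) * cs2)
    dj <- dj / (sum(dj) * cs2)
  }
  A <- sum(regionI@mask & regionJ@mask) * cs2
  list(udoi = A * sum(di * dj) * cs2, intersection_m2 = A)
}

# mass-matrix shortcut: columns are per-individual masked density vectors,
# crossprod gives all pairwise product sums at once
.maskedDensityMatrix <- function(uds, ranges, ids, period, level, renormalize) {
  cs2 <- uds[[paste(ids[1], period, sep = "|")]]@cellSize^2
  cols <- lapply(ids, function(id) {
    ud <- uds[[paste(id, period, sep = "|")]]
    re <- ranges[[paste(id, period, level, sep = "|")]]
    d <- as.vector(ud@density * re@mask)
    if (renormalize) d <- d / (sum(d) * cs2)
    d
  })
  do.call(cbind, cols)
}

#' Dyadic UDOI table across space-use levels
#'
#' Computes UDOI for every dyad in every sampling period at the three
#' space-use levels: HR-HR (both home ranges), CA-CA (both core areas) and
#' HR-CA.  HR-HR and CA-CA are symmetric and reported once per unordered
#' dyad; HR-CA is directional and reported for every ordered pair, with
#' `id_i` the home-range side and `id_j` the core-area side.
#'
#' @param fit result of [estimateRanges()].
#' @param homeLevel,coreLevel the isopleth levels used in `fit`.
#' @param renormalize passed to [udoi()].
#' @return data.frame with columns id_i, id_j, period, level
#'   ("HR-HR"/"HR-CA"/"CA-CA"), intersection_m2, udoi.
#' @export
udoiTable <- function(fit, homeLevel = 0.95, coreLevel = 0.50,
                      renormalize = FALSE) {
  uds <- fit$uds; ranges <- fit$ranges
  periods <- unique(vapply(uds, function(u) u@period, character(1)))
  rows <- list()
  for (per in periods) {
    ids <- sort(vapply(uds[vapply(uds, function(u) u@period == per, logical(1))],
                       function(u) u@individual, character(1)))
    if (length(ids) < 2) next
    cs2 <- uds[[paste(ids[1], per, sep = "|")]]@cellSize^2
    maskOf <- function(id, lv) ranges[[paste(id, per, lv, sep = "|")]]@mask
    for (lv in list(c("HR-HR", homeLevel, homeLevel),
                    c("CA-CA", coreLevel, coreLevel))) {
      M <- .maskedDensityMatrix(uds, ranges, ids, per, as.numeric(lv[2]),
                                renormalize)
      P <- crossprod(M) * cs2           # pairwise product integrals
      for (a in seq_along(ids)[-length(ids)]) for (b in (a + 1):length(ids)) {
        A <- sum(maskOf(ids[a], as.numeric(lv[2])) &
                 maskOf(ids[b], as.numeric(lv[3]))) * cs2
        rows[[length(rows) + 1]] <- data.frame(
          id_i = ids[a], id_j = ids[b], period = per, level = lv[1],
          intersection_m2 = A, udoi = A * P[a, b], stringsAsFactors = FALSE)
      }
    }
    # HR-CA: directional, i's home range against j's core area
    Mh <- .maskedDensityMatrix(uds, ranges, ids, per, homeLevel, renormalize)
    Mc <- .maskedDensityMatrix(uds, ranges, ids, per, coreLevel, renormalize)
    P <- crossprod(Mh, Mc) * cs2
    for (a in seq_along(ids)) for (b in seq_along(ids)) {
      if (a == b) next
      A <- sum(maskOf(ids[a], homeLevel) & maskOf(ids[b], coreLevel)) * cs2
      rows[[length(rows) + 1]] <- data.frame(
        id_i = ids[a], id_j = ids[b], period = per, level = "HR-CA",
        intersection_m2 = A, udoi = A * P[a, b], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Overlap degree per individual
#'
#' Counts, for each individual in each period and space-use level, the
#' number of conspecifics it overlaps with, where a dyad counts as
#' overlapping when its UDOI is at least `threshold` (default 0.01).
#' HR-HR and CA-CA degree is symmetric; HR-CA degree is the number of
#' conspecific home ranges overlapping the individual's own core area.
#'
#' @param overlaps data.frame from [udoiTable()].
#' @param threshold UDOI cut-off; default 0.01.
#' @return data.frame individual_id, period, level, degree.
#' @export
degreeTable <- function(overlaps, threshold = 0.01) {
  rows <- list()
  for (per in unique(overlaps$period)) {
    sub <- overlaps[overlaps$period == per, ]
    ids <- sort(unique(c(sub$id_i, sub$id_j)))
    for (lv in unique(sub$level)) {
      s <- sub[sub$level == lv, ]
      if (anyDuplicated(paste(s$id_i, s$id_j)))
        stop("duplicate dyad entries in overlap table")
      hit <- s[s$udoi >= threshold, ]
      deg <- if (lv == "HR-CA") {
        # count home ranges (id_i side) overlapping each individual's core (id_j)
        stats::setNames(vapply(ids, function(k)
          sum(hit$id_j == k), integer(1)), ids)
      } else {
        stats::setNames(vapply(ids, function(k)
          sum(hit$id_i == k | hit$id_j == k), integer(1)), ids)
      }
      rows[[length(rows) + 1]] <- data.frame(
        individual_id = ids, period = per, level = lv,
        degree = unname(deg), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

.seasonOf <- function(period) ifelse(grepl("^Cold", period), "cold", "warm")

#' Territoriality profile across space-use levels
#'
#' Summarises dyadic overlap by season and space-use level (mean, SE and
#' dyad count of UDOI, and mean/SE of degree), and flags, per season,
#' whether the means decrease monotonically HR-HR > HR-CA > CA-CA — the
#' signature of a territorial group.  Non-territorial groups show roughly
#' equal overlap across levels.
#'
#' @param overlaps data.frame from [udoiTable()].
#' @param degrees optional data.frame from [degreeTable()].
#' @return list with `summary` (season, level, mean_udoi, se_udoi, n_dyads,
#'   and when degrees are given mean_degree, se_degree) and `territorial`
#'   (named logical per season).
#' @export
territorialityProfile <- function(overlaps, degrees = NULL) {
  lv <- c("HR-HR", "HR-CA", "CA-CA")
  overlaps$season <- .seasonOf(overlaps$period)
  rows <- list()
  for (se in unique(overlaps$season)) for (l in lv) {
    v <- overlaps$udoi[overlaps$season == se & overlaps$level == l]
    if (length(v) < 2) next
    row <- data.frame(season = se, level = l, mean_udoi = mean(v),
                      se_udoi = stats::sd(v) / sqrt(length(v)),
                      n_dyads = length(v), stringsAsFactors = FALSE)
    if (!is.null(degrees)) {
      degrees$season <- .seasonOf(degrees$period)
      d <- degrees$degree[degrees$season == se & degrees$level == l]
      row$mean_degree <- mean(d)
      row$se_degree <- stats::sd(d) / sqrt(length(d))
    }
    rows[[length(rows) + 1]] <- row
  }
  summary <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  seasons <- unique(summary$season)
  territorial <- stats::setNames(vapply(seasons, function(se) {
    m <- summary$mean_udoi[summary$season == se][match(lv, summary$level[summary$season == se])]
    !anyNA(m) && m[1] > m[2] && m[2] > m[3]
  }, logical(1)), seasons)
  list(summary = summary, territorial = territorial)
}

#' Seasonal overlap edge lists
#'
#' Aggregates dyadic overlap to the season level for network analysis:
#' per unordered dyad and season, the weighted edge is the arithmetic mean
#' UDOI over that season's sampling periods (years), and the binary edge is
#' present when the aggregated UDOI reaches `threshold`.  Only individuals
#' present in every requested period are retained, so that edge weights
#' average over a complete panel.
#'
#' @param overlaps data.frame from [udoiTable()]; HR-CA rows are aggregated
#'   per ordered pair.
#' @param level space-use level to build the network from (default "HR-HR").
#' @param threshold binary-edge UDOI cut-off; default 0.01.
#' @return data.frame source, target, season, weight, edge (logical binary
#'   edge), n_periods.
#' @export
edgeList <- function(overlaps, level = "HR-HR", threshold = 0.01) {
  s <- overlaps[overlaps$level == level, ]
  s$season <- .seasonOf(s$period)
  # restrict to individuals present in every period of the table
  allPeriods <- unique(overlaps$period)
  present <- lapply(allPeriods, function(p) {
    sub <- overlaps[overlaps$period == p, ]
    unique(c(sub$id_i, sub$id_j))
  })
  keep <- Reduce(intersect, present)
  s <- s[s$id_i %in% keep & s$id_j %in% keep, ]
  key <- paste(s$id_i, s$id_j, s$season, sep = "\r")
  agg <- tapply(s$udoi, key, mean)
  n <- tapply(s$udoi, key, length)
  parts <- do.call(rbind, strsplit(names(agg), "\r", fixed = TRUE))
  data.frame(source = parts[, 1], target = parts[, 2], season = parts[, 3],
             weight = unname(agg), edge = unname(agg >= threshold),
             n_periods = unname(as.integer(n)),
             stringsAsFactors = FALSE, row.names = NULL)
}
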