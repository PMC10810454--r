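#' @include AllClasses.R exhibit-map.R
NULL

#' Standard distance of a point set
#'
#' Root-mean-square distance of locations from their centroid,
#' \eqn{\sigma = \sqrt{\sum[(x-\bar x)^2 + (y-\bar y)^2] / n}}: the scalar
#' dispersion that feeds the optimal kernel bandwidth.
#'
#' @param x,y numeric coordinate vectors (>= 2 points).
#' @return sigma in metres.
#' @export
standardDistance <- function(x, y) {
  if (length(x) < 2) stop("standard distance needs at least 2 points")
  sqrt(sum((x - mean(x))^2 + (y - mean(y))^2) / length(x))
}

#' Optimal kernel bandwidth
#'
#' The fixed-kernel smoothing parameter
#' \eqn{h_{opt} = (2 / (3n))^{1/4} \, \sigma}, where n is the number of
#' locations and \eqn{\sigma} their standard distance.  This selector sits
#' between least-squares cross-validation (which oversmooths scan data of
#' this kind) and the reference bandwidth href (which undersmooths).
#'
#' @param x,y numeric coordinate vectors.
#' @return h in metres.
#' @export
optimalBandwidth <- function(x, y) {
  n <- length(x)
  sigma <- standardDistance(x, y)
  if (sigma == 0)
    stop("zero standard distance: all locations identical; ",
         "jitter the points or skip this individual-period")
  (2 / (3 * n))^(1 / 4) * sigma
}

# Regular analysis grid spanning the exhibit boundary, with the in-bounds
# cell-centre mask precomputed (shared across all UDs of a cohort).
#' Analysis grid over an exhibit
#'
#' Builds the regular grid used for all utilization distributions of an
#' analysis: origin at the boundary bounding box's lower-left corner, square
#' cells of edge `cellSize`, plus the mask of cells whose centres fall
#' inside the boundary (the barrier).  Computing this once and passing it to
#' [estimateUD()] avoids re-deriving the mask for every individual-period.
#'
#' @param map an [ExhibitMap-class].
#' @param cellSize cell edge in metres (default 0.25, sub-animal scale).
#' @param minCells minimum grid extent per axis before a resolution error is
#'   raised (default 50).
#' @return list with origin, cellSize, nx, ny, xCenters, yCenters, inBounds.
#' @export
exhibitGrid <- function(map, cellSize = 0.25, minCells = 50) {
  bb <- apply(boundary(map), 2, range)
  nx <- ceiling((bb[2, 1] - bb[1, 1]) / cellSize)
  ny <- ceiling((bb[2, 2] - bb[1, 2]) / cellSize)
  if (nx < minCells || ny < minCells)
    stop(sprintf("grid too coarse: %d x %d cells (< %d per axis); reduce cellSize",
                 nx, ny, minCells))
  origin <- c(bb[1, 1], bb[1, 2])
  xc <- origin[1] + (seq_len(nx) - 0.5) * cellSize
  yc <- origin[2] + (seq_len(ny) - 0.5) * cellSize
  inB <- matrix(pointsInPolygon(rep(xc, each = ny), rep(yc, times = nx),
                                boundary(map)),
                nrow = ny, ncol = nx)
  list(origin = origin, cellSize = cellSize, nx = nx, ny = ny,
       xCenters = xc, yCenters = yc, inBounds = inB)
}

#' Estimate a utilization distribution by fixed-kernel KDE
#'
#' Sums an isotropic bivariate Gaussian kernel of bandwidth `h` over the
#' locations on a regular grid.  With an exhibit map (or prebuilt
#' [exhibitGrid()]), the boundary acts as a barrier: density in cells whose
#' centres fall outside the boundary is set to zero and the remaining mass
#' renormalised to 1 (truncate-and-renormalise barrier semantics).  With
#' `map = NULL` the estimate is unbounded on a grid spanning the points
#' plus `pad` bandwidths.
#'
#' @param x,y location coordinates (metres); must be in bounds when a map
#'   is given.
#' @param h kernel bandwidth (metres), e.g. from [optimalBandwidth()].
#' @param map an [ExhibitMap-class], a prebuilt [exhibitGrid()] list, or NULL.
#' @param cellSize grid cell edge (m); ignored when a prebuilt grid is given.
#' @param individual,period labels stored on the result.
#' @param pad grid padding in multiples of h for the unbounded case.
#' @return a [UtilizationDistribution-class].
#' @export
estimateUD <- function(x, y, h, map = NULL, cellSize = 0.25,
                       individual = "ind", period = "all", pad = 4) {
  stopifnot(h > 0, length(x) == length(y), length(x) >= 1)
  if (is.null(map)) {
    x0 <- min(x) - pad * h; x1 <- max(x) + pad * h
    y0 <- min(y) - pad * h; y1 <- max(y) + pad * h
    nx <- ceiling((x1 - x0) / cellSize); ny <- ceiling((y1 - y0) / cellSize)
    grid <- list(origin = c(x0, y0), cellSize = cellSize, nx = nx, ny = ny,
                 xCenters = x0 + (seq_len(nx) - 0.5) * cellSize,
                 yCenters = y0 + (seq_len(ny) - 0.5) * cellSize,
                 inBounds = matrix(TRUE, ny, nx))
  } else if (is(map, "ExhibitMap")) {
    grid <- exhibitGrid(map, cellSize = cellSize)
  } else {
    grid <- map
  }
  # separable Gaussian: density = (1/n) * Gy %*% t(Gx), summed over points
  Gy <- outer(grid$yCenters, y, function(c, p) stats::dnorm(c, p, h))
  Gx <- outer(grid$xCenters, x, function(c, p) stats::dnorm(c, p, h))
  dens <- (Gy %*% t(Gx)) / length(x)
  dens[!grid$inBounds] <- 0
  total <- sum(dens) * grid$cellSize^2
  if (total <= 0) stop("all kernel mass fell outside the boundary")
  dens <- dens / total
  new("UtilizationDistribution",
      individual = individual, period = period,
      origin = grid$origin, cellSize = grid$cellSize,
      density = dens, inBounds = grid$inBounds,
      bandwidth = h, nLocations = length(x))
}

#' Extract an isopleth range (home range or core area)
#'
#' Greedy fixed-kernel isopleth: cells are sorted by density (descending,
#' ties broken by row-major cell index) and accumulated until their summed
#' probability first reaches `level`.  The 95% isopleth is the home range,
#' the 50% isopleth the core area.
#'
#' @param ud a [UtilizationDistribution-class].
#' @param level isopleth level strictly between 0 and 1.
#' @return a [RangeEstimate-class]; its area is the masked cell count times
#'   the cell area.
#' @export
isopleth <- function(ud, level) {
  stopifnot(level > 0, level < 1)
  d <- ud@density
  ny <- nrow(d); nx <- ncol(d)
  v <- as.vector(d)                       # column-major
  col <- (seq_along(v) - 1L) %/% ny + 1L
  row <- (seq_along(v) - 1L) %% ny + 1L
  rowMajor <- (row - 1L) * nx + col
  ord <- order(-v, rowMajor)
  prob <- v[ord] * ud@cellSize^2
  k <- which(cumsum(prob) >= level - 1e-12)[1]
  if (is.na(k)) k <- length(v)
  mask <- matrix(FALSE, ny, nx)
  mask[ord[seq_len(k)]] <- TRUE
  new("RangeEstimate",
      individual = ud@individual, period = ud@period,
      level = level, mask = mask,
      area = sum(mask) * ud@cellSize^2,
      origin = ud@origin, cellSize = ud@cellSize)
}

#' Per individual-period utilization distributions and ranges
#'
#' Runs the full space-use estimation over normalised location records: for
#' every individual x sampling period with at least `minLocations` records,
#' computes the optimal bandwidth, the barrier-truncated UD on the shared
#' exhibit grid, and the home-range / core-area isopleths.
#'
#' @param records normalised records (see [normalizeLocations()]) with
#'   columns individual_id, period, x, y.
#' @param map an [ExhibitMap-class].
#' @param cellSize grid cell edge (m).
#' @param levels isopleth levels, core first or last — order free; default
#'   c(home = 0.95, core = 0.50).
#' @param minLocations individual-periods with fewer records are skipped
#'   (with a message); default 10.
#' @return list with elements `uds` (named list "id|period" ->
#'   [UtilizationDistribution-class]), `ranges` (named list "id|period|level"
#'   -> [RangeEstimate-class]) and `areas` (data.frame individual_id, period,
#'   level, n_locations, bandwidth_m, area_m2).
#' @export
estimateRanges <- function(records, map, cellSize = 0.25,
                           levels = c(home = 0.95, core = 0.50),
                           minLocations = 10) {
  grid <- exhibitGrid(map, cellSize = cellSize)
  uds <- list(); ranges <- list(); rows <- list()
  for (per in unique(records$period)) {
    perRec <- records[records$period == per, ]
    for (id in unique(perRec$individual_id)) {
      r <- perRec[perRec$individual_id == id, ]
      if (nrow(r) < minLocations) {
        message(sprintf("skipping %s / %s: %d < %d locations",
                        id, per, nrow(r), minLocations))
        next
      }
      h <- optimalBandwidth(r$x, r$y)
      ud <- estimateUD(r$x, r$y, h, map = grid,
                       individual = id, period = per)
      uds[[paste(id, per, sep = "|")]] <- ud
      for (lv in levels) {
        re <- isopleth(ud, lv)
        ranges[[paste(id, per, lv, sep = "|")]] <- re
        rows[[length(rows) + 1]] <- data.frame(
          individual_id = id, period = per, level = lv,
          n_locations = nrow(r), bandwidth_m = h, area_m2 = re@area,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(uds = uds, ranges = ranges,
       areas = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}
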