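#' @include exhibit-map.R
NULL

# Scan-schedule windows (minutes since midnight). All scans belong to one of
# three daily blocks; clock times between windows snap to the nearest one.
.blockWindows <- data.frame(
  block = c("morning", "midday", "afternoon"),
  start = c(6 * 60 + 30, 10 * 60, 15 * 60),
  end   = c(9 * 60, 12 * 60 + 30, 17 * 60 + 30)
)

#' Read scan-sampled location data
#'
#' Reads a locations CSV (UTF-8, header row) into a validated data.frame of
#' one row per individual per scan.  Column names in the file are mapped via
#' `schema`, so deposited files need not be renamed.  Rows with a missing
#' x or y coordinate are dropped and counted; unparseable dates raise an
#' error reporting the offending row numbers.
#'
#' @param path CSV file path.
#' @param schema named list mapping the canonical fields `id`, `date`, `x`,
#'   `y` and optionally `time` (clock time, "HH:MM" or "HH:MM:SS") or
#'   `block` (time-block label) to the file's column names.
#' @param dateFormat passed to [as.Date()]; default `"%Y-%m-%d"`.
#' @return data.frame with columns individual_id, date, time_block (NA if
#'   neither time nor block was mapped), x, y and scan_id
#'   (date + time-block).  The number of dropped rows is attached as
#'   attribute `"dropped"`.
#' @export
readLocations <- function(path,
                          schema = list(id = "individual_id", date = "date",
                                        time = NULL, block = "time_block",
                                        x = "x", y = "y"),
                          dateFormat = "%Y-%m-%d") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("id", "date", "x", "y")
  for (f in need) {
    col <- schema[[f]]
    if (is.null(col) || !(col %in% names(raw)))
      stop(sprintf("schema error: required column '%s' (field '%s') missing",
                   col %||% "<unset>", f))
  }
  x <- suppressWarnings(as.numeric(raw[[schema$x]]))
  y <- suppressWarnings(as.numeric(raw[[schema$y]]))
  keep <- !(is.na(x) | is.na(y))
  dropped <- sum(!keep)
  raw <- raw[keep, , drop = FALSE]
  x <- x[keep]; y <- y[keep]
  dates <- as.Date(as.character(raw[[schema$date]]), format = dateFormat)
  if (anyNA(dates))
    stop("unparseable date(s) at row(s): ",
         paste(utils::head(which(is.na(dates)), 10), collapse = ", "))
  block <- rep(NA_character_, nrow(raw))
  if (!is.null(schema$block) && schema$block %in% names(raw)) {
    block <- as.character(raw[[schema$block]])
  } else if (!is.null(schema$time) && schema$time %in% names(raw)) {
    block <- assignTimeBlock(raw[[schema$time]])
  }
  out <- data.frame(
    individual_id = as.character(raw[[schema$id]]),
    date = dates,
    time_block = block,
    x = x, y = y,
    stringsAsFactors = FALSE)
  out$scan_id <- paste(format(out$date), out$time_block, sep = "_")
  attr(out, "dropped") <- dropped
  out
}

#' Map clock times to scan blocks
#'
#' The daily scan schedule has three windows: morning 06:30-09:00, midday
#' 10:00-12:30, afternoon 15:00-17:30.  Times inside a window get that
#' block; times between windows are assigned to the nearest window edge
#' (ties to the earlier block) with a warning.
#'
#' @param times character "HH:MM" / "HH:MM:SS" times, or numeric minutes
#'   since midnight.
#' @return character vector of block labels.
#' @export
assignTimeBlock <- function(times) {
  if (is.character(times) || is.factor(times)) {
    parts <- strsplit(as.character(times), ":", fixed = TRUE)
    mins <- vapply(parts, function(p)
      as.numeric(p[1]) * 60 + as.numeric(p[2]), numeric(1))
  } else {
    mins <- as.numeric(times)
  }
  w <- .blockWindows
  dist <- vapply(seq_len(nrow(w)), function(k)
    pmax(w$start[k] - mins, mins - w$end[k], 0), numeric(length(mins)))
  dist <- matrix(dist, nrow = length(mins))
  pick <- apply(dist, 1, which.min)
  if (any(apply(dist, 1, min) > 0))
    warning(sum(apply(dist, 1, min) > 0),
            " time(s) outside the scan windows assigned to the nearest block")
  w$block[pick]
}

#' Fit an affine georeferencing transform
#'
#' Least-squares fit of the 6-parameter planar affine map
#' \eqn{x = a u + b v + c,\; y = d u + e v + f} from control-point pairs,
#' as used to georeference digitiser-grid coordinates into map metres.
#'
#' @param src two-column matrix of source (u, v) control points (>= 3,
#'   non-collinear).
#' @param dst two-column matrix of matching target (x, y) points.
#' @return an object of class `"affineTransform"`: list with elements
#'   a, b, c, d, e, f.
#' @export
fitAffine <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (nrow(src) < 3) stop("need at least 3 control points")
  X <- cbind(src, 1)
  qrX <- qr(X)
  if (qrX$rank < 3) stop("control points are collinear; affine fit is degenerate")
  beta <- unname(qr.coef(qrX, dst))
  tr <- list(a = beta[1, 1], b = beta[2, 1], c = beta[3, 1],
             d = beta[1, 2], e = beta[2, 2], f = beta[3, 2])
  class(tr) <- "affineTransform"
  tr
}

#' Apply an affine transform to points
#'
#' @param transform an `"affineTransform"` (or list with a..f).
#' @param pts two-column matrix of (u, v) points.
#' @return two-column matrix of (x, y) map coordinates.
#' @export
applyAffine <- function(transform, pts) {
  t <- transform
  if (abs(t$a * t$e - t$b * t$d) < .Machine$double.eps)
    stop("affine transform is not invertible (a*e - b*d = 0)")
  pts <- as.matrix(pts)
  cbind(x = t$a * pts[, 1] + t$b * pts[, 2] + t$c,
        y = t$d * pts[, 1] + t$e * pts[, 2] + t$f)
}

#' Label dates with season and sampling period
#'
#' Seasons are calendar-defined: cold = October-March, warm = April-September.
#' A two-year study starting at the beginning of a season comprises four
#' sampling periods (season x study year), labelled e.g. "Cold Season 1".
#'
#' @param dates Date vector.
#' @param studyStart Date the study began (first day of the first period).
#' @param studyDays length of the study window in days; dates outside
#'   `[studyStart, studyStart + studyDays)` raise an error.
#' @return data.frame with columns season ("cold"/"warm"), year_index and
#'   period (label).
#' @export
labelPeriod <- function(dates, studyStart, studyDays = 731) {
  dates <- as.Date(dates); studyStart <- as.Date(studyStart)
  if (length(dates) == 0)
    return(data.frame(season = character(0), year_index = integer(0),
                      period = character(0), stringsAsFactors = FALSE))
  off <- as.numeric(dates - studyStart)
  if (any(off < 0 | off >= studyDays))
    stop("date(s) outside the study window: ",
         paste(format(utils::head(dates[off < 0 | off >= studyDays], 5)),
               collapse = ", "))
  mo <- as.integer(format(dates, "%m"))
  yr <- as.integer(format(dates, "%Y"))
  season <- ifelse(mo >= 4 & mo <= 9, "warm", "cold")
  m0 <- as.integer(format(studyStart, "%m"))
  y0 <- as.integer(format(studyStart, "%Y"))
  monthsElapsed <- 12L * (yr - y0) + (mo - m0)
  yearIndex <- monthsElapsed %/% 12L + 1L
  data.frame(season = season, year_index = yearIndex,
             period = paste0(ifelse(season == "cold", "Cold", "Warm"),
                             " Season ", yearIndex),
             stringsAsFactors = FALSE)
}

#' Normalise locations against the exhibit boundary
#'
#' Labels each record with season/period, then resolves records lying
#' outside the boundary: points within `snapTolerance` metres of the
#' boundary (digitiser error) are snapped to the nearest boundary point,
#' farther points are dropped.  Counts of snapped and dropped records are
#' attached as attributes.
#'
#' @param records data.frame from [readLocations()] (or the same columns).
#' @param map an [ExhibitMap-class].
#' @param studyStart Date; defaults to the earliest record date.
#' @param studyDays study window length in days.
#' @param snapTolerance metres; default 1.
#' @return the labelled, in-bounds records with attributes `"snapped"` and
#'   `"dropped_oob"`.
#' @export
normalizeLocations <- function(records, map, studyStart = min(records$date),
                               studyDays = 731, snapTolerance = 1) {
  lab <- labelPeriod(records$date, studyStart, studyDays)
  records$season <- lab$season
  records$period <- lab$period
  bnd <- boundary(map)
  inside <- pointsInPolygon(records$x, records$y, bnd)
  snapped <- 0L
  drop <- rep(FALSE, nrow(records))
  for (i in which(!inside)) {
    if (distanceToPolygon(records$x[i], records$y[i], bnd) <= snapTolerance) {
      p <- nearestPointOnPolygon(records$x[i], records$y[i], bnd)
      records$x[i] <- p[1]; records$y[i] <- p[2]
      snapped <- snapped + 1L
    } else {
      drop[i] <- TRUE
    }
  }
  out <- records[!drop, , drop = FALSE]
  attr(out, "snapped") <- snapped
  attr(out, "dropped_oob") <- sum(drop)
  out
}
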