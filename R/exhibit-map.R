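#' @include AllClasses.R geometry-utils.R
NULL

#' Construct an ExhibitMap from polygons
#'
#' Builds and validates an [ExhibitMap-class]: feature polygons must lie
#' inside the boundary and must not overlap one another beyond
#' `tolerance` (in m^2).  Because exact polygon clipping is not needed for
#' a tolerance check, containment and overlap are assessed on a fine grid
#' of cell centres (cell edge `checkCell`, default 0.1 m).
#'
#' @param boundary two-column vertex matrix (metres).
#' @param featurePolygons named list of two-column vertex matrices; names are
#'   the feature codes.
#' @param featureNames optional named character vector of descriptive names.
#' @param tolerance maximum tolerated overlap / out-of-boundary area per
#'   feature, m^2.  Hand-digitised maps are imperfect; default 0.05.
#' @param checkCell grid cell edge (m) used for the tolerance checks.
#' @return a validated [ExhibitMap-class] object.
#' @export
ExhibitMap <- function(boundary, featurePolygons, featureNames = NULL,
                       tolerance = 0.05, checkCell = 0.1) {
  boundary <- as.matrix(boundary)
  storage.mode(boundary) <- "double"
  featurePolygons <- lapply(featurePolygons, function(p) {
    p <- as.matrix(p); storage.mode(p) <- "double"; p
  })
  codes <- names(featurePolygons)
  if (is.null(codes) || any(codes == ""))
    stop("featurePolygons must be a fully named list of polygons")
  if (is.null(featureNames)) {
    featureNames <- stats::setNames(codes, codes)
  } else {
    featureNames <- featureNames[codes]
    names(featureNames) <- codes
  }
  areas <- vapply(featurePolygons, polygonArea, numeric(1))

  # tolerance checks on a sampling grid of cell centres; the grid must span
  # the features too, or mass outside the boundary bbox would go unseen
  bb <- apply(do.call(rbind, c(list(boundary), featurePolygons)), 2, range)
  xs <- seq(bb[1, 1] + checkCell / 2, bb[2, 1], by = checkCell)
  ys <- seq(bb[1, 2] + checkCell / 2, bb[2, 2], by = checkCell)
  gx <- rep(xs, times = length(ys))
  gy <- rep(ys, each = length(xs))
  inB <- pointsInPolygon(gx, gy, boundary)
  hits <- integer(length(gx))
  outArea <- numeric(length(codes))
  for (k in seq_along(codes)) {
    inF <- pointsInPolygonStrict(gx, gy, featurePolygons[[k]])
    hits <- hits + inF
    outArea[k] <- sum(inF & !inB) * checkCell^2
  }
  overlapArea <- sum(hits > 1) * checkCell^2
  if (overlapArea > tolerance)
    stop(sprintf("feature polygons overlap by ~%.3f m^2 (> %.3f tolerance)",
                 overlapArea, tolerance))
  bad <- which(outArea > tolerance)
  if (length(bad))
    stop(sprintf("feature(s) %s extend outside the boundary beyond tolerance",
                 paste(codes[bad], collapse = ", ")))

  new("ExhibitMap", boundary = boundary, features = featurePolygons,
      featureNames = featureNames, featureAreas = areas)
}

#' Build a schematic ExhibitMap from a feature-area table
#'
#' Encodes a published feature table (code, name, area in m^2) as a
#' rectangular enclosure divided into vertical strips, one per feature, each
#' strip's area equal to the tabulated area.  The geometry is schematic —
#' a synthetic stand-in for the real enclosure's internal layout — but every
#' area- and availability-dependent quantity (expected use, electivity,
#' feature assignment proportions) is exact.
#'
#' @param table data.frame with columns `code`, `name`, `area_m2` (or a path
#'   to such a CSV).
#' @param height enclosure height in metres (strip width = area / height).
#' @return an [ExhibitMap-class] whose total area equals the table's sum.
#' @seealso [table1Exhibit()] for the packaged 12-feature table.
#' @export
exhibitFromFeatureTable <- function(table, height = 20) {
  if (is.character(table))
    table <- utils::read.csv(table, stringsAsFactors = FALSE)
  stopifnot(all(c("code", "area_m2") %in% names(table)))
  widths <- table$area_m2 / height
  x1 <- cumsum(widths)
  x0 <- c(0, x1[-length(x1)])
  polys <- stats::setNames(
    lapply(seq_len(nrow(table)),
           function(i) rectanglePolygon(x0[i], 0, x1[i], height)),
    table$code)
  nm <- if ("name" %in% names(table))
    stats::setNames(table$name, table$code) else NULL
  bnd <- rectanglePolygon(0, 0, sum(widths), height)
  ExhibitMap(bnd, polys, featureNames = nm)
}

#' The packaged 12-feature exhibit
#'
#' The schematic [ExhibitMap-class] built from the packaged 12-feature
#' area table (three beaches, three islands, three open-water sections, two
#' land strips and a shallow channel; 620.65 m^2 in total).
#'
#' @param height strip height in metres passed to [exhibitFromFeatureTable()].
#' @return an [ExhibitMap-class].
#' @export
table1Exhibit <- function(height = 20) {
  path <- system.file("extdata", "exhibit_features_table1.csv",
                      package = "ExhibitSpace", mustWork = TRUE)
  exhibitFromFeatureTable(path, height = height)
}

#' Load an exhibit map from GeoJSON sources
#'
#' Reads the enclosure boundary and (optionally) the feature polygons from
#' GeoJSON files.  The boundary file must contain at least one Polygon
#' feature (the first is used; only exterior rings are read).  The features
#' file must be a FeatureCollection of Polygons each carrying a `code`
#' property (and optionally `name`).  When `features` is instead a
#' feature-area table (data.frame or CSV path), schematic strip geometry is
#' generated with [exhibitFromFeatureTable()] and the GeoJSON boundary is
#' ignored for area arithmetic.
#'
#' @param boundary path to a GeoJSON file with the boundary polygon.
#' @param features path to a GeoJSON file of feature polygons, or a
#'   feature-area table / CSV path, or NULL to fall back to the packaged table.
#' @param ... passed to [ExhibitMap()] (tolerances).
#' @return an [ExhibitMap-class].
#' @export
loadExhibit <- function(boundary, features = NULL, ...) {
  bnd <- readGeoJSONPolygons(boundary)
  if (length(bnd$polygons) == 0)
    stop("no Polygon geometry found in boundary source: ", boundary)
  if (is.null(features))
    return(table1Exhibit())
  if (is.character(features) && grepl("\\.csv$", features, ignore.case = TRUE))
    return(exhibitFromFeatureTable(features))
  if (is.data.frame(features))
    return(exhibitFromFeatureTable(features))
  ft <- readGeoJSONPolygons(features)
  if (length(ft$polygons) == 0)
    stop("no Polygon geometry found in features source: ", features)
  codes <- ft$properties$code
  if (is.null(codes))
    stop("feature GeoJSON must carry a 'code' property per feature")
  polys <- stats::setNames(ft$polygons, codes)
  nms <- ft$properties$name
  if (!is.null(nms)) nms <- stats::setNames(nms, codes)
  ExhibitMap(bnd$polygons[[1]], polys, featureNames = nms, ...)
}

# Parse Polygon features (exterior rings) out of a GeoJSON file or string.
readGeoJSONPolygons <- function(src) {
  g <- jsonlite::fromJSON(src, simplifyVector = FALSE)
  feats <- switch(g$type %||% "",
    FeatureCollection = g$features,
    Feature = list(g),
    Polygon = list(list(geometry = g, properties = NULL)),
    stop("unsupported GeoJSON type: ", g$type))
  polys <- list(); props <- list()
  for (f in feats) {
    geom <- f$geometry
    if (is.null(geom) || !identical(geom$type, "Polygon")) next
    ring <- geom$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    # drop the GeoJSON closing vertex; our polygons close implicitly
    if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    colnames(m) <- c("x", "y")
    polys[[length(polys) + 1]] <- m
    props[[length(props) + 1]] <- f$properties
  }
  propDF <- NULL
  if (length(props) && !is.null(props[[1]])) {
    keys <- unique(unlist(lapply(props, names)))
    propDF <- as.data.frame(
      stats::setNames(lapply(keys, function(k)
        vapply(props, function(p) as.character(p[[k]] %||% NA), character(1))),
        keys), stringsAsFactors = FALSE)
  }
  list(polygons = polys, properties = propDF)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assign a location to an exhibit feature
#'
#' Returns the feature code containing each point.  Points on a shared edge
#' go to the first-listed feature; points inside the boundary but in a gap
#' sliver between features are assigned to the nearest feature outline
#' within `gapTolerance` metres, beyond which assignment fails.
#'
#' @param x,y numeric vectors of point coordinates (metres).
#' @param map an [ExhibitMap-class].
#' @param gapTolerance metres; default 0.5.
#' @return character vector of feature codes.
#' @export
assignFeature <- function(x, y, map, gapTolerance = 0.5) {
  polys <- features(map)
  codes <- names(polys)
  out <- rep(NA_character_, length(x))
  remaining <- rep(TRUE, length(x))
  for (k in seq_along(polys)) {
    if (!any(remaining)) break
    idx <- which(remaining)
    hit <- pointsInPolygon(x[idx], y[idx], polys[[k]])
    out[idx[hit]] <- codes[k]
    remaining[idx[hit]] <- FALSE
  }
  for (i in which(remaining)) {
    d <- vapply(polys, function(p) distanceToPolygon(x[i], y[i], p), numeric(1))
    if (min(d) <= gapTolerance) {
      out[i] <- codes[which.min(d)]
    } else {
      stop(sprintf("point (%.2f, %.2f) is %.2f m from every feature (> %.2f tolerance)",
                   x[i], y[i], min(d), gapTolerance))
    }
  }
  out
}

#' Feature table with areas and availability
#'
#' @param map an [ExhibitMap-class].
#' @return data.frame with columns code, name, area_m2 and percent_exhibit
#'   (availability on the 0-100 scale).
#' @export
featureTable <- function(map) {
  a <- featureAreas(map)
  data.frame(code = names(a),
             name = unname(map@featureNames[names(a)]),
             area_m2 = unname(a),
             percent_exhibit = unname(100 * a / sum(a)),
             stringsAsFactors = FALSE, row.names = NULL)
}
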