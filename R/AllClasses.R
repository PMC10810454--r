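#' @import methods
NULL

#' ExhibitMap: a bounded enclosure with named features
#'
#' An `ExhibitMap` holds the enclosure boundary polygon (planar metre
#' coordinates) together with a set of named, non-overlapping feature
#' polygons (beaches, islands, water sections, ...), their areas and their
#' availability proportions.  Availability \eqn{p_i} is each feature's share
#' of the summed feature area, the "expected use" of electivity analysis.
#'
#' Feature polygons may be genuine digitised geometry or schematic stand-in
#' rectangles that reproduce a published feature-area table (see
#' [exhibitFromFeatureTable()]); all downstream area and availability
#' arithmetic only depends on the polygon areas.
#'
#' @slot boundary two-column numeric matrix of boundary vertices (x, y), metres.
#' @slot features named list of two-column vertex matrices, one per feature
#'   code, in a fixed order used for tie-breaking in point assignment.
#' @slot featureNames named character vector, code -> descriptive name.
#' @slot featureAreas named numeric vector, code -> planar area in m^2.
#'
#' @seealso [loadExhibit()], [exhibitFromFeatureTable()], [assignFeature()]
#' @export
setClass("ExhibitMap",
  representation(
    boundary = "matrix",
    features = "list",
    featureNames = "character",
    featureAreas = "numeric"
  )
)

setValidity("ExhibitMap", function(object) {
  msg <- character()
  if (ncol(object@boundary) != 2 || nrow(object@boundary) < 3)
    msg <- c(msg, "boundary must be a >=3-row, 2-column vertex matrix")
  codes <- names(object@features)
  if (is.null(codes) || anyDuplicated(codes))
    msg <- c(msg, "features must be a uniquely named list")
  if (!identical(codes, names(object@featureAreas)))
    msg <- c(msg, "featureAreas names must match feature codes")
  if (any(object@featureAreas <= 0))
    msg <- c(msg, "every feature must have positive area")
  p <- object@featureAreas / sum(object@featureAreas)
  if (abs(sum(p) - 1) > 1e-9)
    msg <- c(msg, "availability proportions must sum to 1")
  if (length(msg)) msg else TRUE
})

#' UtilizationDistribution: a gridded probability density of space use
#'
#' A kernel density estimate of one individual's space use in one sampling
#' period, discretised on a regular grid.  Cell (iy, ix) of the `density`
#' matrix holds the density (per m^2) at centre
#' (x0 + (ix - 1/2) * cellSize, y0 + (iy - 1/2) * cellSize).  Densities sum
#' to 1 after multiplying by the cell area, and are exactly zero in cells
#' whose centres fall outside the enclosure boundary (the barrier).
#'
#' @slot individual character, individual id.
#' @slot period character, sampling-period label (e.g. "Cold Season 1").
#' @slot origin numeric length 2, (x0, y0) of the grid's lower-left corner, metres.
#' @slot cellSize numeric, grid cell edge length in metres.
#' @slot density numeric matrix (rows index y, columns index x), density per m^2.
#' @slot inBounds logical matrix, TRUE where the cell centre is inside the boundary.
#' @slot bandwidth numeric, the kernel bandwidth h (metres) used.
#' @slot nLocations integer, number of locations the estimate is based on.
#'
#' @seealso [estimateUD()], [isopleth()], [udoi()]
#' @export
setClass("UtilizationDistribution",
  representation(
    individual = "character",
    period = "character",
    origin = "numeric",
    cellSize = "numeric",
    density = "matrix",
    inBounds = "matrix",
    bandwidth = "numeric",
    nLocations = "integer"
  )
)

setValidity("UtilizationDistribution", function(object) {
  msg <- character()
  if (length(object@origin) != 2) msg <- c(msg, "origin must be length 2")
  if (object@cellSize <= 0) msg <- c(msg, "cellSize must be positive")
  if (!identical(dim(object@density), dim(object@inBounds)))
    msg <- c(msg, "density and inBounds dimensions differ")
  if (any(object@density < 0)) msg <- c(msg, "densities must be non-negative")
  if (any(object@density[!object@inBounds] != 0))
    msg <- c(msg, "density must be zero outside the boundary")
  total <- sum(object@density) * object@cellSize^2
  if (abs(total - 1) > 1e-6)
    msg <- c(msg, sprintf("density must integrate to 1 (got %.8f)", total))
  if (length(msg)) msg else TRUE
})

#' RangeEstimate: an isopleth region of a utilization distribution
#'
#' The smallest set of grid cells (by density ordering) whose cumulative
#' probability reaches `level`: the 95% isopleth is the home range, the 50%
#' isopleth the core area.  The mask is aligned to the parent UD's grid and
#' the area is the masked cell count times the cell area.
#'
#' @slot individual,period as in the parent [UtilizationDistribution-class].
#' @slot level numeric in (0, 1), the isopleth level.
#' @slot mask logical matrix on the parent grid.
#' @slot area numeric, m^2.
#' @slot origin,cellSize grid geometry copied from the parent UD.
#' @export
setClass("RangeEstimate",
  representation(
    individual = "character",
    period = "character",
    level = "numeric",
    mask = "matrix",
    area = "numeric",
    origin = "numeric",
    cellSize = "numeric"
  )
)

setValidity("RangeEstimate", function(object) {
  msg <- character()
  if (object@level <= 0 || object@level >= 1)
    msg <- c(msg, "level must lie strictly between 0 and 1")
  if (abs(object@area - sum(object@mask) * object@cellSize^2) > 1e-9)
    msg <- c(msg, "area must equal masked cell count times cell area")
  if (length(msg)) msg else TRUE
})
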