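#' @include AllClasses.R
NULL

#' Accessors for spatial classes
#'
#' Small accessor generics for [ExhibitMap-class],
#' [UtilizationDistribution-class] and [RangeEstimate-class] objects:
#' `boundary()` returns the boundary vertex matrix, `features()` the named
#' list of feature polygons, `featureAreas()` the areas (m^2),
#' `availability()` the availability proportions \eqn{p_i} (summing to 1),
#' `udDensity()` the density matrix, `gridOrigin()` and `cellSize()` the
#' grid geometry, `rangeMask()` the isopleth cell mask, `rangeArea()` its
#' area in m^2 and `isoLevel()` its level.
#'
#' @param x an object of the documented classes.
#' @return see Description; accessors never copy-modify their argument.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("boundary", function(x) standardGeneric("boundary"))
#' @rdname accessors
#' @export
setGeneric("features", function(x) standardGeneric("features"))
#' @rdname accessors
#' @export
setGeneric("featureAreas", function(x) standardGeneric("featureAreas"))
#' @rdname accessors
#' @export
setGeneric("availability", function(x) standardGeneric("availability"))
#' @rdname accessors
#' @export
setGeneric("udDensity", function(x) standardGeneric("udDensity"))
#' @rdname accessors
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))
#' @rdname accessors
#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))
#' @rdname accessors
#' @export
setGeneric("rangeMask", function(x) standardGeneric("rangeMask"))
#' @rdname accessors
#' @export
setGeneric("rangeArea", function(x) standardGeneric("rangeArea"))
#' @rdname accessors
#' @export
setGeneric("isoLevel", function(x) standardGeneric("isoLevel"))

#' @rdname accessors
setMethod("boundary", "ExhibitMap", function(x) x@boundary)
#' @rdname accessors
setMethod("features", "ExhibitMap", function(x) x@features)
#' @rdname accessors
setMethod("featureAreas", "ExhibitMap", function(x) x@featureAreas)
#' @rdname accessors
setMethod("availability", "ExhibitMap",
          function(x) x@featureAreas / sum(x@featureAreas))
#' @rdname accessors
setMethod("udDensity", "UtilizationDistribution", function(x) x@density)
#' @rdname accessors
setMethod("gridOrigin", "UtilizationDistribution", function(x) x@origin)
#' @rdname accessors
setMethod("cellSize", "UtilizationDistribution", function(x) x@cellSize)
#' @rdname accessors
setMethod("gridOrigin", "RangeEstimate", function(x) x@origin)
#' @rdname accessors
setMethod("cellSize", "RangeEstimate", function(x) x@cellSize)
#' @rdname accessors
setMethod("rangeMask", "RangeEstimate", function(x) x@mask)
#' @rdname accessors
setMethod("rangeArea", "RangeEstimate", function(x) x@area)
#' @rdname accessors
setMethod("isoLevel", "RangeEstimate", function(x) x@level)

setMethod("show", "ExhibitMap", function(object) {
  a <- featureAreas(object)
  cat("ExhibitMap:", length(a), "features,",
      sprintf("%.2f m^2 total\n", sum(a)))
  cat(" codes:", paste(names(a), collapse = " "), "\n")
})

setMethod("show", "UtilizationDistribution", function(object) {
  d <- dim(object@density)
  cat("UtilizationDistribution:", object@individual,
      "/", object@period, "\n")
  cat(sprintf(" grid %d x %d cells at %.3g m, h = %.3g m, n = %d\n",
              d[2], d[1], object@cellSize, object@bandwidth,
              object@nLocations))
})

setMethod("show", "RangeEstimate", function(object) {
  cat(sprintf("RangeEstimate: %s / %s, %.0f%% isopleth, %.2f m^2 (%d cells)\n",
              object@individual, object@period, 100 * object@level,
              object@area, sum(object@mask)))
})
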