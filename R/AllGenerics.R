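#' Grid geometry accessors
#'
#' @param x a grid object.
#' @return \code{gridOrigin}: numeric(2) lower-left corner in metres;
#'   \code{gridCellSize}: cell edge in metres; \code{gridDim}: c(nrow, ncol).
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

#' @rdname gridOrigin
#' @export
setGeneric("gridCellSize", function(x) standardGeneric("gridCellSize"))

#' @rdname gridOrigin
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' Extract a named layer as a matrix
#'
#' @param x a grid object.
#' @param name layer name (a slot holding a matrix or, for monthly
#'   climatology, one of "tmean", "tmin", "precip" with a month index).
#' @param ... further arguments for methods (e.g. \code{month}).
#' @return a numeric matrix.
#' @export
setGeneric("gridLayer", function(x, name, ...) standardGeneric("gridLayer"))

#' Names of the layers a grid carries
#' @param x a grid object.
#' @return character vector of layer names.
#' @export
setGeneric("layerNames", function(x) standardGeneric("layerNames"))

#' Area fractions of a vegetation map as a three-column matrix
#' @param x a \linkS4class{VegetationMap}.
#' @return matrix with columns pinusPumila, snowbed, fellfield (one row per cell).
#' @export
setGeneric("communityFractions",
  function(x) standardGeneric("communityFractions"))

#' Observation table of a territory data set
#' @param x a \linkS4class{TerritoryObservations}.
#' @return the underlying data.frame.
#' @export
setGeneric("observations", function(x) standardGeneric("observations"))

#' Habitat area accounting
#'
#' Cell counts, square kilometres and percent-of-reference for the habitat
#' cells of a projection or ensemble summary.
#'
#' @param object a \linkS4class{HabitatProjection} or
#'   \linkS4class{EnsembleSummary}.
#' @param currentReference reference area in km^2 (usually the
#'   current-climate habitat area) used for the percentage column; NA to
#'   omit percentages.
#' @return data.frame with columns scenario, habitatCells, habitatKm2,
#'   pctOfCurrent (percent, rounded to one decimal).
#' @export
setGeneric("habitatAreaSummary",
  function(object, currentReference = NA_real_)
    standardGeneric("habitatAreaSummary"))
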