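#' @import methods
NULL

## Grid conventions used throughout:
##   - layers are plain numeric matrices, nrow x ncol
##   - row index i increases with northing (y), column index j with easting (x)
##   - cell (i, j) has centre x = origin[1] + (j - 0.5) * cellSize,
##                         y = origin[2] + (i - 0.5) * cellSize
## All grids of one landscape share an origin; resolutions nest exactly.

#' Virtual parent of all gridded containers
#'
#' Carries the shared geometry: the lower-left corner of the domain
#' (`origin`, metres) and the cell edge length (`cellSize`, metres).
#' Concrete subclasses add one matrix (or array) per layer; all layers of an
#' object share the same dimensions and geometry.
#'
#' @slot origin numeric(2), x and y of the lower-left domain corner in metres.
#' @slot cellSize numeric(1), cell edge length in metres.
#' @exportClass AlpineGrid
setClass("AlpineGrid", representation("VIRTUAL",
  origin = "numeric", cellSize = "numeric"))

setValidity("AlpineGrid", function(object) {
  if (length(object@origin) != 2L || anyNA(object@origin))
    return("origin must be numeric(2)")
  if (length(object@cellSize) != 1L || !is.finite(object@cellSize) ||
      object@cellSize <= 0)
    return("cellSize must be a single positive number")
  TRUE
})

#' Elevation grid
#'
#' A digital elevation model on the fine (terrain) lattice.
#'
#' @slot elevation matrix of elevations in metres.
#' @exportClass ElevationGrid
setClass("ElevationGrid", contains = "AlpineGrid",
  representation(elevation = "matrix"))

setValidity("ElevationGrid", function(object) {
  if (!is.numeric(object@elevation)) return("elevation must be numeric")
  if (any(object@elevation < 0, na.rm = TRUE))
    return("elevations must be nonnegative")
  TRUE
})

#' Monthly climatology grid
#'
#' Monthly mean and minimum temperature and monthly precipitation on the
#' coarse climate lattice. Temperature arrays are nrow x ncol x 12 in deg C,
#' precipitation in mm per month. Invariants: the monthly minimum never
#' exceeds the monthly mean in any cell-month, and precipitation is
#' nonnegative.
#'
#' @slot tmean 3-d array, monthly mean temperature (deg C).
#' @slot tmin 3-d array, monthly mean daily minimum temperature (deg C).
#' @slot precip 3-d array, monthly precipitation (mm).
#' @exportClass ClimateGrid
setClass("ClimateGrid", contains = "AlpineGrid",
  representation(tmean = "array", tmin = "array", precip = "array"))

setValidity("ClimateGrid", function(object) {
  d <- dim(object@tmean)
  if (length(d) != 3L || d[3] != 12L)
    return("tmean must be an nrow x ncol x 12 array")
  if (!identical(d, dim(object@tmin)) || !identical(d, dim(object@precip)))
    return("tmean, tmin and precip must share dimensions")
  if (any(object@tmin > object@tmean + 1e-9, na.rm = TRUE))
    return("monthly minimum temperature exceeds monthly mean")
  if (any(object@precip < 0, na.rm = TRUE))
    return("precipitation must be nonnegative")
  TRUE
})

#' Bioclimatic index grid
#'
#' The four bioclimatic predictors of the vegetation-zone model, per climate
#' cell: warmth index WI (deg C month), coldest-month minimum temperature TMC
#' (deg C), May-September precipitation PRS (mm) and maximum snow-water
#' equivalent MSW (mm).
#'
#' @slot wi matrix, warmth index.
#' @slot tmc matrix, minimum temperature of the coldest month.
#' @slot prs matrix, summer precipitation.
#' @slot msw matrix, maximum snow-water equivalent.
#' @exportClass BioclimGrid
setClass("BioclimGrid", contains = "AlpineGrid",
  representation(wi = "matrix", tmc = "matrix", prs = "matrix",
    msw = "matrix"))

setValidity("BioclimGrid", function(object) {
  d <- dim(object@wi)
  for (s in c("tmc", "prs", "msw"))
    if (!identical(d, dim(slot(object, s))))
      return("all index layers must share dimensions")
  if (any(object@wi < 0, na.rm = TRUE)) return("WI must be nonnegative")
  if (any(object@prs < 0, na.rm = TRUE)) return("PRS must be nonnegative")
  if (any(object@msw < 0, na.rm = TRUE)) return("MSW must be nonnegative")
  TRUE
})

#' Terrain predictor grid
#'
#' The DEM plus the five topographic predictors of the area-fraction model.
#' Slope is in degrees; aspect in compass degrees clockwise from north
#' (NA on flat cells); curvature is signed, convex-up positive, in 1/m;
#' TWI is dimensionless; ridge distance in metres (0 exactly on ridge cells).
#'
#' @slot elevation,slope,aspect,curvature,twi,ridgeDistance matrices.
#' @slot ridgeMask logical matrix marking drainage-divide (ridge) cells.
#' @exportClass TerrainGrid
setClass("TerrainGrid", contains = "AlpineGrid",
  representation(elevation = "matrix", slope = "matrix", aspect = "matrix",
    curvature = "matrix", twi = "matrix", ridgeDistance = "matrix",
    ridgeMask = "matrix"))

setValidity("TerrainGrid", function(object) {
  d <- dim(object@elevation)
  for (s in c("slope", "aspect", "curvature", "twi", "ridgeDistance",
              "ridgeMask"))
    if (!identical(d, dim(slot(object, s))))
      return("all terrain layers must share dimensions")
  sl <- object@slope
  if (any(sl < 0 | sl >= 90, na.rm = TRUE))
    return("slope must lie in [0, 90)")
  asp <- object@aspect
  if (any(asp < 0 | asp >= 360, na.rm = TRUE))
    return("aspect must lie in [0, 360) or be NA on flat cells")
  rd <- object@ridgeDistance
  if (any(rd < 0, na.rm = TRUE)) return("ridge distance must be nonnegative")
  if (any(rd[object@ridgeMask] != 0, na.rm = TRUE))
    return("ridge distance must be 0 on ridge cells")
  TRUE
})

#' Vegetation community area-fraction map
#'
#' Per fine cell, the area fraction in [0,1] covered by each of the three
#' alpine communities: Pinus pumila scrub, snowbed grassland and fellfield.
#' Fractions sum to at most 1 in every cell.
#'
#' @slot pinusPumila,snowbed,fellfield matrices of fractions.
#' @exportClass VegetationMap
setClass("VegetationMap", contains = "AlpineGrid",
  representation(pinusPumila = "matrix", snowbed = "matrix",
    fellfield = "matrix"))

setValidity("VegetationMap", function(object) {
  d <- dim(object@pinusPumila)
  if (!identical(d, dim(object@snowbed)) ||
      !identical(d, dim(object@fellfield)))
    return("community layers must share dimensions")
  tot <- object@pinusPumila + object@snowbed + object@fellfield
  lo <- min(object@pinusPumila, object@snowbed, object@fellfield, na.rm = TRUE)
  if (lo < -1e-9) return("fractions must be nonnegative")
  if (any(tot > 1 + 1e-9, na.rm = TRUE))
    return("community fractions must sum to at most 1 per cell")
  TRUE
})

#' One GCM climate-change scenario
#'
#' Coarse anomaly fields from one general circulation model: additive
#' temperature differences (separately for monthly means and monthly
#' minimums) and multiplicative precipitation ratios, on the scenario's
#' native coarse lattice. Applied to a baseline climatology by bilinear
#' interpolation (delta method).
#'
#' @slot name scenario label.
#' @slot deltaMean matrix, additive anomaly for monthly mean temperature (deg C).
#' @slot deltaMin matrix, additive anomaly for monthly minimum temperature (deg C).
#' @slot precipRatio matrix, multiplicative precipitation ratio (> 0).
#' @exportClass GcmScenario
setClass("GcmScenario", contains = "AlpineGrid",
  representation(name = "character", deltaMean = "matrix",
    deltaMin = "matrix", precipRatio = "matrix"))

setValidity("GcmScenario", function(object) {
  d <- dim(object@deltaMean)
  if (!identical(d, dim(object@deltaMin)) ||
      !identical(d, dim(object@precipRatio)))
    return("anomaly fields must share dimensions")
  if (any(object@precipRatio <= 0, na.rm = TRUE))
    return("precipitation ratios must be positive")
  TRUE
})

#' Territory presence/absence observations
#'
#' One row per surveyed territory-grid cell: presence (0/1), number of
#' surveys (>= 1), aggregated community area fractions and mean ridge
#' distance. Cells never surveyed are excluded.
#'
#' @slot data data.frame with columns cellRow, cellCol, presence, nSurveys,
#'   afPp, afSg, afFf, dr.
#' @slot cellSize territory cell edge in metres.
#' @slot origin numeric(2) domain lower-left corner.
#' @exportClass TerritoryObservations
setClass("TerritoryObservations",
  representation(data = "data.frame", origin = "numeric",
    cellSize = "numeric"))

setValidity("TerritoryObservations", function(object) {
  need <- c("cellRow", "cellCol", "presence", "nSurveys",
            "afPp", "afSg", "afFf", "dr")
  if (!all(need %in% names(object@data)))
    return(paste("data must contain columns:", paste(need, collapse = ", ")))
  d <- object@data
  if (nrow(d) && any(d$nSurveys < 1))
    return("included cells must have at least one survey")
  if (nrow(d) && !all(d$presence %in% c(0, 1)))
    return("presence must be 0/1")
  fr <- c(d$afPp, d$afSg, d$afFf)
  if (length(fr) && (min(fr) < -1e-9 || max(fr) > 1 + 1e-9))
    return("area fractions must lie in [0, 1]")
  TRUE
})

#' Fitted vegetation-zone occurrence model
#'
#' An additive logistic model of alpine-zone presence on the climate lattice,
#' with a bivariate thin-plate smooth of (WI, TMC) and univariate smooths of
#' PRS and MSW.
#'
#' @slot fit the underlying \code{mgcv::gam} fit.
#' @slot training the training table used.
#' @slot metrics list with training AUC, sensitivity, specificity, threshold.
#' @exportClass ZoneModel
setClass("ZoneModel",
  representation(fit = "ANY", training = "data.frame", metrics = "list"))

#' Fitted area-fraction forests
#'
#' One random-forest regressor per alpine community, mapping the five
#' topographic predictors plus zone occurrence probability to the community
#' area fraction.
#'
#' @slot forests named list of three \code{randomForest} fits.
#' @slot importance data.frame of increased-MSE permutation importance.
#' @slot oob named numeric, out-of-bag MSE per community.
#' @slot seed integer seed the forests were grown with.
#' @exportClass FractionModels
setClass("FractionModels",
  representation(forests = "list", importance = "data.frame",
    oob = "numeric", seed = "integer"))

setValidity("FractionModels", function(object) {
  if (!identical(sort(names(object@forests)),
                 sort(c("pinusPumila", "snowbed", "fellfield"))))
    return("forests must be named pinusPumila, snowbed, fellfield")
  TRUE
})

#' Fitted territory habitat model
#'
#' An additive logistic model of territory presence with a bivariate smooth
#' of (ridge distance, P. pumila fraction), univariate smooths of the
#' fellfield and snowbed fractions, and a log-survey-count offset. The
#' training threshold is chosen so that at least the configured share of
#' presences (default 95\%) falls inside predicted habitat.
#'
#' @slot fit the underlying \code{mgcv::gam} fit.
#' @slot threshold numeric habitat threshold on effort-standardised probabilities.
#' @slot referenceEffort survey count at which predictions are standardised.
#' @slot metrics list: training AUC, sensitivity, specificity, cutoff.
#' @slot training the observation table used.
#' @exportClass HabitatModel
setClass("HabitatModel",
  representation(fit = "ANY", threshold = "numeric",
    referenceEffort = "numeric", metrics = "list", training = "data.frame"))

#' One scenario's habitat projection
#'
#' The cascade output for a single climate scenario: zone probabilities on
#' the climate lattice, community fractions on the fine lattice, and habitat
#' probability / binary habitat on the territory lattice, with area totals.
#'
#' @slot scenarioName label.
#' @slot zoneProbability matrix at climate resolution.
#' @slot fractions a \linkS4class{VegetationMap}.
#' @slot habitatProbability matrix at territory resolution.
#' @slot habitatBinary logical matrix, \code{habitatProbability >= threshold}.
#' @slot threshold the (frozen) training threshold used.
#' @slot cellSize territory cell edge, metres.
#' @slot origin numeric(2).
#' @exportClass HabitatProjection
setClass("HabitatProjection",
  representation(scenarioName = "character", zoneProbability = "matrix",
    fractions = "VegetationMap", habitatProbability = "matrix",
    habitatBinary = "matrix", threshold = "numeric", cellSize = "numeric",
    origin = "numeric"))

setValidity("HabitatProjection", function(object) {
  if (!identical(dim(object@habitatProbability),
                 dim(object@habitatBinary)))
    return("probability and binary grids must share dimensions")
  expect <- object@habitatProbability >= object@threshold
  if (!identical(expect, object@habitatBinary))
    return("habitatBinary must equal habitatProbability >= threshold")
  TRUE
})

#' Ensemble summary over climate scenarios
#'
#' Cell-wise median habitat probability over the scenario ensemble, the
#' median-based binary habitat at the frozen training threshold, the
#' per-cell count of scenarios under which habitat is sustained, and the
#' area table.
#'
#' @slot medianProbability matrix at territory resolution.
#' @slot medianBinary logical matrix.
#' @slot agreementCount integer matrix in [0, nScenarios].
#' @slot areas data.frame: scenario, habitatCells, habitatKm2, pctOfCurrent.
#' @slot threshold numeric.
#' @slot nScenarios integer.
#' @slot cellSize numeric, metres.
#' @exportClass EnsembleSummary
setClass("EnsembleSummary",
  representation(medianProbability = "matrix", medianBinary = "matrix",
    agreementCount = "matrix", areas = "data.frame", threshold = "numeric",
    nScenarios = "integer", cellSize = "numeric"))

setValidity("EnsembleSummary", function(object) {
  ac <- object@agreementCount
  if (any(ac < 0 | ac > object@nScenarios, na.rm = TRUE))
    return("agreement counts must lie in [0, nScenarios]")
  TRUE
})
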