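#' @include habitat-model.R
NULL

#' Project one climate scenario through the full cascade
#'
#' Delta-downscales the scenario onto the baseline climatology, recomputes
#' the bioclimatic indices (same daily-synthesis seed as the baseline),
#' predicts zone occurrence, community fractions and territory habitat
#' probability, and thresholds at the habitat model's frozen training
#' threshold. Topographic predictors are held constant across scenarios.
#'
#' @param scenario a \linkS4class{GcmScenario} (use
#'   \code{\link{identityScenario}} for the current-climate projection).
#' @param baseline the current \linkS4class{ClimateGrid}.
#' @param terrain a \linkS4class{TerrainGrid}.
#' @param zoneModel,fractionModels,habitatModel the fitted cascade; all
#'   three must be supplied.
#' @param snowParams,daily the snow model and daily-synthesis settings used
#'   for the baseline indices.
#' @param territoryResolutionM territory cell edge (m).
#' @return a \linkS4class{HabitatProjection}.
#' @export
projectScenario <- function(scenario, baseline, terrain, zoneModel,
                            fractionModels, habitatModel,
                            snowParams = snowModelParams(),
                            daily = dailySynthesisConfig(),
                            territoryResolutionM = 300) {
  if (missing(zoneModel) || missing(fractionModels) ||
      missing(habitatModel) || is.null(zoneModel) ||
      is.null(fractionModels) || is.null(habitatModel))
    stop("pipeline incomplete: all three fitted models are required")
  future <- applyGcmDelta(baseline, scenario)
  bioclim <- computeBioclim(future, snowParams, daily)
  fac <- baseline@cellSize / terrain@cellSize
  zoneFine <- predictZoneProbability(zoneModel, bioclim, fineFactor = fac)
  zoneCoarse <- predictZoneProbability(zoneModel, bioclim)
  fractions <- predictFractions(fractionModels, terrain, zoneFine)
  agg <- aggregatePredictors(fractions, terrain, territoryResolutionM)
  p <- predictHabitatProbability(habitatModel, agg)
  sh <- gridShape(ncol(terrain@elevation) * terrain@cellSize,
                  nrow(terrain@elevation) * terrain@cellSize,
                  territoryResolutionM)
  pGrid <- matrix(p, sh[1], sh[2])
  thr <- habitatModel@threshold
  new("HabitatProjection", scenarioName = scenario@name,
      zoneProbability = zoneCoarse, fractions = fractions,
      habitatProbability = pGrid, habitatBinary = pGrid >= thr,
      threshold = thr, cellSize = territoryResolutionM,
      origin = terrain@origin)
}

#' Ensemble summary over scenario projections
#'
#' Cell-wise median habitat probability (even member counts average the two
#' central order statistics), binary habitat from the same frozen training
#' threshold, and per-cell agreement counts. With a \code{current}
#' projection supplied, agreement counts scenarios under which currently
#' suitable habitat is sustained (current AND future habitat); without one,
#' they count scenarios predicting habitat. Results do not depend on the
#' order of the scenario list.
#'
#' @param projections list of \linkS4class{HabitatProjection} sharing
#'   geometry and threshold.
#' @param current optional current-climate \linkS4class{HabitatProjection}.
#' @return an \linkS4class{EnsembleSummary}.
#' @export
ensembleMedian <- function(projections, current = NULL) {
  if (!length(projections)) stop("no projections supplied")
  thr <- projections[[1]]@threshold
  d <- dim(projections[[1]]@habitatProbability)
  probs <- vapply(projections, function(p) p@habitatProbability,
                  matrix(0, d[1], d[2]))
  med <- apply(probs, c(1, 2), stats::median)
  agree <- Reduce(`+`, lapply(projections, function(p)
    matrix(as.integer(p@habitatBinary), d[1], d[2])))
  if (!is.null(current))
    agree <- agree * matrix(as.integer(current@habitatBinary), d[1], d[2])
  cellKm2 <- cellAreaKm2(projections[[1]]@cellSize)
  areas <- data.frame(
    scenario = c(vapply(projections, function(p) p@scenarioName,
                        character(1)), "ensembleMedian"),
    habitatCells = c(vapply(projections, function(p)
      sum(p@habitatBinary), numeric(1)), sum(med >= thr)))
  areas$habitatKm2 <- areas$habitatCells * cellKm2
  new("EnsembleSummary", medianProbability = med, medianBinary = med >= thr,
      agreementCount = agree, areas = areas, threshold = thr,
      nScenarios = length(projections),
      cellSize = projections[[1]]@cellSize)
}

#' @rdname habitatAreaSummary
setMethod("habitatAreaSummary", "HabitatProjection",
  function(object, currentReference = NA_real_) {
    cells <- sum(object@habitatBinary)
    km2 <- cells * cellAreaKm2(object@cellSize)
    data.frame(scenario = object@scenarioName, habitatCells = cells,
               habitatKm2 = km2,
               pctOfCurrent = if (is.na(currentReference)) NA_real_
                 else percentOfReference(km2, currentReference))
  })

#' @rdname habitatAreaSummary
setMethod("habitatAreaSummary", "EnsembleSummary",
  function(object, currentReference = NA_real_) {
    out <- object@areas
    out$pctOfCurrent <- if (is.na(currentReference)) NA_real_
      else percentOfReference(out$habitatKm2, currentReference)
    out
  })
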