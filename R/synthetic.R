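#' @include climate.R terrain.R
NULL

#' Synthetic landscape configuration
#'
#' Geometry and physical parameters of the generated study system. The
#' default domain is 12 km (E-W) by 18 km (N-S), tiled exactly by the 100-m
#' terrain lattice, the 1-km climate lattice and the 300-m territory
#' lattice.
#'
#' @param domainWidthM,domainHeightM domain extents (m); every resolution
#'   must divide them evenly.
#' @param terrainResolutionM fine (terrain/vegetation) cell edge (m).
#' @param climateResolutionM coarse climate cell edge (m); an integer
#'   multiple of the terrain resolution.
#' @param territoryResolutionM territory cell edge (m); an integer multiple
#'   of the terrain resolution.
#' @param ruggedness dimensionless amplitude of the whole terrain relief
#'   (ridge spine plus smoothed random field); 0 gives a constant-elevation
#'   grid, 1 a crest reaching just below the configured peak.
#' @param peakElevationM highest elevation of the ridge spine (m).
#' @param lapseRateCPerKm temperature lapse rate (deg C per km, positive =
#'   cooling with elevation).
#' @param seed integer master seed for the generators.
#' @return a validated list of class settings.
#' @export
landscapeConfig <- function(domainWidthM = 12000, domainHeightM = 18000,
                            terrainResolutionM = 100,
                            climateResolutionM = 1000,
                            territoryResolutionM = 300,
                            ruggedness = 1.0, peakElevationM = 3000,
                            lapseRateCPerKm = 6.0, seed = 1L) {
  if (any(c(domainWidthM, domainHeightM, terrainResolutionM,
            climateResolutionM, territoryResolutionM) <= 0))
    stop("invalid configuration: extents and resolutions must be positive")
  for (res in c(terrainResolutionM, climateResolutionM,
                territoryResolutionM))
    gridShape(domainWidthM, domainHeightM, res)   # errors if not tiling
  for (res in c(climateResolutionM, territoryResolutionM))
    if (res %% terrainResolutionM != 0)
      stop("invalid configuration: coarse resolutions must be integer ",
           "multiples of the terrain resolution")
  list(domainWidthM = domainWidthM, domainHeightM = domainHeightM,
       terrainResolutionM = terrainResolutionM,
       climateResolutionM = climateResolutionM,
       territoryResolutionM = territoryResolutionM,
       ruggedness = ruggedness, peakElevationM = peakElevationM,
       lapseRateCPerKm = lapseRateCPerKm, seed = as.integer(seed))
}

#' Generative ground truth of the synthetic ecosystem
#'
#' The known response functions every fitting stage should recover.
#' \code{zoneResponse} are logistic coefficients of alpine-zone occurrence
#' on the four bioclimatic indices (WI effect negative: warmth excludes the
#' zone; MSW effect positive: snow sustains it). \code{fractionResponses}
#' scale the per-community cover responses to zone suitability and terrain
#' (ridge distance dominates P. pumila; zone suitability dominates snowbed
#' and fellfield). \code{habitatResponse} are logistic coefficients of
#' per-survey territory occupancy on aggregated fractions and ridge
#' distance. \code{noiseSd} are additive latent-scale noise s.d.s.
#'
#' @param zoneResponse named list: intercept, wi, tmc, prs, msw.
#' @param fractionResponses named list of per-community parameter lists.
#' @param habitatResponse named list: intercept, afPp, afSg, afFf, drPerM.
#' @param noiseSd named list: climate (deg C), vegetation (fraction),
#'   precipRel (relative).
#' @return list of class truth parameters.
#' @export
trueResponseParams <- function(
    zoneResponse = list(intercept = 4.5, wi = -0.45, tmc = 0.0, prs = 0.0,
                        msw = 0.001),
    fractionResponses = list(
      pinusPumila = list(maxCover = 0.50, drScaleM = 250),
      snowbed = list(maxCover = 0.28, twiWeight = 0.4),
      fellfield = list(maxCover = 0.20, curvWeight = 0.4)),
    habitatResponse = list(intercept = -6.0, afPp = 16.0, afSg = 5.0,
                           afFf = 5.0, drPerM = -0.0015),
    noiseSd = list(climate = 0.3, vegetation = 0.03, precipRel = 0.1)) {
  list(zoneResponse = zoneResponse, fractionResponses = fractionResponses,
       habitatResponse = habitatResponse, noiseSd = noiseSd)
}

#' Generate a synthetic DEM
#'
#' A north-south ridge spine through the domain centre (crest elevation
#' undulating just below the configured peak) with flanks decaying towards
#' the domain edges, plus a smoothed seeded random field; \code{ruggedness}
#' scales the whole relief. The spine guarantees a connected locus of local
#' maxima so ridge extraction has a known answer. Deterministic given the
#' seed.
#'
#' @param config a \code{\link{landscapeConfig}}.
#' @return an \linkS4class{ElevationGrid} on the fine lattice.
#' @export
generateDem <- function(config) {
  sh <- gridShape(config$domainWidthM, config$domainHeightM,
                  config$terrainResolutionM)
  nr <- sh[1]; nc <- sh[2]
  cc <- cellCenters(nr, nc, c(0, 0), config$terrainResolutionM)
  x <- matrix(cc$x, nr, nc, byrow = TRUE)
  y <- matrix(cc$y, nr, nc)
  w <- config$domainWidthM; h <- config$domainHeightM
  crest <- 0.95 + 0.04 * sin(2 * pi * y / h * 1.5)        # of peak elevation
  flank <- exp(-((x - w / 2) / (0.30 * w))^2)
  base <- config$peakElevationM * crest * flank
  noise <- withSeed(deriveSeed(config$seed, "dem"), {
    ## coarse white noise, bilinearly refined then mean-smoothed twice
    ctrl <- matrix(stats::rnorm(ceiling(nr / 10) * ceiling(nc / 10)),
                   ceiling(nr / 10), ceiling(nc / 10))
    f <- bilinearInterpolate(ctrl, c(0, 0), 10 * config$terrainResolutionM,
                             cc$x, cc$y)
    for (i in 1:2) {
      s <- .shifts(f)
      f <- Reduce(`+`, unlist(s, recursive = FALSE)) / 9
    }
    f
  })
  z <- config$ruggedness * (base + 0.08 * config$peakElevationM * noise)
  z <- pmin(pmax(z, 0), config$peakElevationM)
  new("ElevationGrid", origin = c(0, 0),
      cellSize = config$terrainResolutionM, elevation = z)
}

#' Generate a monthly climatology over a DEM
#'
#' Elevation is block-averaged to the climate lattice; monthly mean
#' temperature is the sea-level value minus lapse rate times elevation (km)
#' plus seeded noise; monthly minimums sit a fixed diurnal offset below the
#' means (never above); precipitation scales with a mild orographic factor
#' and stays nonnegative. Defaults emulate a maritime temperate mountain
#' climate with snowy winters.
#'
#' @param dem an \linkS4class{ElevationGrid} on the fine lattice.
#' @param config a \code{\link{landscapeConfig}}.
#' @param seaLevelMonthlyMeans,seaLevelMonthlyMins numeric(12), deg C.
#' @param monthlyPrecipMeans numeric(12), mm.
#' @param truth \code{\link{trueResponseParams}} (noise levels).
#' @return a \linkS4class{ClimateGrid} on the climate lattice.
#' @export
generateClimatology <- function(dem, config,
    seaLevelMonthlyMeans = c(2.7, 3.2, 6.4, 12.3, 17.2, 20.8, 24.8, 26.3,
                             22.2, 16.3, 10.5, 5.3),
    seaLevelMonthlyMins = seaLevelMonthlyMeans - 6,
    monthlyPrecipMeans = c(180, 120, 130, 110, 120, 170, 200, 130, 180, 130,
                           120, 190),
    truth = trueResponseParams()) {
  .check12(seaLevelMonthlyMeans, "seaLevelMonthlyMeans")
  .check12(seaLevelMonthlyMins, "seaLevelMonthlyMins")
  .check12(monthlyPrecipMeans, "monthlyPrecipMeans")
  fac <- config$climateResolutionM / config$terrainResolutionM
  elev <- blockAggregate(dem@elevation, fac)
  nr <- nrow(elev); nc <- ncol(elev)
  elevKm <- elev / 1000
  sdC <- truth$noiseSd$climate
  sdP <- truth$noiseSd$precipRel
  arr <- function() array(0, c(nr, nc, 12))
  tmean <- arr(); tmin <- arr(); precip <- arr()
  withSeed(deriveSeed(config$seed, "climatology"), {
    for (m in 1:12) {
      nzM <- if (sdC > 0) matrix(stats::rnorm(nr * nc, 0, sdC), nr, nc) else 0
      tmean[, , m] <- seaLevelMonthlyMeans[m] -
        config$lapseRateCPerKm * elevKm + nzM
      tmin[, , m] <- pmin(
        seaLevelMonthlyMins[m] - config$lapseRateCPerKm * elevKm +
          (if (sdC > 0) matrix(stats::rnorm(nr * nc, 0, sdC), nr, nc) else 0),
        tmean[, , m])
      nzP <- if (sdP > 0) matrix(stats::rnorm(nr * nc, 0, sdP), nr, nc) else 0
      precip[, , m] <- pmax(0, monthlyPrecipMeans[m] *
                              (1 + 0.3 * elevKm) * (1 + nzP))
    }
  })
  new("ClimateGrid", origin = dem@origin,
      cellSize = config$climateResolutionM,
      tmean = tmean, tmin = tmin, precip = precip)
}

#' Generate an ensemble of synthetic GCM anomaly scenarios
#'
#' Each scenario carries coarse fields of additive temperature anomalies
#' (for monthly means and minimums) and multiplicative precipitation ratios.
#' Scenario-level mean warming is spread evenly over the requested range;
#' mild spatial structure is added within each field and clipped to the
#' stated bounds. Deterministic given the seed.
#'
#' @param nScenarios number of ensemble members (>= 1).
#' @param warmingRange numeric(2), min and max temperature anomaly (deg C).
#' @param precipRatioRange numeric(2), min and max precipitation ratio.
#' @param coarseShape integer(2), rows x cols of the scenario lattice.
#' @param domainWidthM,domainHeightM extent the scenarios must cover (m).
#' @param seed integer.
#' @return list of \linkS4class{GcmScenario}.
#' @export
generateGcmAnomalies <- function(nScenarios, warmingRange = c(1.5, 5.0),
                                 precipRatioRange = c(0.9, 1.15),
                                 coarseShape = c(3L, 2L),
                                 domainWidthM = 12000, domainHeightM = 18000,
                                 seed = 1L) {
  if (nScenarios < 1) stop("invalid configuration: nScenarios must be >= 1")
  nr <- coarseShape[1]; nc <- coarseShape[2]
  ## lattice padded one cell beyond the domain so cell centres bracket it
  cs <- max(domainWidthM / nc, domainHeightM / nr) * 1.5
  origin <- c((domainWidthM - nc * cs) / 2, (domainHeightM - nr * cs) / 2)
  levels <- if (nScenarios == 1) mean(warmingRange) else
    seq(warmingRange[1], warmingRange[2], length.out = nScenarios)
  spatialSd <- diff(warmingRange) * 0.05
  withSeed(seed, lapply(seq_len(nScenarios), function(i) {
    clipT <- function(f) matrix(pmin(pmax(f, warmingRange[1]),
                                     warmingRange[2]), nr, nc)
    dMean <- clipT(levels[i] + stats::rnorm(nr * nc, 0, spatialSd))
    dMin <- clipT(dMean + stats::rnorm(nr * nc, 0, spatialSd))
    r0 <- stats::runif(1, precipRatioRange[1], precipRatioRange[2])
    ratio <- matrix(pmin(pmax(r0 + stats::rnorm(nr * nc, 0,
                                 diff(precipRatioRange) * 0.05),
                              precipRatioRange[1]), precipRatioRange[2]),
                    nr, nc)
    new("GcmScenario", name = sprintf("gcm%02d", i), origin = origin,
        cellSize = cs, deltaMean = dMean, deltaMin = dMin,
        precipRatio = ratio)
  }))
}

#' True zone-occurrence probability from the generative parameters
#'
#' @param bioclim a \linkS4class{BioclimGrid}.
#' @param truth \code{\link{trueResponseParams}}.
#' @return matrix of probabilities at climate resolution.
#' @export
trueZoneProbability <- function(bioclim, truth = trueResponseParams()) {
  z <- truth$zoneResponse
  stats::plogis(z$intercept + z$wi * bioclim@wi + z$tmc * bioclim@tmc +
                z$prs * bioclim@prs + z$msw * bioclim@msw)
}

## True community fractions (no noise) from zone suitability and terrain.
.trueFractions <- function(zoneFine, terrain, truth) {
  fr <- truth$fractionResponses
  dr <- terrain@ridgeDistance
  tw <- terrain@twi
  cv <- terrain@curvature
  twS <- stats::plogis((tw - stats::median(tw)) / max(stats::sd(tw), 1e-6))
  cvS <- stats::plogis(-(cv - stats::median(cv)) / max(stats::sd(cv), 1e-6))
  out <- list(
    pinusPumila = fr$pinusPumila$maxCover * zoneFine *
      exp(-dr / fr$pinusPumila$drScaleM),
    snowbed = fr$snowbed$maxCover * zoneFine *
      (1 - fr$snowbed$twiWeight + fr$snowbed$twiWeight * twS),
    fellfield = fr$fellfield$maxCover * zoneFine *
      (1 - fr$fellfield$curvWeight + fr$fellfield$curvWeight * cvS))
  ## minimum mapping unit: cover too sparse to digitise is mapped as absent
  lapply(out, function(f) { f[f < 0.005] <- 0; f })
}

#' Generate a synthetic vegetation map
#'
#' Applies the true community response functions to zone suitability (from
#' the true zone model on the bioclim grid, replicated to the fine lattice)
#' and terrain, adds truncated Gaussian noise, and enforces per-cell
#' fraction sums of at most 1.
#'
#' @param bioclim a \linkS4class{BioclimGrid} at climate resolution.
#' @param terrain a \linkS4class{TerrainGrid} at fine resolution.
#' @param truth \code{\link{trueResponseParams}}.
#' @param seed integer.
#' @return a \linkS4class{VegetationMap}; attribute \code{"trueFractions"}
#'   holds the noise-free truth for validation.
#' @export
generateVegetation <- function(bioclim, terrain,
                               truth = trueResponseParams(), seed = 1L) {
  fac <- bioclim@cellSize / terrain@cellSize
  if (fac != round(fac)) stop("grids do not nest")
  zoneFine <- disaggregateNearest(trueZoneProbability(bioclim, truth), fac)
  tf <- .trueFractions(zoneFine, terrain, truth)
  sdV <- truth$noiseSd$vegetation
  d <- dim(zoneFine)
  ## noise only where the community truly occurs: absent stays exactly 0,
  ## as in a digitised vegetation map, so any-cover zone labels stay meaningful
  noisy <- withSeed(seed, lapply(tf, function(f) {
    g <- f + (if (sdV > 0)
      matrix(stats::rnorm(prod(d), 0, sdV), d[1], d[2]) * (f > 1e-6) else 0)
    pmin(pmax(g, 0), 1)
  }))
  tot <- noisy$pinusPumila + noisy$snowbed + noisy$fellfield
  over <- tot > 1
  if (any(over)) {
    sc <- ifelse(over, 1 / tot, 1)
    noisy <- lapply(noisy, function(f) f * sc)
  }
  out <- new("VegetationMap", origin = terrain@origin,
             cellSize = terrain@cellSize,
             pinusPumila = noisy$pinusPumila, snowbed = noisy$snowbed,
             fellfield = noisy$fellfield)
  attr(out, "trueFractions") <- tf
  out
}

#' True per-survey territory occupancy probability
#'
#' @param afPp,afSg,afFf,dr aggregated predictors (fractions and metres).
#' @param truth \code{\link{trueResponseParams}}.
#' @return probabilities in (0, 1).
#' @export
trueHabitatProbability <- function(afPp, afSg, afFf, dr,
                                   truth = trueResponseParams()) {
  h <- truth$habitatResponse
  stats::plogis(h$intercept + h$afPp * afPp + h$afSg * afSg +
                h$afFf * afFf + h$drPerM * dr)
}

#' Generate synthetic territory observations
#'
#' Aggregates the vegetation map and ridge distance to the territory
#' lattice, evaluates the true per-survey occupancy probability p, and draws
#' presence as Bernoulli with detection probability
#' \code{1 - (1 - p)^nSurveys} (each survey an independent chance to record
#' the territory). Cells with zero surveys are excluded.
#'
#' @param vegetation a \linkS4class{VegetationMap} at fine resolution.
#' @param terrain a \linkS4class{TerrainGrid} at fine resolution.
#' @param truth \code{\link{trueResponseParams}}.
#' @param surveysPerCell integer scalar, vector (one per territory cell,
#'   column-major), or matrix; 0 excludes a cell. Default: seeded draws of
#'   1-5 surveys per cell.
#' @param territoryResolutionM territory cell edge (m).
#' @param seed integer.
#' @return a \linkS4class{TerritoryObservations}; attribute \code{"pTrue"}
#'   holds the per-survey truth for included cells.
#' @export
generateTerritories <- function(vegetation, terrain,
                                truth = trueResponseParams(),
                                surveysPerCell = NULL,
                                territoryResolutionM = 300, seed = 1L) {
  agg <- aggregatePredictors(vegetation, terrain, territoryResolutionM)
  n <- nrow(agg)
  if (is.null(surveysPerCell)) {
    surveys <- withSeed(deriveSeed(seed, "surveys"),
                        sample(1:5, n, replace = TRUE))
  } else {
    surveys <- rep(as.vector(surveysPerCell), length.out = n)
  }
  if (any(surveys < 0)) stop("invalid input: negative survey counts")
  pTrue <- trueHabitatProbability(agg$afPp, agg$afSg, agg$afFf, agg$dr,
                                  truth)
  pDet <- 1 - (1 - pTrue)^surveys
  pres <- withSeed(deriveSeed(seed, "territories"),
                   stats::rbinom(n, 1, pDet))
  keep <- surveys >= 1
  d <- data.frame(cellRow = agg$cellRow, cellCol = agg$cellCol,
                  presence = pres, nSurveys = surveys,
                  afPp = agg$afPp, afSg = agg$afSg, afFf = agg$afFf,
                  dr = agg$dr)[keep, , drop = FALSE]
  rownames(d) <- NULL
  out <- new("TerritoryObservations", data = d, origin = vegetation@origin,
             cellSize = territoryResolutionM)
  attr(out, "pTrue") <- pTrue[keep]
  out
}

#' Generate the complete synthetic study system
#'
#' Convenience wrapper running DEM, terrain, climatology, bioclim,
#' vegetation and territory generation with one configuration; every stage
#' is seeded from \code{config$seed}.
#'
#' @param config \code{\link{landscapeConfig}}.
#' @param truth \code{\link{trueResponseParams}}.
#' @param snowParams \code{\link{snowModelParams}}.
#' @param daily \code{\link{dailySynthesisConfig}}; defaults to a seed
#'   derived from the master seed.
#' @return list with dem, terrain, climate, bioclim, vegetation,
#'   territories, plus the inputs (config, truth, snowParams, daily).
#' @export
generateLandscape <- function(config = landscapeConfig(),
                              truth = trueResponseParams(),
                              snowParams = snowModelParams(),
                              daily = dailySynthesisConfig(
                                seed = deriveSeed(config$seed, "daily"))) {
  dem <- generateDem(config)
  terrain <- computeTerrain(dem)
  climate <- generateClimatology(dem, config, truth = truth)
  bioclim <- computeBioclim(climate, snowParams, daily)
  vegetation <- generateVegetation(bioclim, terrain, truth,
                                   seed = deriveSeed(config$seed, "veg"))
  territories <- generateTerritories(vegetation, terrain, truth,
                                     territoryResolutionM =
                                       config$territoryResolutionM,
                                     seed = deriveSeed(config$seed, "terr"))
  list(dem = dem, terrain = terrain, climate = climate, bioclim = bioclim,
       vegetation = vegetation, territories = territories, config = config,
       truth = truth, snowParams = snowParams, daily = daily)
}
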