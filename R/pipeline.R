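#' @include projection.R
NULL

#' Full pipeline run configuration
#'
#' One declarative object driving every stage; a single master seed expands
#' deterministically into per-stage seeds. Round-trips losslessly through
#' YAML (\code{\link{writeRunConfig}} / \code{\link{readRunConfig}}).
#'
#' @param landscape \code{\link{landscapeConfig}}.
#' @param truth \code{\link{trueResponseParams}}.
#' @param snow \code{\link{snowModelParams}}.
#' @param model list: k2, k1 (smooth basis dims), nTrees, maxRows (forest
#'   training subsample), cutoff (threshold sensitivity).
#' @param ensemble list: nScenarios, warmingRange, precipRatioRange,
#'   coarseShape.
#' @param seed master seed.
#' @return nested configuration list.
#' @export
runConfig <- function(landscape = landscapeConfig(),
                      truth = trueResponseParams(),
                      snow = snowModelParams(),
                      model = list(k2 = 25L, k1 = 10L, nTrees = 500L,
                                   maxRows = 5000L, cutoff = 0.95),
                      ensemble = list(nScenarios = 24L,
                                      warmingRange = c(1.5, 5.0),
                                      precipRatioRange = c(0.9, 1.15),
                                      coarseShape = c(3L, 2L)),
                      seed = 1L) {
  list(landscape = landscape, truth = truth, snow = snow, model = model,
       ensemble = ensemble, seed = as.integer(seed))
}

#' @rdname runConfig
#' @param config a configuration from \code{runConfig}.
#' @param path YAML file path.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname runConfig
#' @export
readRunConfig <- function(path) yaml::read_yaml(path)

.need <- function(path) {
  if (!file.exists(path))
    stop("dependency error: missing upstream artifact '", path, "'")
  path
}

.writeVeg <- function(veg, dir, prefix) {
  for (cm in c("pinusPumila", "snowbed", "fellfield"))
    writeAsciiGrid(slot(veg, cm),
                   file.path(dir, paste0(prefix, "_", cm, ".asc")),
                   veg@origin, veg@cellSize)
}

#' Run the modelling pipeline
#'
#' Orchestrates the stages \code{simulate} (synthetic landscape, climate,
#' scenarios, territories), \code{derive} (terrain predictors, bioclim
#' indices), \code{fit} (zone, fraction and habitat models), \code{project}
#' (scenario ensemble and summaries) and \code{report} (run manifest).
#' Stage outputs are written under \code{outputDir} (grids as ESRI ASCII,
#' tables as CSV, scenarios/metrics as JSON, fitted models as RDS with a
#' JSON sidecar); a stage run later in a fresh session reloads what it
#' needs from these artifacts and fails with a dependency error naming any
#' absent file. The manifest records inputs, outputs (with MD5 content
#' hashes), seeds and metric summaries, but no timestamps, so identical
#' configurations yield identical manifests.
#'
#' @param config \code{\link{runConfig}}.
#' @param stages subset of simulate, derive, fit, project, report.
#' @param outputDir directory for artifacts (created if needed).
#' @return the manifest list, invisibly.
#' @export
runPipeline <- function(config = runConfig(),
                        stages = c("simulate", "derive", "fit", "project",
                                   "report"),
                        outputDir = tempfile("alpcascade_run_")) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  lc <- config$landscape
  lc$seed <- deriveSeed(config$seed, "landscape")
  daily <- dailySynthesisConfig(seed = deriveSeed(config$seed, "daily"))
  st <- new.env(parent = emptyenv())
  manifest <- list(config = config, seeds = list(master = config$seed),
                   outputs = character(0), metrics = list())
  addOut <- function(...) {
    manifest$outputs <<- unique(c(manifest$outputs, file.path(outputDir, c(...))))
  }

  if ("simulate" %in% stages) {
    st$dem <- generateDem(lc)
    st$terrainPre <- computeTerrain(st$dem)
    st$climate <- generateClimatology(st$dem, lc, truth = config$truth)
    st$bioclimPre <- computeBioclim(st$climate, config$snow, daily)
    st$vegetation <- generateVegetation(st$bioclimPre, st$terrainPre,
                                        config$truth,
                                        seed = deriveSeed(config$seed, "veg"))
    st$territories <- generateTerritories(
      st$vegetation, st$terrainPre, config$truth,
      territoryResolutionM = lc$territoryResolutionM,
      seed = deriveSeed(config$seed, "terr"))
    st$scenarios <- generateGcmAnomalies(
      config$ensemble$nScenarios, config$ensemble$warmingRange,
      config$ensemble$precipRatioRange, config$ensemble$coarseShape,
      lc$domainWidthM, lc$domainHeightM,
      seed = deriveSeed(config$seed, "gcm"))
    writeAsciiGrid(st$dem@elevation, file.path(outputDir, "dem.asc"),
                   st$dem@origin, st$dem@cellSize)
    .writeVeg(st$vegetation, outputDir, "vegetation")
    utils::write.csv(st$territories@data,
                     file.path(outputDir, "territories.csv"),
                     row.names = FALSE)
    jsonlite::write_json(lapply(st$scenarios, function(s) list(
      name = s@name, origin = s@origin, cellSize = s@cellSize,
      shape = dim(s@deltaMean), deltaMean = as.vector(s@deltaMean),
      deltaMin = as.vector(s@deltaMin),
      precipRatio = as.vector(s@precipRatio))),
      file.path(outputDir, "scenarios.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(list(tmean = as.vector(st$climate@tmean),
                              tmin = as.vector(st$climate@tmin),
                              precip = as.vector(st$climate@precip),
                              dim = dim(st$climate@tmean),
                              origin = st$climate@origin,
                              cellSize = st$climate@cellSize),
                         file.path(outputDir, "climate.json"), digits = NA)
    jsonlite::write_json(config$truth, file.path(outputDir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    addOut("dem.asc", "territories.csv", "scenarios.json", "climate.json",
           "truth.json",
           paste0("vegetation_", c("pinusPumila", "snowbed", "fellfield"),
                  ".asc"))
  }

  loadClimate <- function() {
    if (is.null(st$climate)) {
      j <- jsonlite::read_json(.need(file.path(outputDir, "climate.json")),
                               simplifyVector = TRUE)
      st$climate <- new("ClimateGrid", origin = j$origin,
                        cellSize = j$cellSize,
                        tmean = array(j$tmean, j$dim),
                        tmin = array(j$tmin, j$dim),
                        precip = array(j$precip, j$dim))
    }
    st$climate
  }
  loadDem <- function() {
    if (is.null(st$dem)) {
      g <- readAsciiGrid(.need(file.path(outputDir, "dem.asc")))
      st$dem <- new("ElevationGrid", origin = g$origin,
                    cellSize = g$cellSize, elevation = g$values)
    }
    st$dem
  }

  if ("derive" %in% stages) {
    st$terrain <- computeTerrain(loadDem())
    st$bioclim <- computeBioclim(loadClimate(), config$snow, daily)
    for (ly in c("slope", "aspect", "curvature", "twi", "ridgeDistance"))
      writeAsciiGrid(slot(st$terrain, ly),
                     file.path(outputDir, paste0("terrain_", ly, ".asc")),
                     st$terrain@origin, st$terrain@cellSize)
    for (ly in c("wi", "tmc", "prs", "msw"))
      writeAsciiGrid(slot(st$bioclim, ly),
                     file.path(outputDir, paste0("bioclim_", ly, ".asc")),
                     st$bioclim@origin, st$bioclim@cellSize)
    addOut(paste0("terrain_", c("slope", "aspect", "curvature", "twi",
                                "ridgeDistance"), ".asc"),
           paste0("bioclim_", c("wi", "tmc", "prs", "msw"), ".asc"))
  }

  loadVeg <- function() {
    if (is.null(st$vegetation)) {
      g <- lapply(c("pinusPumila", "snowbed", "fellfield"), function(cm)
        readAsciiGrid(.need(file.path(outputDir,
                                      paste0("vegetation_", cm, ".asc")))))
      st$vegetation <- new("VegetationMap", origin = g[[1]]$origin,
                           cellSize = g[[1]]$cellSize,
                           pinusPumila = g[[1]]$values,
                           snowbed = g[[2]]$values, fellfield = g[[3]]$values)
    }
    st$vegetation
  }
  loadTerrain <- function() {
    if (is.null(st$terrain)) st$terrain <- computeTerrain(loadDem())
    st$terrain
  }
  loadBioclim <- function() {
    if (is.null(st$bioclim))
      st$bioclim <- computeBioclim(loadClimate(), config$snow, daily)
    st$bioclim
  }

  if ("fit" %in% stages) {
    terr <- loadTerrain(); bc <- loadBioclim(); veg <- loadVeg()
    if (is.null(st$territories)) {
      tf <- .need(file.path(outputDir, "territories.csv"))
      st$territories <- new("TerritoryObservations",
                            data = utils::read.csv(tf),
                            origin = veg@origin,
                            cellSize = lc$territoryResolutionM)
    }
    mc <- config$model
    zt <- makeZoneLabels(veg, bc)
    st$zoneModel <- fitZoneModel(zt, mc$k2, mc$k1, mc$cutoff)
    fac <- bc@cellSize / terr@cellSize
    zoneFine <- predictZoneProbability(st$zoneModel, bc, fineFactor = fac)
    tabs <- lapply(stats::setNames(nm = c("pinusPumila", "snowbed",
                                          "fellfield")), function(cm)
      fractionTrainingTable(terr, zoneFine, veg, cm))
    st$fractionModels <- fitFractionModels(
      tabs, nTrees = mc$nTrees, seed = deriveSeed(config$seed, "rf"),
      maxRows = mc$maxRows)
    st$habitatModel <- fitHabitatModel(st$territories, mc$k2, mc$k1,
                                       mc$cutoff,
                                       seed = deriveSeed(config$seed, "boot"))
    st$iov <- iovAkaike(st$territories, mc$k2, mc$k1)
    models <- list(zone = st$zoneModel, fractions = st$fractionModels,
                   habitat = st$habitatModel)
    saveRDS(models, file.path(outputDir, "models.rds"))
    utils::write.csv(st$fractionModels@importance,
                     file.path(outputDir, "importance.csv"),
                     row.names = FALSE)
    utils::write.csv(st$iov$models, file.path(outputDir, "iov_models.csv"),
                     row.names = FALSE)
    manifest$metrics$zone <- st$zoneModel@metrics
    manifest$metrics$habitat <- st$habitatModel@metrics
    manifest$metrics$iov <- as.list(st$iov$iov)
    ## Spearman validation of the fraction models on their training cells
    manifest$metrics$spearman <- lapply(
      stats::setNames(nm = names(tabs)), function(cm) {
        pr <- stats::predict(st$fractionModels@forests[[cm]],
                             tabs[[cm]][, .fractionPredictors])
        spearmanRho(pr, tabs[[cm]]$fraction)$rho
      })
    jsonlite::write_json(list(zone = st$zoneModel@metrics,
                              habitat = st$habitatModel@metrics,
                              iov = as.list(st$iov$iov),
                              spearman = manifest$metrics$spearman,
                              terms = list(zone = "s(wi,tmc)+s(prs)+s(msw)",
                                habitat = "s(dr,afPp)+s(afFf)+s(afSg)+offset(log(nSurveys))")),
                         file.path(outputDir, "model_metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    addOut("models.rds", "importance.csv", "iov_models.csv",
           "model_metrics.json")
  }

  if ("project" %in% stages) {
    if (is.null(st$zoneModel)) {
      models <- readRDS(.need(file.path(outputDir, "models.rds")))
      st$zoneModel <- models$zone
      st$fractionModels <- models$fractions
      st$habitatModel <- models$habitat
    }
    if (is.null(st$scenarios)) {
      j <- jsonlite::read_json(.need(file.path(outputDir, "scenarios.json")),
                               simplifyVector = TRUE, simplifyDataFrame = FALSE)
      st$scenarios <- lapply(j, function(s)
        new("GcmScenario", name = s$name, origin = unlist(s$origin),
            cellSize = s$cellSize,
            deltaMean = matrix(unlist(s$deltaMean), s$shape[[1]]),
            deltaMin = matrix(unlist(s$deltaMin), s$shape[[1]]),
            precipRatio = matrix(unlist(s$precipRatio), s$shape[[1]])))
    }
    base <- loadClimate(); terr <- loadTerrain()
    proj1 <- function(sc) projectScenario(
      sc, base, terr, st$zoneModel, st$fractionModels, st$habitatModel,
      config$snow, daily, lc$territoryResolutionM)
    st$current <- proj1(identityScenario(base))
    st$projections <- lapply(st$scenarios, proj1)
    st$summary <- ensembleMedian(st$projections, current = st$current)
    curKm2 <- sum(st$current@habitatBinary) *
      cellAreaKm2(lc$territoryResolutionM)
    areas <- habitatAreaSummary(st$summary,
                                currentReference = max(curKm2, 1e-12))
    utils::write.csv(areas, file.path(outputDir, "habitat_areas.csv"),
                     row.names = FALSE)
    writeAsciiGrid(st$summary@medianProbability,
                   file.path(outputDir, "ensemble_median_probability.asc"),
                   terr@origin, lc$territoryResolutionM)
    writeAsciiGrid(st$summary@agreementCount + 0,
                   file.path(outputDir, "ensemble_agreement.asc"),
                   terr@origin, lc$territoryResolutionM)
    manifest$metrics$currentHabitatKm2 <- curKm2
    manifest$metrics$medianFutureHabitatKm2 <-
      areas$habitatKm2[areas$scenario == "ensembleMedian"]
    addOut("habitat_areas.csv", "ensemble_median_probability.asc",
           "ensemble_agreement.asc")
  }

  if ("report" %in% stages) {
    existing <- manifest$outputs[file.exists(manifest$outputs)]
    manifest$hashes <- as.list(tools::md5sum(existing))
    jsonlite::write_json(manifest[c("seeds", "metrics", "hashes")],
                         file.path(outputDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  manifest$outputDir <- outputDir
  manifest$state <- st
  invisible(manifest)
}
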