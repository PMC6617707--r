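# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# Default synthetic landscape with the full fitted cascade.
fittedCascade <- function() {
  if (is.null(.fixtures$cascade)) {
    L <- generateLandscape(landscapeConfig(seed = 42L))
    zt <- makeZoneLabels(L$vegetation, L$bioclim)
    zm <- suppressWarnings(fitZoneModel(zt))
    fac <- L$bioclim@cellSize / L$terrain@cellSize
    zf <- predictZoneProbability(zm, L$bioclim, fineFactor = fac)
    tabs <- lapply(stats::setNames(nm = c("pinusPumila", "snowbed",
                                          "fellfield")), function(cm)
      fractionTrainingTable(L$terrain, zf, L$vegetation, cm))
    fm <- fitFractionModels(tabs, nTrees = 300L, seed = 7L, maxRows = 4000L)
    hm <- fitHabitatModel(L$territories, seed = 5L)
    cur <- projectScenario(identityScenario(L$climate), L$climate,
                           L$terrain, zm, fm, hm, L$snowParams, L$daily,
                           L$config$territoryResolutionM)
    .fixtures$cascade <- list(L = L, zoneTable = zt, zoneModel = zm,
                              zoneFine = zf, fractionTables = tabs,
                              fractionModels = fm, habitatModel = hm,
                              current = cur)
  }
  .fixtures$cascade
}

# A small flat-terrain stand-in where only ridge distance matters, for
# territory-generator checks that need many independent cells.
flatTerrain <- function(nr, nc, cellSize = 100, rd = 0) {
  z <- matrix(0, nr, nc)
  new("TerrainGrid", origin = c(0, 0), cellSize = cellSize, elevation = z,
      slope = z, aspect = z + NA_real_, curvature = z, twi = z,
      ridgeDistance = z + rd, ridgeMask = matrix(rd == 0, nr, nc))
}

uniformVegetation <- function(nr, nc, pp, sg, ff, cellSize = 100) {
  new("VegetationMap", origin = c(0, 0), cellSize = cellSize,
      pinusPumila = matrix(pp, nr, nc), snowbed = matrix(sg, nr, nc),
      fellfield = matrix(ff, nr, nc))
}

# Minimal constant climatology for downscaling tests.
constantClimate <- function(nr = 3, nc = 2, tmean = 10, tminOffset = 5,
                            precip = 100, cellSize = 1000) {
  new("ClimateGrid", origin = c(0, 0), cellSize = cellSize,
      tmean = array(tmean, c(nr, nc, 12)),
      tmin = array(tmean - tminOffset, c(nr, nc, 12)),
      precip = array(precip, c(nr, nc, 12)))
}
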