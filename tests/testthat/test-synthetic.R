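test_that("landscape configuration enforces tiling and nesting invariants", {
  expect_error(landscapeConfig(domainWidthM = -1), "positive")
  expect_error(landscapeConfig(terrainResolutionM = 130), "evenly")
  expect_error(landscapeConfig(territoryResolutionM = 250), "multiple|evenly")
  cfg <- landscapeConfig()
  expect_equal(cfg$territoryResolutionM %% cfg$terrainResolutionM, 0)
})

test_that("DEM generation is deterministic, bounded and ridge-structured", {
  cfg <- landscapeConfig(seed = 1L)
  d1 <- generateDem(cfg)
  d2 <- generateDem(cfg)
  expect_identical(d1@elevation, d2@elevation)
  expect_true(all(d1@elevation >= 0 &
                  d1@elevation <= cfg$peakElevationM))
  expect_gte(max(d1@elevation), 0.9 * cfg$peakElevationM)
  # zero relief: constant-elevation grid
  flat <- generateDem(landscapeConfig(ruggedness = 0))
  expect_equal(length(unique(as.vector(flat@elevation))), 1L)
  # different seeds differ
  d3 <- generateDem(landscapeConfig(seed = 2L))
  expect_false(identical(d1@elevation, d3@elevation))
})

test_that("climatology follows the lapse rate and keeps minimums below means", {
  cfg <- landscapeConfig()
  dem <- generateDem(cfg)
  noiseFree <- trueResponseParams(noiseSd = list(climate = 0,
                                                 vegetation = 0,
                                                 precipRel = 0))
  cl <- generateClimatology(dem, cfg, truth = noiseFree)
  fac <- cfg$climateResolutionM / cfg$terrainResolutionM
  elev <- blockAggregate(dem@elevation, fac)
  # July mean at 1000 m with sea-level 24.8 and 6 deg/km: 18.8
  i <- which.min(abs(elev - 1000))
  expect_equal(cl@tmean[, , 7][i], 24.8 - 6 * elev[i] / 1000,
               tolerance = 1e-9)
  expect_true(all(cl@tmin <= cl@tmean))
  expect_true(all(cl@precip >= 0))
  # zero lapse, zero noise: spatially constant temperatures
  cfg0 <- landscapeConfig(lapseRateCPerKm = 0)
  cl0 <- generateClimatology(generateDem(cfg0), cfg0, truth = noiseFree)
  for (m in c(1, 7)) {
    expect_equal(length(unique(as.vector(cl0@tmean[, , m]))), 1L)
  }
})

test_that("GCM anomaly ensembles respect bounds, count and determinism", {
  sc <- generateGcmAnomalies(24, warmingRange = c(1.5, 5),
                             precipRatioRange = c(0.9, 1.15), seed = 3)
  expect_length(sc, 24)
  expect_length(unique(vapply(sc, function(s) s@name, character(1))), 24)
  for (s in sc) {
    expect_true(all(s@deltaMean >= 1.5 & s@deltaMean <= 5))
    expect_true(all(s@deltaMin >= 1.5 & s@deltaMin <= 5))
    expect_true(all(s@precipRatio >= 0.9 & s@precipRatio <= 1.15))
  }
  sc2 <- generateGcmAnomalies(24, warmingRange = c(1.5, 5),
                              precipRatioRange = c(0.9, 1.15), seed = 3)
  expect_identical(sc[[5]]@deltaMean, sc2[[5]]@deltaMean)
  # degenerate ranges give identity-like scenarios
  sc0 <- generateGcmAnomalies(3, warmingRange = c(0, 0),
                              precipRatioRange = c(1, 1), seed = 4)
  for (s in sc0) {
    expect_true(all(s@deltaMean == 0))
    expect_true(all(s@precipRatio == 1))
  }
  expect_error(generateGcmAnomalies(0), "nScenarios")
})

test_that("vegetation fractions respect truth, bounds and zone gating", {
  casc <- fittedCascade()
  L <- casc$L
  cf <- communityFractions(L$vegetation)
  expect_true(all(cf >= 0 & cf <= 1))
  expect_true(all(rowSums(cf) <= 1 + 1e-9))
  # noise-free generation reproduces the true responses exactly
  nf <- trueResponseParams(noiseSd = list(climate = 0.3, vegetation = 0,
                                          precipRel = 0.1))
  veg0 <- generateVegetation(L$bioclim, L$terrain, nf, seed = 1)
  tf <- attr(veg0, "trueFractions")
  expect_equal(veg0@pinusPumila, tf$pinusPumila)
  expect_equal(veg0@snowbed, tf$snowbed)
  # zero zone suitability everywhere: all fractions zero
  deadZone <- trueResponseParams(
    zoneResponse = list(intercept = -50, wi = 0, tmc = 0, prs = 0, msw = 0))
  vegDead <- generateVegetation(L$bioclim, L$terrain, deadZone, seed = 1)
  expect_true(all(communityFractions(vegDead) == 0))
})

test_that("territory generation thins presence by survey effort as 1-(1-p)^n", {
  # rig the truth so every cell has p = 0.3 per survey, 2 surveys each
  nr <- 100; nc <- 100
  terr <- flatTerrain(nr, nc)
  veg <- uniformVegetation(nr, nc, 0, 0, 0)
  truth <- trueResponseParams(
    habitatResponse = list(intercept = qlogis(0.3), afPp = 0, afSg = 0,
                           afFf = 0, drPerM = 0))
  obs <- generateTerritories(veg, terr, truth, surveysPerCell = 2,
                             territoryResolutionM = 100, seed = 8)
  d <- observations(obs)
  expect_equal(nrow(d), nr * nc)
  pDet <- 1 - (1 - 0.3)^2      # 0.51
  se <- sqrt(pDet * (1 - pDet) / nrow(d))
  expect_lt(abs(mean(d$presence) - pDet), 3 * se)
  # deterministic given the seed
  obs2 <- generateTerritories(veg, terr, truth, surveysPerCell = 2,
                              territoryResolutionM = 100, seed = 8)
  expect_identical(observations(obs2)$presence, d$presence)
  # boundary cases: p = 0 all absent; p = 1 all present
  pZero <- trueResponseParams(habitatResponse = list(
    intercept = -1e3, afPp = 0, afSg = 0, afFf = 0, drPerM = 0))
  expect_equal(sum(observations(generateTerritories(
    veg, terr, pZero, 2, 100, seed = 8))$presence), 0)
  pOne <- trueResponseParams(habitatResponse = list(
    intercept = 1e3, afPp = 0, afSg = 0, afFf = 0, drPerM = 0))
  expect_equal(mean(observations(generateTerritories(
    veg, terr, pOne, 1, 100, seed = 8))$presence), 1)
  expect_error(generateTerritories(veg, terr, truth, -1, 100, seed = 8),
               "negative")
})

test_that("fine, coarse and territory grids tile the same domain", {
  casc <- fittedCascade()
  L <- casc$L
  cfg <- L$config
  fineD <- dim(L$dem@elevation)
  climD <- dim(L$bioclim@wi)
  facC <- cfg$climateResolutionM / cfg$terrainResolutionM
  facT <- cfg$territoryResolutionM / cfg$terrainResolutionM
  expect_equal(fineD, climD * facC)
  terrShape <- gridShape(cfg$domainWidthM, cfg$domainHeightM,
                         cfg$territoryResolutionM)
  expect_equal(fineD, terrShape * facT)
  expect_equal(nrow(observations(L$territories)), prod(terrShape))
})
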