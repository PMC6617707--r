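test_that("identity scenario reproduces the current-climate projection", {
  casc <- fittedCascade()
  L <- casc$L
  cur2 <- projectScenario(identityScenario(L$climate), L$climate,
                          L$terrain, casc$zoneModel, casc$fractionModels,
                          casc$habitatModel, L$snowParams, L$daily,
                          L$config$territoryResolutionM)
  expect_identical(cur2@habitatProbability,
                   casc$current@habitatProbability)
  expect_identical(cur2@habitatBinary, casc$current@habitatBinary)
  expect_gt(sum(casc$current@habitatBinary), 0)
})

test_that("missing models raise a pipeline-incomplete error", {
  casc <- fittedCascade()
  L <- casc$L
  expect_error(projectScenario(identityScenario(L$climate), L$climate,
                               L$terrain, casc$zoneModel, NULL,
                               casc$habitatModel),
               "pipeline incomplete")
})

test_that("warming contracts habitat monotonically to zero at saturation", {
  casc <- fittedCascade()
  L <- casc$L
  proj <- function(d) projectScenario(
    uniformScenario(L$climate, d), L$climate, L$terrain, casc$zoneModel,
    casc$fractionModels, casc$habitatModel, L$snowParams, L$daily,
    L$config$territoryResolutionM)
  cells0 <- sum(casc$current@habitatBinary)
  hot <- proj(10)
  mid <- proj(3)
  expect_equal(sum(hot@habitatBinary), 0)
  expect_gt(sum(mid@habitatBinary), sum(hot@habitatBinary))
  expect_lt(sum(mid@habitatBinary), cells0)
  # warming lowers mean zone probability under the fitted negative WI effect
  expect_lt(mean(mid@zoneProbability), mean(casc$current@zoneProbability))
})

test_that("ensemble median, agreement and areas follow their definitions", {
  casc <- fittedCascade()
  mk <- function(p, name = "x") {
    thr <- casc$habitatModel@threshold
    new("HabitatProjection", scenarioName = name,
        zoneProbability = matrix(0.5, 2, 2),
        fractions = uniformVegetation(2, 2, 0.1, 0.1, 0.1, cellSize = 300),
        habitatProbability = p, habitatBinary = p >= thr, threshold = thr,
        cellSize = 300, origin = c(0, 0))
  }
  p1 <- matrix(c(0.1, 0.0, 0.9, 0.0), 2, 2)
  p2 <- matrix(c(0.5, 0.0, 0.9, 0.0), 2, 2)
  p3 <- matrix(c(0.9, 0.0, 0.9, 0.0), 2, 2)
  es <- ensembleMedian(list(mk(p1, "a"), mk(p2, "b"), mk(p3, "c")))
  expect_equal(es@medianProbability[1, 1], 0.5)   # odd-count median
  expect_equal(es@agreementCount[1, 2], 3L)
  expect_equal(es@agreementCount[2, 1], 0L)
  # identical members: median equals each, agreement N on habitat cells
  esI <- ensembleMedian(list(mk(p1), mk(p1), mk(p1), mk(p1)))
  expect_equal(esI@medianProbability, p1)
  expect_true(all(esI@agreementCount[p1 >= casc$habitatModel@threshold]
                  == 4L))
  expect_true(all(esI@agreementCount[!(p1 >= casc$habitatModel@threshold)]
                  == 0L))
  # even count: mean of the two central values
  es2 <- ensembleMedian(list(mk(p1), mk(p2)))
  expect_equal(es2@medianProbability[1, 1], 0.3)
  # order invariance
  esR <- ensembleMedian(list(mk(p3, "c"), mk(p1, "a"), mk(p2, "b")))
  expect_equal(esR@medianProbability, es@medianProbability)
  expect_equal(esR@agreementCount, es@agreementCount)
  # duplicating a member moves the median at most between central order stats
  esD <- ensembleMedian(list(mk(p1), mk(p2), mk(p3), mk(p2)))
  expect_lte(abs(esD@medianProbability[1, 1] - es@medianProbability[1, 1]),
             abs(p3[1, 1] - p1[1, 1]) / 2)
})

test_that("area accounting uses exact cell areas and one-decimal percentages", {
  casc <- fittedCascade()
  thr <- 0.5
  p <- matrix(0, 2, 3); p[c(1, 3, 5)] <- 0.9
  hp <- new("HabitatProjection", scenarioName = "toy",
            zoneProbability = matrix(0.5, 1, 1),
            fractions = uniformVegetation(2, 3, 0.1, 0.1, 0.1,
                                          cellSize = 300),
            habitatProbability = p, habitatBinary = p >= thr,
            threshold = thr, cellSize = 300, origin = c(0, 0))
  tab <- habitatAreaSummary(hp)
  expect_equal(tab$habitatCells, 3)
  expect_equal(tab$habitatKm2, 0.27)     # 3 cells x 0.09 km2
  expect_equal(habitatAreaSummary(hp, currentReference = 2464)$pctOfCurrent,
               0.0)
  # the in-print arithmetic: 18 of 2464 km2 is 0.7%
  expect_equal(percentOfReference(18, 2464), 0.7)
  # empty habitat
  p0 <- matrix(0, 2, 3)
  hp0 <- hp; hp0@habitatProbability <- p0; hp0@habitatBinary <- p0 >= thr
  t0 <- habitatAreaSummary(hp0, currentReference = 10)
  expect_equal(t0$habitatCells, 0)
  expect_equal(t0$habitatKm2, 0)
  expect_equal(t0$pctOfCurrent, 0)
})

test_that("a warming ensemble shrinks median habitat below current on planted decline", {
  casc <- fittedCascade()
  L <- casc$L
  scens <- generateGcmAnomalies(8, warmingRange = c(2, 5),
                                domainWidthM = L$config$domainWidthM,
                                domainHeightM = L$config$domainHeightM,
                                seed = 17)
  projs <- lapply(scens, function(s) projectScenario(
    s, L$climate, L$terrain, casc$zoneModel, casc$fractionModels,
    casc$habitatModel, L$snowParams, L$daily,
    L$config$territoryResolutionM))
  es <- ensembleMedian(projs, current = casc$current)
  curKm2 <- sum(casc$current@habitatBinary) * cellAreaKm2(300)
  medKm2 <- es@areas$habitatKm2[es@areas$scenario == "ensembleMedian"]
  expect_lt(medKm2, curKm2)
  expect_true(all(es@agreementCount >= 0 & es@agreementCount <= 8))
  # agreement restricted to currently suitable cells
  expect_true(all(es@agreementCount[!casc$current@habitatBinary] == 0))
})
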