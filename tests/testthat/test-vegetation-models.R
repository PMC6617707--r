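# Synthetic predictor tables for recovery experiments
zoneTableFromTruth <- function(n, beta, noise = 0, seed = 1) {
  withr::with_seed(seed, {
    tb <- data.frame(wi = runif(n, 0, 110), tmc = runif(n, -25, 0),
                     prs = runif(n, 400, 1500), msw = runif(n, 0, 2000))
    eta <- beta[1] + beta[2] * tb$wi + beta[3] * tb$tmc +
      beta[4] * tb$prs + beta[5] * tb$msw + rnorm(n, 0, noise)
    tb$zonePresence <- rbinom(n, 1, plogis(eta))
    tb
  })
}

fractionTableFromTruth <- function(n, f, noise = 0.02, seed = 1) {
  withr::with_seed(seed, {
    tb <- data.frame(slope = runif(n, 0, 45), aspect = runif(n, 0, 360),
                     curvature = rnorm(n, 0, 0.01), twi = runif(n, 2, 12),
                     ridgeDistance = runif(n, 0, 3000),
                     zoneProbability = runif(n))
    tb$fraction <- pmin(pmax(f(tb) + rnorm(n, 0, noise), 0), 1)
    tb
  })
}

test_that("zone labelling matches a hand count on a toy grid", {
  # 4x4 fine grid, factor 2: vegetated western half only
  veg <- uniformVegetation(4, 4, 0, 0, 0)
  veg@pinusPumila[, 1:2] <- 0.5
  bc <- new("BioclimGrid", origin = c(0, 0), cellSize = 200,
            wi = matrix(1:4, 2, 2), tmc = matrix(-5, 2, 2),
            prs = matrix(800, 2, 2), msw = matrix(500, 2, 2))
  tb <- makeZoneLabels(veg, bc)
  expect_equal(nrow(tb), 4L)
  expect_equal(sum(tb$zonePresence), 2L)
  expect_equal(tb$zonePresence[tb$cellCol == 1], c(1L, 1L))
  expect_equal(tb$zonePresence[tb$cellCol == 2], c(0L, 0L))
  # all-absent / all-present extremes
  expect_equal(sum(makeZoneLabels(uniformVegetation(4, 4, 0, 0, 0),
                                  bc)$zonePresence), 0L)
  expect_equal(sum(makeZoneLabels(uniformVegetation(4, 4, 0.9, 0, 0),
                                  bc)$zonePresence), 4L)
})

test_that("zone model separates a strong planted WI signal and recovers its sign", {
  tb <- zoneTableFromTruth(2500, c(10, -0.4, 0, 0, 0), seed = 11)
  m <- suppressWarnings(fitZoneModel(tb))
  expect_gte(m@metrics$auc, 0.99)
  # prediction consistency on training predictors
  pr <- predictZoneProbability(
    m, new("BioclimGrid", origin = c(0, 0), cellSize = 1000,
           wi = matrix(tb$wi, 50), tmc = matrix(tb$tmc, 50),
           prs = matrix(tb$prs, 50), msw = matrix(tb$msw, 50)))
  expect_equal(as.vector(pr), unname(fitted(m@fit)), tolerance = 1e-8)
  # monotone decreasing partial response in WI at median co-predictors
  grid <- data.frame(wi = seq(5, 105, length.out = 25),
                     tmc = median(tb$tmc), prs = median(tb$prs),
                     msw = median(tb$msw))
  pp <- predict(m@fit, newdata = grid, type = "link")
  expect_lt(pp[25], pp[1])
  expect_lt(cor(grid$wi, as.vector(pp), method = "spearman"), -0.9)
})

test_that("zone model on permuted labels has no discrimination", {
  tb <- zoneTableFromTruth(2000, c(8, -0.35, 0, 0, 0), seed = 12)
  tb$zonePresence <- withr::with_seed(13, sample(tb$zonePresence))
  m <- suppressWarnings(fitZoneModel(tb))
  expect_gte(m@metrics$auc, 0.45)
  expect_lte(m@metrics$auc, 0.65)
})

test_that("zone model rejects degenerate inputs", {
  tb <- zoneTableFromTruth(200, c(10, -0.4, 0, 0, 0), seed = 14)
  expect_error(fitZoneModel(tb[1:20, ]), "50")
  tb$zonePresence <- 1L
  expect_error(fitZoneModel(tb), "degenerate")
})

test_that("nearest-neighbour refinement of zone probabilities preserves values", {
  casc <- fittedCascade()
  pCoarse <- predictZoneProbability(casc$zoneModel, casc$L$bioclim)
  pFine <- predictZoneProbability(casc$zoneModel, casc$L$bioclim,
                                  fineFactor = 10)
  expect_true(all(pCoarse > 0 & pCoarse < 1))
  expect_equal(dim(pFine), dim(pCoarse) * 10L)
  expect_equal(blockAggregate(pFine, 10), pCoarse, tolerance = 1e-12)
  expect_identical(pFine[1:10, 1:10], matrix(pCoarse[1, 1], 10, 10))
})

test_that("fraction forests are deterministic and near-constant on constant responses", {
  tabs <- lapply(stats::setNames(nm = c("pinusPumila", "snowbed",
                                        "fellfield")), function(cm)
    fractionTableFromTruth(400, function(tb) 0.4, noise = 0, seed = 21))
  fm <- suppressWarnings(fitFractionModels(tabs, nTrees = 100, seed = 3))
  fm2 <- suppressWarnings(fitFractionModels(tabs, nTrees = 100, seed = 3))
  pr <- predict(fm@forests$pinusPumila, tabs$pinusPumila)
  expect_identical(pr, predict(fm2@forests$pinusPumila, tabs$pinusPumila))
  expect_lt(max(abs(pr - 0.4)), 1e-6)
  imp <- fm@importance$increasedMse[fm@importance$community == "pinusPumila"]
  expect_lt(max(abs(imp)), 1e-8)
})

test_that("permutation importance ranks the planted dominant variable first", {
  fDr <- function(tb) 0.6 * exp(-tb$ridgeDistance / 400)
  fZp <- function(tb) 0.5 * tb$zoneProbability
  tbDr <- fractionTableFromTruth(1200, fDr, seed = 22)
  tbZp <- fractionTableFromTruth(1200, fZp, seed = 23)
  tabs <- list(pinusPumila = tbDr, snowbed = tbZp, fellfield = tbZp)
  fm <- fitFractionModels(tabs, nTrees = 200, seed = 4)
  top <- function(cm) {
    sub <- fm@importance[fm@importance$community == cm, ]
    sub$variable[which.max(sub$increasedMse)]
  }
  expect_equal(top("pinusPumila"), "ridgeDistance")
  expect_equal(top("snowbed"), "zoneProbability")
  expect_equal(top("fellfield"), "zoneProbability")
  # planted single-signal importance dwarfs every null variable
  sub <- fm@importance[fm@importance$community == "pinusPumila", ]
  planted <- sub$increasedMse[sub$variable == "ridgeDistance"]
  others <- sub$increasedMse[sub$variable != "ridgeDistance"]
  expect_gt(planted, 5 * max(others))
  # the response itself may not be permuted
  expect_error(increasedMseImportance(fm@forests$pinusPumila, tbDr,
                                      response = "fraction",
                                      variables = c("fraction", "slope")),
               "response")
})

test_that("fraction predictions are bounded, rescaled and recover strong truth", {
  casc <- fittedCascade()
  veg <- predictFractions(casc$fractionModels, casc$L$terrain,
                          casc$zoneFine)
  cf <- communityFractions(veg)
  expect_true(all(cf >= 0))
  expect_true(all(rowSums(cf) <= 1 + 1e-9))
  # Spearman recovery on training cells for a strong-signal P. pumila
  # community with a clean planted ridge-distance response
  tbS <- fractionTableFromTruth(
    1500, function(tb) 0.6 * exp(-tb$ridgeDistance / 400), noise = 0.02,
    seed = 27)
  rfS <- withr::with_seed(28, randomForest::randomForest(
    x = tbS[, setdiff(names(tbS), "fraction")], y = tbS$fraction,
    ntree = 200))
  expect_gte(spearmanRho(predict(rfS, tbS), tbS$fraction)$rho, 0.85)
  # on the full landscape (mass of exactly-zero cells, noise) recovery is
  # weaker but still strongly positive
  tb <- casc$fractionTables$pinusPumila
  pr <- predict(casc$fractionModels@forests$pinusPumila, tb)
  expect_gte(spearmanRho(pr, tb$fraction)$rho, 0.5)
  # zero zone probability everywhere: near-zero predicted cover
  vegDead <- predictFractions(casc$fractionModels, casc$L$terrain,
                              matrix(0, nrow(casc$zoneFine),
                                     ncol(casc$zoneFine)))
  expect_lt(mean(communityFractions(vegDead)), 0.02)
})

test_that("noise-free fraction recovery beats noisy recovery in rank correlation", {
  fDr <- function(tb) 0.6 * exp(-tb$ridgeDistance / 400)
  rhoAt <- function(noise) {
    tb <- fractionTableFromTruth(1500, fDr, noise = noise, seed = 25)
    rf <- withr::with_seed(26, randomForest::randomForest(
      x = tb[, setdiff(names(tb), "fraction")], y = tb$fraction,
      ntree = 200))
    spearmanRho(predict(rf, tb), tb$fraction)$rho
  }
  r0 <- rhoAt(0); r1 <- rhoAt(0.05); r2 <- rhoAt(0.2)
  expect_gte(r0, 0.95)
  expect_gt(r0, r1)
  expect_gt(r1, r2)
})
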