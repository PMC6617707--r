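test_that("warmth index sums positive monthly excesses over 5 degrees", {
  expect_equal(warmthIndex(rep(5, 12)), 0)
  expect_equal(warmthIndex(rep(10, 12)), 60)
  expect_equal(warmthIndex(c(-10, -8, -4, 0, 4, 6, 10, 12, 8, 3, -2, -7)),
               16)
  expect_error(warmthIndex(1:11), "12")
  # brute-force oracle on random 12-vectors
  set.seed(31)
  for (i in 1:25) {
    tv <- runif(12, -20, 30)
    expect_equal(warmthIndex(tv), sum(vapply(tv, function(t)
      max(0, t - 5), numeric(1))))
  }
})

test_that("coldest-month minimum and summer precipitation match exhaustive scans", {
  expect_equal(minTempColdestMonth(rep(-3, 12)), -3)
  expect_equal(minTempColdestMonth(c(-20, rep(-5, 11))), -20)
  expect_equal(summerPrecipitation(rep(100, 12)), 500)
  expect_equal(summerPrecipitation(rep(0, 12)), 0)
  set.seed(32)
  for (i in 1:25) {
    tv <- runif(12, -30, 10); pv <- runif(12, 0, 400)
    expect_equal(minTempColdestMonth(tv), min(tv))
    expect_equal(summerPrecipitation(pv), sum(pv[5:9]))
  }
  expect_error(summerPrecipitation(c(-1, rep(10, 11))), "nonnegative")
})

test_that("snowpack follows the degree-day balance day by day", {
  p <- snowModelParams(rainSnowThresholdC = 2, degreeDayFactor = 4,
                       meltBaseTempC = 0)
  # warm days: all rain, no pack
  warm <- simulateSnowpack(rep(10, 20), rep(5, 20), p)
  expect_equal(warm$swe, rep(0, 20))
  expect_equal(warm$msw, 0)
  # pure accumulation
  cold <- simulateSnowpack(rep(-5, 30), rep(10, 30), p)
  expect_equal(cold$msw, 300)
  expect_equal(cold$swe, cumsum(rep(10, 30)))
  # hand-stepped trajectory: 10 cold snow days then 5 warm melt days
  mix <- simulateSnowpack(c(rep(-5, 10), rep(4, 5)),
                          c(rep(10, 10), rep(0, 5)), p)
  expect_equal(mix$swe, c(seq(10, 100, by = 10), 84, 68, 52, 36, 20))
  expect_equal(mix$msw, 100)
  # melt floored at zero once the pack is gone
  gone <- simulateSnowpack(c(rep(-5, 2), rep(10, 5)),
                           c(rep(10, 2), rep(0, 5)), p)
  expect_equal(gone$swe, c(10, 20, 0, 0, 0, 0, 0))
  expect_error(simulateSnowpack(1:5, 1:4), "equal length")
  expect_error(simulateSnowpack(1:5, c(1, -1, 1, 1, 1)), "nonnegative")
})

test_that("snow mass balance holds exactly on random series", {
  set.seed(33)
  p <- snowModelParams()
  for (i in 1:50) {
    tv <- runif(365, -15, 25)
    pv <- rexp(365, 1 / 5)
    s <- simulateSnowpack(tv, pv, p)
    expect_equal(s$snowfall - s$melt, s$swe[365], tolerance = 1e-10)
    expect_true(all(s$swe >= 0))
    expect_equal(s$msw, max(s$swe))
  }
})

test_that("identity scenario reproduces the baseline bioclim bit for bit", {
  casc <- fittedCascade()
  base <- casc$L$climate
  fut <- applyGcmDelta(base, identityScenario(base))
  expect_identical(fut@tmean, base@tmean)
  expect_identical(fut@precip, base@precip)
  b0 <- computeBioclim(base, casc$L$snowParams, casc$L$daily)
  b1 <- computeBioclim(fut, casc$L$snowParams, casc$L$daily)
  expect_identical(b1@wi, b0@wi)
  expect_identical(b1@msw, b0@msw)
  expect_identical(b1@tmc, b0@tmc)
  expect_identical(b1@prs, b0@prs)
})

test_that("a uniform +3 degree delta shifts every monthly temperature by exactly 3", {
  base <- constantClimate(tmean = 8)
  fut <- applyGcmDelta(base, uniformScenario(base, 3))
  expect_equal(fut@tmean, base@tmean + 3)
  expect_equal(fut@tmin, base@tmin + 3)
  expect_equal(fut@precip, base@precip)
  fut2 <- applyGcmDelta(base, uniformScenario(base, 0, precipRatio = 1.2))
  expect_equal(fut2@precip, base@precip * 1.2)
  expect_equal(fut2@tmean, base@tmean)
})

test_that("warming raises WI and TMC and lowers MSW with fixed daily seed", {
  casc <- fittedCascade()
  base <- casc$L$climate
  b0 <- casc$L$bioclim
  for (d in c(1, 4)) {
    fut <- applyGcmDelta(base, uniformScenario(base, d))
    b1 <- computeBioclim(fut, casc$L$snowParams, casc$L$daily)
    expect_true(all(b1@wi >= b0@wi))
    expect_true(all(b1@tmc >= b0@tmc))
    expect_true(all(b1@msw <= b0@msw))
  }
})

test_that("bioclim grids match the per-cell scalar operations", {
  casc <- fittedCascade()
  cl <- casc$L$climate
  bc <- casc$L$bioclim
  set.seed(34)
  d <- dim(cl@tmean)
  for (k in 1:20) {
    i <- sample(d[1], 1); j <- sample(d[2], 1)
    expect_equal(bc@wi[i, j], warmthIndex(cl@tmean[i, j, ]))
    expect_equal(bc@tmc[i, j], minTempColdestMonth(cl@tmin[i, j, ]))
    expect_equal(bc@prs[i, j], summerPrecipitation(cl@precip[i, j, ]))
  }
  # uniformly warm climate: no snow anywhere
  warmBc <- computeBioclim(constantClimate(tmean = 15, tminOffset = 3))
  expect_true(all(warmBc@msw == 0))
  # +1 degree on all months in the all-positive regime adds exactly 12 to WI
  c1 <- constantClimate(tmean = 10); c2 <- constantClimate(tmean = 11)
  expect_equal(computeBioclim(c2)@wi, computeBioclim(c1)@wi + 12)
})

test_that("scenario coverage and validity are enforced", {
  base <- constantClimate()
  tiny <- new("GcmScenario", name = "tiny", origin = c(0, 0), cellSize = 10,
              deltaMean = matrix(0, 1, 1), deltaMin = matrix(0, 1, 1),
              precipRatio = matrix(1, 1, 1))
  expect_error(applyGcmDelta(base, tiny), "cover")
  expect_error(new("GcmScenario", name = "bad", origin = c(0, 0),
                   cellSize = 1e5, deltaMean = matrix(0, 1, 1),
                   deltaMin = matrix(0, 1, 1),
                   precipRatio = matrix(-1, 1, 1)), "positive")
})
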