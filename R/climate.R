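#' @include grid-methods.R
NULL

## Month lengths of the hydrological year used by the snow model:
## September through August, non-leap (365 days), so one winter snowpack is
## contiguous within a single simulated series.
.hydroMonths <- c(9L, 10L, 11L, 12L, 1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L)
.monthDays <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)

.check12 <- function(x, what) {
  if (length(x) != 12L || anyNA(x))
    stop(what, " must be 12 non-missing monthly values")
  invisible(x)
}

#' Warmth index
#'
#' Annual sum of positive excesses of monthly mean temperature over +5 deg C,
#' a heat-sum measure of growing conditions (deg C month).
#'
#' @param monthlyMeanTemp numeric(12), monthly mean temperatures (deg C),
#'   January first.
#' @return WI >= 0.
#' @examples
#' warmthIndex(rep(10, 12))  # 60
#' @export
warmthIndex <- function(monthlyMeanTemp) {
  .check12(monthlyMeanTemp, "monthlyMeanTemp")
  sum(pmax(0, monthlyMeanTemp - 5))
}

#' Minimum temperature of the coldest month
#'
#' The minimum over the twelve monthly mean daily minimum temperatures; a
#' measure of extreme cold (deg C).
#'
#' @param monthlyMinTemp numeric(12).
#' @return TMC (deg C).
#' @export
minTempColdestMonth <- function(monthlyMinTemp) {
  .check12(monthlyMinTemp, "monthlyMinTemp")
  min(monthlyMinTemp)
}

#' Summer (May-September) precipitation
#'
#' Sum of monthly precipitation over months 5 through 9 inclusive; growing
#' season water supply (mm).
#'
#' @param monthlyPrecip numeric(12), mm, January first.
#' @return PRS >= 0.
#' @export
summerPrecipitation <- function(monthlyPrecip) {
  .check12(monthlyPrecip, "monthlyPrecip")
  if (any(monthlyPrecip < 0)) stop("precipitation must be nonnegative")
  sum(monthlyPrecip[5:9])
}

#' Degree-day snow model parameters
#'
#' @param rainSnowThresholdC temperature below which precipitation falls as
#'   snow (deg C).
#' @param degreeDayFactor melt per positive degree-day (mm / deg C / day).
#' @param meltBaseTempC temperature above which melt occurs (deg C).
#' @return list of class parameters for \code{\link{simulateSnowpack}}.
#' @export
snowModelParams <- function(rainSnowThresholdC = 2.0, degreeDayFactor = 4.0,
                            meltBaseTempC = 0.0) {
  if (degreeDayFactor <= 0) stop("degreeDayFactor must be positive")
  list(rainSnowThresholdC = rainSnowThresholdC,
       degreeDayFactor = degreeDayFactor, meltBaseTempC = meltBaseTempC)
}

#' Degree-day snowpack simulation
#'
#' Steps a daily snow-water-equivalent (SWE) balance through one hydrological
#' year: precipitation on days colder than the rain/snow threshold accrues to
#' the pack as snow (rain is not stored); potential melt is
#' \code{degreeDayFactor * max(0, T - meltBaseTempC)}, and actual melt is
#' capped at the pack present after the day's accumulation. The maximum
#' snow-water equivalent (MSW) is the maximum of the daily SWE series.
#'
#' Mass balance holds exactly: cumulative snowfall minus cumulative melt
#' equals the final SWE.
#'
#' @param dailyTemp numeric vector (or days x cells matrix) of daily mean
#'   temperatures (deg C).
#' @param dailyPrecip same shape, daily precipitation (mm, >= 0).
#' @param params see \code{\link{snowModelParams}}.
#' @return list(swe = daily SWE series (same shape as input), msw = maximum
#'   SWE per cell, snowfall = total snowfall, melt = total melt).
#' @export
simulateSnowpack <- function(dailyTemp, dailyPrecip,
                             params = snowModelParams()) {
  tm <- as.matrix(dailyTemp); pr <- as.matrix(dailyPrecip)
  if (!identical(dim(tm), dim(pr)))
    stop("daily temperature and precipitation series must have equal length")
  if (any(pr < 0)) stop("precipitation must be nonnegative")
  nd <- nrow(tm); ncell <- ncol(tm)
  snow <- pr * (tm < params$rainSnowThresholdC)
  pot <- params$degreeDayFactor * pmax(tm - params$meltBaseTempC, 0)
  swe <- matrix(0, nd, ncell)
  melt <- matrix(0, nd, ncell)
  prev <- rep(0, ncell)
  for (d in seq_len(nd)) {
    avail <- prev + snow[d, ]
    m <- pmin(pot[d, ], avail)
    prev <- avail - m
    swe[d, ] <- prev
    melt[d, ] <- m
  }
  if (is.null(dim(dailyTemp))) {
    list(swe = as.vector(swe), msw = max(swe), snowfall = sum(snow),
         melt = sum(melt))
  } else {
    list(swe = swe, msw = apply(swe, 2, max), snowfall = colSums(snow),
         melt = colSums(melt))
  }
}

#' Daily-weather synthesis settings
#'
#' The snow model needs daily forcing, while the climatology is monthly.
#' Daily temperature is a smooth periodic interpolation of the monthly means
#' through month midpoints plus seeded day-to-day noise shared across cells
#' (one mountain area shares its weather); wet days are drawn per day with a
#' fixed frequency and each month's precipitation total is split equally over
#' that month's wet days, preserving monthly totals exactly.
#'
#' @param tempNoiseSd day-to-day temperature s.d. (deg C).
#' @param wetDayFrequency probability a day is wet.
#' @param seed integer; fixes the shared daily noise and wet-day pattern.
#' @return list of settings for \code{\link{computeBioclim}}.
#' @export
dailySynthesisConfig <- function(tempNoiseSd = 2.0, wetDayFrequency = 0.4,
                                 seed = 1L) {
  list(tempNoiseSd = tempNoiseSd, wetDayFrequency = wetDayFrequency,
       seed = as.integer(seed))
}

## Periodic interpolation of 12 monthly values to 365 daily values on the
## hydrological year (Sep 1 - Aug 31). Returns a length-365 vector.
.monthlyToDaily <- function(monthly) {
  mo <- .hydroMonths
  len <- .monthDays[mo]
  mid <- cumsum(len) - len / 2          # month midpoints, hydro day-of-year
  v <- monthly[mo]
  stats::spline(c(mid, mid[1] + 365), c(v, v[1]), method = "periodic",
                xout = seq_len(365))$y
}

## Shared daily structure for a given synthesis config: temperature noise and
## the per-month wet-day weight matrix (day x 12 months of the calendar).
.dailyStructure <- function(config) {
  withSeed(config$seed, {
    noise <- stats::rnorm(365, 0, config$tempNoiseSd)
    wet <- stats::runif(365) < config$wetDayFrequency
    monthOfDay <- rep(.hydroMonths, .monthDays[.hydroMonths])
    w <- numeric(365)
    for (m in 1:12) {
      idx <- which(monthOfDay == m)
      wm <- wet[idx]
      if (!any(wm)) wm[ceiling(length(idx) / 2)] <- TRUE
      w[idx] <- wm / sum(wm)
    }
    list(noise = noise, precipWeight = w, monthOfDay = monthOfDay)
  })
}

#' Bioclimatic indices from a monthly climatology
#'
#' Computes, per climate cell, the warmth index (WI), the coldest-month
#' minimum temperature (TMC), May-September precipitation (PRS) and the
#' maximum snow-water equivalent (MSW) from a degree-day snowpack simulation
#' driven by synthesised daily weather (see
#' \code{\link{dailySynthesisConfig}}).
#'
#' @param climate a \linkS4class{ClimateGrid}.
#' @param params snow parameters, \code{\link{snowModelParams}}.
#' @param daily daily-synthesis settings, \code{\link{dailySynthesisConfig}};
#'   the same seed yields bit-identical indices for identical climatologies.
#' @return a \linkS4class{BioclimGrid}.
#' @export
computeBioclim <- function(climate, params = snowModelParams(),
                           daily = dailySynthesisConfig()) {
  stopifnot(is(climate, "ClimateGrid"))
  d <- dim(climate@tmean)[1:2]
  ncell <- prod(d)
  tmeanFlat <- matrix(climate@tmean, ncell, 12)   # cell x month
  tminFlat <- matrix(climate@tmin, ncell, 12)
  precipFlat <- matrix(climate@precip, ncell, 12)

  wi <- rowSums(pmax(tmeanFlat - 5, 0))
  tmc <- apply(tminFlat, 1, min)
  prs <- rowSums(precipFlat[, 5:9, drop = FALSE])

  st <- .dailyStructure(daily)
  ## daily temperature per cell: smooth seasonal curve + shared noise
  dailyTemp <- apply(tmeanFlat, 1, .monthlyToDaily) + st$noise  # 365 x cell
  dailyPrecip <- st$precipWeight *
    t(precipFlat[, st$monthOfDay, drop = FALSE])                # 365 x cell
  msw <- simulateSnowpack(dailyTemp, dailyPrecip, params)$msw

  new("BioclimGrid", origin = climate@origin, cellSize = climate@cellSize,
      wi = matrix(wi, d[1], d[2]), tmc = matrix(tmc, d[1], d[2]),
      prs = matrix(prs, d[1], d[2]), msw = matrix(msw, d[1], d[2]))
}

#' Identity (no-change) scenario for a baseline climatology
#'
#' Zero temperature anomalies and unit precipitation ratios on a minimal
#' coarse lattice covering the baseline domain; applying it reproduces the
#' baseline exactly.
#'
#' @param baseline a \linkS4class{ClimateGrid}.
#' @return a \linkS4class{GcmScenario}.
#' @export
identityScenario <- function(baseline) {
  d <- dim(baseline@tmean)[1:2]
  ext <- c(d[2], d[1]) * baseline@cellSize
  new("GcmScenario", name = "identity",
      origin = baseline@origin - ext,  # generous margin: full coverage
      cellSize = 3 * max(ext),
      deltaMean = matrix(0, 1, 1), deltaMin = matrix(0, 1, 1),
      precipRatio = matrix(1, 1, 1))
}

#' Uniform-shift scenario
#'
#' A spatially constant warming / precipitation-scaling scenario, mainly for
#' sensitivity checks.
#'
#' @param baseline a \linkS4class{ClimateGrid}.
#' @param deltaC additive temperature change (deg C), applied to monthly
#'   means and minimums alike.
#' @param precipRatio multiplicative precipitation change.
#' @param name scenario label.
#' @return a \linkS4class{GcmScenario}.
#' @export
uniformScenario <- function(baseline, deltaC, precipRatio = 1,
                            name = sprintf("uniform%+.1fC", deltaC)) {
  s <- identityScenario(baseline)
  s@name <- name
  s@deltaMean[] <- deltaC
  s@deltaMin[] <- deltaC
  s@precipRatio[] <- precipRatio
  validObject(s)
  s
}

#' Delta-method downscaling: apply a GCM scenario to a baseline climatology
#'
#' Interpolates the scenario's coarse anomaly fields bilinearly (treating
#' coarse values as cell-centre points) to the baseline lattice, then adds
#' the temperature differences to the monthly means and minimums and
#' multiplies precipitation by the ratio field.
#'
#' @param baseline a \linkS4class{ClimateGrid}.
#' @param scenario a \linkS4class{GcmScenario} whose extent covers the
#'   baseline domain.
#' @return a future \linkS4class{ClimateGrid}.
#' @export
applyGcmDelta <- function(baseline, scenario) {
  stopifnot(is(baseline, "ClimateGrid"), is(scenario, "GcmScenario"))
  d <- dim(baseline@tmean)[1:2]
  cc <- cellCenters(d[1], d[2], baseline@origin, baseline@cellSize)
  sext <- scenario@origin +
    c(ncol(scenario@deltaMean), nrow(scenario@deltaMean)) * scenario@cellSize
  bext <- baseline@origin + c(d[2], d[1]) * baseline@cellSize
  if (any(scenario@origin > baseline@origin + 1e-6) ||
      any(sext < bext - 1e-6))
    stop("scenario extent does not cover the baseline domain")
  ip <- function(f) bilinearInterpolate(f, scenario@origin,
                                        scenario@cellSize, cc$x, cc$y)
  dMean <- ip(scenario@deltaMean)
  dMin <- ip(scenario@deltaMin)
  rPr <- ip(scenario@precipRatio)
  if (any(rPr <= 0)) stop("interpolated precipitation ratio must be positive")
  fut <- baseline
  fut@tmean <- baseline@tmean + as.vector(dMean)   # recycles over months
  fut@tmin <- baseline@tmin + as.vector(dMin)
  fut@precip <- baseline@precip * as.vector(rPr)
  validObject(fut)
  fut
}
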