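#' @include grid-methods.R
NULL

## Edge handling: derivative filters use edge replication so every cell gets
## a defined value; model-fitting tables drop the one-cell border where the
## stencil is padded (see trainingMask()).

.padReplicate <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  m2 <- m[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  m2
}

## 3x3 shifted views of a padded matrix; s[[di+2]][[dj+2]] is the neighbour
## at row offset di, col offset dj (row + 1 = one cell north).
.shifts <- function(m) {
  p <- .padReplicate(m)
  nr <- nrow(m); nc <- ncol(m)
  lapply(-1:1, function(di) lapply(-1:1, function(dj)
    p[(2 + di):(nr + 1 + di), (2 + dj):(nc + 1 + dj)]))
}

#' Slope and aspect (Horn's method)
#'
#' Horn 3x3 finite-difference gradient. Slope is
#' \code{atan(|grad z|)} in degrees; aspect is the downslope compass
#' direction in degrees clockwise from north (a plane dipping west has
#' aspect 270), NA on flat cells.
#'
#' @param elevation matrix (rows = northing) of elevations (m).
#' @param cellSize cell edge (m).
#' @param flatTolerance gradient magnitude below which a cell counts as flat.
#' @return list(slope, aspect) matrices.
#' @export
slopeAspect <- function(elevation, cellSize, flatTolerance = 1e-8) {
  if (nrow(elevation) < 3 || ncol(elevation) < 3)
    stop("grid must be at least 3 x 3")
  s <- .shifts(elevation)
  N <- s[[3]]; S <- s[[1]]; C <- s[[2]]
  ## dz/dx: (east column) - (west column), Horn weights 1,2,1
  gx <- ((N[[3]] + 2 * C[[3]] + S[[3]]) -
         (N[[1]] + 2 * C[[1]] + S[[1]])) / (8 * cellSize)
  gy <- ((N[[1]] + 2 * N[[2]] + N[[3]]) -
         (S[[1]] + 2 * S[[2]] + S[[3]])) / (8 * cellSize)
  g <- sqrt(gx^2 + gy^2)
  slope <- atan(g) * 180 / pi
  aspect <- (atan2(-gx, -gy) * 180 / pi) %% 360   # downslope, from north CW
  aspect[g < flatTolerance] <- NA_real_
  list(slope = slope, aspect = aspect)
}

#' General curvature (Zevenbergen-Thorne)
#'
#' Second derivatives from the 3x3 quadratic fit; sign convention convex-up
#' positive, so ridge crests are positive and hollows negative (1/m).
#'
#' @inheritParams slopeAspect
#' @return curvature matrix.
#' @export
curvatureZT <- function(elevation, cellSize) {
  if (nrow(elevation) < 3 || ncol(elevation) < 3)
    stop("grid must be at least 3 x 3")
  s <- .shifts(elevation)
  C <- s[[2]][[2]]
  D <- ((s[[2]][[1]] + s[[2]][[3]]) / 2 - C) / cellSize^2   # d2z/dx2 / 2
  E <- ((s[[1]][[2]] + s[[3]][[2]]) / 2 - C) / cellSize^2   # d2z/dy2 / 2
  -2 * (D + E)
}

## Minimal pit filling: iteratively raise interior cells lower than all eight
## neighbours to the lowest neighbour plus a small step, so D8 routing has no
## internal sinks. Border cells drain off-grid and are left alone.
.fillPits <- function(elevation, maxIter = 100L, step = 1e-4) {
  z <- elevation
  nr <- nrow(z); nc <- ncol(z)
  for (it in seq_len(maxIter)) {
    s <- .shifts(z)
    nbrMin <- Reduce(pmin, list(s[[1]][[1]], s[[1]][[2]], s[[1]][[3]],
                                s[[2]][[1]], s[[2]][[3]],
                                s[[3]][[1]], s[[3]][[2]], s[[3]][[3]]))
    pit <- z < nbrMin
    pit[c(1, nr), ] <- FALSE; pit[, c(1, nc)] <- FALSE
    if (!any(pit)) break
    z[pit] <- nbrMin[pit] + step
  }
  z
}

#' D8 flow accumulation
#'
#' Single-direction routing: each cell drains to the neighbour with the
#' steepest distance-weighted drop; accumulation counts the cell itself plus
#' all upslope contributors (units: cells). A minimal pit fill is applied
#' first; cells with no lower neighbour (domain border, filled flats) retain
#' their accumulated inflow.
#'
#' @inheritParams slopeAspect
#' @param fillPits logical; apply the minimal pit fill first.
#' @return matrix of accumulated cell counts (>= 1).
#' @export
flowAccumulationD8 <- function(elevation, cellSize, fillPits = TRUE) {
  z <- if (fillPits) .fillPits(elevation) else elevation
  nr <- nrow(z); nc <- ncol(z)
  off <- cbind(di = c(-1, -1, -1, 0, 0, 1, 1, 1),
               dj = c(-1, 0, 1, -1, 1, -1, 0, 1))
  dist <- sqrt(off[, 1]^2 + off[, 2]^2) * cellSize
  n <- nr * nc
  idx <- seq_len(n)
  ri <- ((idx - 1L) %% nr) + 1L
  ci <- ((idx - 1L) %/% nr) + 1L
  receiver <- integer(n)                 # 0 = sink / off-grid
  bestDrop <- rep(0, n)
  for (k in 1:8) {
    r2 <- ri + off[k, 1]; c2 <- ci + off[k, 2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    tgt <- (c2 - 1L) * nr + r2
    drop <- rep(-Inf, n)
    drop[ok] <- (z[idx[ok]] - z[tgt[ok]]) / dist[k]
    upd <- ok & drop > bestDrop
    receiver[upd] <- tgt[upd]
    bestDrop[upd] <- drop[upd]
  }
  acc <- rep(1, n)
  ord <- order(z, decreasing = TRUE)     # process high to low
  for (i in ord) {
    r <- receiver[i]
    if (r > 0L) acc[r] <- acc[r] + acc[i]
  }
  matrix(acc, nr, nc)
}

#' Topographic wetness index
#'
#' \code{TWI = ln(a / tan(beta))} with specific catchment area
#' \code{a = accumulation * cellSize} (m) from D8 routing and slope beta from
#' Horn's method. Flat cells use a small slope floor so the index stays
#' finite.
#'
#' @inheritParams slopeAspect
#' @param slopeFloorTan lower bound on tan(beta).
#' @return TWI matrix (dimensionless).
#' @export
twi <- function(elevation, cellSize, slopeFloorTan = 1e-3) {
  acc <- flowAccumulationD8(elevation, cellSize)
  sl <- slopeAspect(elevation, cellSize)$slope
  tanb <- pmax(tan(sl * pi / 180), slopeFloorTan)
  log(acc * cellSize / tanb)
}

#' Ridge cells and Euclidean distance to the ridgeline
#'
#' Ridge (drainage-divide) cells are those whose D8 flow accumulation on the
#' inverted DEM exceeds a high quantile: water poured on the upside-down
#' landscape collects along the divides of the original one. Distance is the
#' exact Euclidean distance from each cell centre to the nearest ridge-cell
#' centre, in metres (0 on ridge cells).
#'
#' @inheritParams slopeAspect
#' @param ridgeThresholdQuantile quantile of inverted-DEM accumulation above
#'   which a cell is a ridge cell.
#' @return list(ridgeMask logical matrix, distance matrix in metres).
#' @export
ridgeDistance <- function(elevation, cellSize,
                          ridgeThresholdQuantile = 0.99) {
  invAcc <- flowAccumulationD8(max(elevation) - elevation, cellSize)
  thr <- stats::quantile(invAcc, ridgeThresholdQuantile, names = FALSE)
  mask <- invAcc > thr
  if (!any(mask))
    stop("degenerate landscape: no ridge cells above the quantile threshold")
  nr <- nrow(elevation); nc <- ncol(elevation)
  rIdx <- which(mask, arr.ind = TRUE)
  ri <- row(elevation); ci <- col(elevation)
  ## exact distance transform by blocks of ridge cells (small ridge sets)
  d2 <- matrix(Inf, nr, nc)
  for (k in seq_len(nrow(rIdx))) {
    dd <- (ri - rIdx[k, 1])^2 + (ci - rIdx[k, 2])^2
    d2 <- pmin(d2, dd)
  }
  list(ridgeMask = mask, distance = sqrt(d2) * cellSize)
}

#' Derive all topographic predictors from a DEM
#'
#' Produces the five predictors of the area-fraction model (slope, aspect,
#' curvature, TWI, ridge distance) on the fine lattice.
#'
#' @param dem an \linkS4class{ElevationGrid}.
#' @param ridgeThresholdQuantile see \code{\link{ridgeDistance}}.
#' @return a \linkS4class{TerrainGrid}.
#' @export
computeTerrain <- function(dem, ridgeThresholdQuantile = 0.99) {
  stopifnot(is(dem, "ElevationGrid"))
  z <- dem@elevation
  sa <- slopeAspect(z, dem@cellSize)
  cv <- curvatureZT(z, dem@cellSize)
  tw <- twi(z, dem@cellSize)
  rd <- ridgeDistance(z, dem@cellSize, ridgeThresholdQuantile)
  new("TerrainGrid", origin = dem@origin, cellSize = dem@cellSize,
      elevation = z, slope = sa$slope, aspect = sa$aspect, curvature = cv,
      twi = tw, ridgeDistance = rd$distance,
      ridgeMask = rd$ridgeMask)
}

#' Interior-cell mask for model fitting
#'
#' TRUE for cells at least one cell away from the domain border, where the
#' 3x3 derivative stencils are fully supported by real data.
#'
#' @param nr,nc grid dimensions.
#' @return logical matrix.
#' @export
trainingMask <- function(nr, nc) {
  m <- matrix(TRUE, nr, nc)
  m[c(1, nr), ] <- FALSE
  m[, c(1, nc)] <- FALSE
  m
}
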