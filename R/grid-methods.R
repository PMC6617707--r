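#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname gridOrigin
setMethod("gridOrigin", "AlpineGrid", function(x) x@origin)
#' @rdname gridOrigin
setMethod("gridCellSize", "AlpineGrid", function(x) x@cellSize)

.firstMatrixSlot <- function(x) {
  for (s in slotNames(x)) {
    v <- slot(x, s)
    if (is.matrix(v)) return(v)
    if (is.array(v) && length(dim(v)) == 3L) return(v[, , 1L])
  }
  stop("object carries no matrix layer")
}

#' @rdname gridOrigin
setMethod("gridDim", "AlpineGrid", function(x) dim(.firstMatrixSlot(x)))

#' @rdname layerNames
setMethod("layerNames", "AlpineGrid", function(x) {
  sn <- slotNames(x)
  sn[vapply(sn, function(s) is.matrix(slot(x, s)) || is.array(slot(x, s)),
            logical(1))]
})

#' @rdname gridLayer
#' @param month month index 1..12 for monthly climatology layers.
setMethod("gridLayer", "AlpineGrid", function(x, name, month = NULL) {
  if (!name %in% slotNames(x)) stop("no layer named '", name, "'")
  v <- slot(x, name)
  if (is.array(v) && length(dim(v)) == 3L) {
    if (is.null(month)) stop("layer '", name, "' is monthly; give month = 1..12")
    return(v[, , month])
  }
  v
})

#' @rdname communityFractions
setMethod("communityFractions", "VegetationMap", function(x)
  cbind(pinusPumila = as.vector(x@pinusPumila),
        snowbed = as.vector(x@snowbed),
        fellfield = as.vector(x@fellfield)))

#' @rdname observations
setMethod("observations", "TerritoryObservations", function(x) x@data)

setMethod("show", "AlpineGrid", function(object) {
  d <- gridDim(object)
  cat(class(object), ": ", d[1], " x ", d[2], " cells @ ",
      object@cellSize, " m (", paste(layerNames(object), collapse = ", "),
      ")\n", sep = "")
})

setMethod("show", "TerritoryObservations", function(object) {
  d <- object@data
  cat("TerritoryObservations: ", nrow(d), " surveyed cells @ ",
      object@cellSize, " m; ", sum(d$presence), " presences\n", sep = "")
})

setMethod("show", "ZoneModel", function(object) {
  cat("ZoneModel (additive logistic, s(WI,TMC) + s(PRS) + s(MSW))\n",
      "  n = ", nrow(object@training),
      ", training AUC = ", round(object@metrics$auc, 3),
      ", threshold = ", signif(object@metrics$threshold, 3), "\n", sep = "")
})

setMethod("show", "FractionModels", function(object) {
  cat("FractionModels: random forests for",
      paste(names(object@forests), collapse = ", "), "\n")
  cat("  OOB MSE:", paste(sprintf("%s=%.4g", names(object@oob), object@oob),
                          collapse = ", "), "\n")
})

setMethod("show", "HabitatModel", function(object) {
  cat("HabitatModel (s(DR,AF_Pp) + s(AF_Ff) + s(AF_Sg) + offset(log n))\n",
      "  n = ", nrow(object@training),
      ", training AUC = ", round(object@metrics$auc, 3),
      ", threshold = ", signif(object@threshold, 3),
      " at effort ", object@referenceEffort, "\n", sep = "")
})

setMethod("show", "HabitatProjection", function(object) {
  cat("HabitatProjection '", object@scenarioName, "': ",
      sum(object@habitatBinary), " habitat cells (",
      format(sum(object@habitatBinary) * (object@cellSize / 1000)^2),
      " km^2)\n", sep = "")
})

setMethod("show", "EnsembleSummary", function(object) {
  cat("EnsembleSummary over ", object@nScenarios, " scenarios: ",
      sum(object@medianBinary), " median habitat cells; max agreement ",
      max(object@agreementCount), "\n", sep = "")
})

## ---- geometry helpers -----------------------------------------------------

#' Number of cells tiling a rectangular domain
#'
#' @param widthM,heightM domain extents in metres.
#' @param resolutionM cell edge in metres; must divide both extents evenly.
#' @return integer cell count, e.g. 60000 for a 20 km x 30 km domain at 100 m.
#' @export
gridCellCount <- function(widthM, heightM, resolutionM) {
  s <- gridShape(widthM, heightM, resolutionM)
  s[1] * s[2]
}

#' Grid shape (rows, cols) for a domain and resolution
#' @inheritParams gridCellCount
#' @return integer c(nrow, ncol); rows run along the height (northing).
#' @export
gridShape <- function(widthM, heightM, resolutionM) {
  if (any(c(widthM, heightM, resolutionM) <= 0))
    stop("extents and resolution must be positive")
  nr <- heightM / resolutionM
  nc <- widthM / resolutionM
  if (abs(nr - round(nr)) > 1e-9 || abs(nc - round(nc)) > 1e-9)
    stop("resolution must divide the domain extents evenly")
  c(as.integer(round(nr)), as.integer(round(nc)))
}

#' Area of one square cell in square kilometres
#' @param resolutionM cell edge in metres.
#' @return km^2, e.g. 0.09 for a 300-m cell.
#' @export
cellAreaKm2 <- function(resolutionM) (resolutionM / 1000)^2

#' A value as a percent of a reference, rounded to one decimal
#' @param value,reference same units; reference > 0.
#' @return percentage rounded to one decimal, e.g. 0.7 for 18 of 2464.
#' @export
percentOfReference <- function(value, reference) {
  if (any(reference <= 0)) stop("reference must be positive")
  round(100 * value / reference, 1)
}

#' Cell-centre coordinates of a grid
#' @param nr,nc grid dimensions.
#' @param origin numeric(2) lower-left corner (m).
#' @param cellSize cell edge (m).
#' @return list(x = numeric(nc), y = numeric(nr)).
#' @export
cellCenters <- function(nr, nc, origin, cellSize) {
  list(x = origin[1] + (seq_len(nc) - 0.5) * cellSize,
       y = origin[2] + (seq_len(nr) - 0.5) * cellSize)
}

#' Block-average a fine matrix onto a coarser lattice
#'
#' Aggregates factor x factor blocks of fine cells into one coarse cell by
#' the mean; the factor must divide both dimensions. Each coarse cell covers
#' exactly factor^2 fine cells.
#'
#' @param m numeric matrix on the fine lattice.
#' @param factor integer coarsening factor (coarse cell edge / fine cell edge).
#' @return matrix of dimension dim(m)/factor.
#' @export
blockAggregate <- function(m, factor) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be a positive integer")
  d <- dim(m)
  if (any(d %% factor != 0L))
    stop("aggregation factor must divide the grid dimensions")
  nr <- d[1] %/% factor; nc <- d[2] %/% factor
  ri <- (seq_len(d[1]) - 1L) %/% factor + 1L
  ci <- (seq_len(d[2]) - 1L) %/% factor + 1L
  acc <- rowsum(m, ri)                      # sum over row blocks
  acc <- t(rowsum(t(acc), ci))              # then over column blocks
  dimnames(acc) <- NULL
  acc / factor^2
}

#' Replicate a coarse matrix onto a finer lattice (nearest neighbour)
#'
#' Each coarse value is copied into its factor x factor block of fine cells,
#' preserving the coarse model's values exactly.
#'
#' @param m coarse matrix.
#' @param factor integer refinement factor.
#' @return matrix of dimension dim(m) * factor.
#' @export
disaggregateNearest <- function(m, factor) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be a positive integer")
  m[rep(seq_len(nrow(m)), each = factor),
    rep(seq_len(ncol(m)), each = factor), drop = FALSE]
}

#' Bilinear interpolation from a coarse cell-centre lattice
#'
#' Coarse values are treated as point values at cell centres; queries are
#' interpolated bilinearly between the four surrounding centres and clamped
#' (held constant) beyond the outermost centres.
#'
#' @param m coarse matrix (rows = northing).
#' @param origin,cellSize coarse-grid geometry (m).
#' @param xout,yout query coordinates (m); all combinations are evaluated.
#' @return matrix length(yout) x length(xout) of interpolated values.
#' @export
bilinearInterpolate <- function(m, origin, cellSize, xout, yout) {
  nr <- nrow(m); nc <- ncol(m)
  cx <- origin[1] + (seq_len(nc) - 0.5) * cellSize
  cy <- origin[2] + (seq_len(nr) - 0.5) * cellSize
  fx <- (xout - cx[1]) / cellSize           # fractional column index - 1
  fy <- (yout - cy[1]) / cellSize
  fx <- pmin(pmax(fx, 0), nc - 1)
  fy <- pmin(pmax(fy, 0), nr - 1)
  j0 <- pmin(floor(fx), nc - 2 + (nc == 1)); tx <- fx - j0
  i0 <- pmin(floor(fy), nr - 2 + (nr == 1)); ty <- fy - i0
  if (nc == 1) { j0 <- rep(0, length(fx)); tx <- rep(0, length(fx)) }
  if (nr == 1) { i0 <- rep(0, length(fy)); ty <- rep(0, length(fy)) }
  out <- matrix(0, length(yout), length(xout))
  for (ii in seq_along(yout)) {
    i <- i0[ii] + 1L
    iN <- min(i + 1L, nr)
    w <- ty[ii]
    rowLo <- m[i, ]; rowHi <- m[iN, ]
    vLo <- rowLo[j0 + 1L] * (1 - tx) + rowLo[pmin(j0 + 2L, nc)] * tx
    vHi <- rowHi[j0 + 1L] * (1 - tx) + rowHi[pmin(j0 + 2L, nc)] * tx
    out[ii, ] <- vLo * (1 - w) + vHi * w
  }
  out
}

## Run expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

## Deterministic per-stage seed derived from one global seed (kept < 2^31).
deriveSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483587)
}

## ---- ESRI ASCII grid I/O --------------------------------------------------

#' Write a matrix as an ESRI ASCII grid
#'
#' Plain-text raster interchange format; row 1 of the file is the northern
#' edge, so the matrix (rows = northing, ascending) is written bottom-up.
#'
#' @param m numeric matrix (rows = northing).
#' @param path output file.
#' @param origin numeric(2) lower-left corner (m).
#' @param cellSize cell edge (m).
#' @param naValue value written for NA cells.
#' @export
writeAsciiGrid <- function(m, path, origin, cellSize, naValue = -9999) {
  hdr <- c(
    paste("ncols", ncol(m)), paste("nrows", nrow(m)),
    paste("xllcorner", origin[1]), paste("yllcorner", origin[2]),
    paste("cellsize", cellSize), paste("NODATA_value", naValue))
  mm <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  mm[is.na(mm)] <- naValue
  lines <- apply(mm, 1, function(r)
    paste(formatC(r, digits = 17, format = "g"), collapse = " "))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#' @param path file written by \code{\link{writeAsciiGrid}} or another tool.
#' @return list(values = matrix with rows = northing ascending,
#'   origin = numeric(2), cellSize = numeric(1)).
#' @export
readAsciiGrid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  h <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  vals <- scan(text = lines[-(1:6)], quiet = TRUE)
  m <- matrix(vals, nrow = h[["nrows"]], ncol = h[["ncols"]], byrow = TRUE)
  m[m == h[["nodata_value"]]] <- NA
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  list(values = m, origin = c(h[["xllcorner"]], h[["yllcorner"]]),
       cellSize = h[["cellsize"]])
}
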