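#' @include metrics.R
NULL

#' Zone presence/absence labels on the climate lattice
#'
#' A climate cell is labelled present when the mean total alpine-community
#' cover of its constituent fine cells exceeds \code{coverThreshold}
#' (default 0: any cover counts).
#'
#' @param vegetation a \linkS4class{VegetationMap} at fine resolution.
#' @param bioclim a \linkS4class{BioclimGrid} at climate resolution.
#' @param coverThreshold mean-cover threshold for presence.
#' @return data.frame: wi, tmc, prs, msw, zonePresence (0/1), cellRow,
#'   cellCol.
#' @export
makeZoneLabels <- function(vegetation, bioclim, coverThreshold = 0) {
  fac <- bioclim@cellSize / vegetation@cellSize
  if (fac != round(fac)) stop("grids do not nest")
  tot <- vegetation@pinusPumila + vegetation@snowbed + vegetation@fellfield
  cover <- blockAggregate(tot, fac)
  d <- dim(cover)
  data.frame(
    cellRow = as.vector(row(cover)), cellCol = as.vector(col(cover)),
    wi = as.vector(bioclim@wi), tmc = as.vector(bioclim@tmc),
    prs = as.vector(bioclim@prs), msw = as.vector(bioclim@msw),
    zonePresence = as.integer(as.vector(cover) > coverThreshold))
}

.kFor <- function(x, k) min(k, max(3L, length(unique(round(x, 8))) - 1L))

#' Fit the alpine-vegetation-zone occurrence model
#'
#' Additive logistic (binomial, logit link) model of zone presence with a
#' bivariate thin-plate smooth of (WI, TMC) and univariate smooths of PRS
#' and MSW, smoothness selected by REML. Basis dimensions shrink
#' automatically when a predictor has few unique values.
#'
#' @param table data.frame from \code{\link{makeZoneLabels}} (columns wi,
#'   tmc, prs, msw, zonePresence), >= 50 rows, both classes present.
#' @param k2 basis dimension of the bivariate smooth (default 25).
#' @param k1 basis dimension of the univariate smooths (default 10).
#' @param cutoff sensitivity cutoff for the training threshold.
#' @return a \linkS4class{ZoneModel}.
#' @export
fitZoneModel <- function(table, k2 = 25L, k1 = 10L, cutoff = 0.95) {
  if (nrow(table) < 50) stop("need at least 50 training rows")
  if (length(unique(table$zonePresence)) < 2L)
    stop("degenerate data: a single presence class")
  k2u <- min(k2, max(4L, nrow(unique(round(table[, c("wi", "tmc")], 8))) - 1L))
  form <- stats::as.formula(sprintf(
    "zonePresence ~ s(wi, tmc, k = %d) + s(prs, k = %d) + s(msw, k = %d)",
    k2u, .kFor(table$prs, k1), .kFor(table$msw, k1)))
  fit <- mgcv::gam(form, family = stats::binomial(), data = table,
                   method = "REML")
  scores <- as.vector(stats::predict(fit, type = "response"))
  rep <- validationReport(scores, table$zonePresence, cutoff = cutoff)
  new("ZoneModel", fit = fit, training = table, metrics = rep)
}

#' Predict zone occurrence probability
#'
#' Applies the fitted zone model to a bioclim grid; optionally resamples
#' the climate-resolution probabilities to the fine lattice by nearest
#' neighbour (the coarse values are preserved exactly).
#'
#' @param model a \linkS4class{ZoneModel}.
#' @param bioclim a \linkS4class{BioclimGrid}.
#' @param fineFactor integer; if > 1, replicate each climate cell into a
#'   fineFactor x fineFactor block.
#' @return matrix of probabilities in (0, 1).
#' @export
predictZoneProbability <- function(model, bioclim, fineFactor = 1L) {
  nd <- data.frame(wi = as.vector(bioclim@wi), tmc = as.vector(bioclim@tmc),
                   prs = as.vector(bioclim@prs),
                   msw = as.vector(bioclim@msw))
  p <- matrix(as.vector(stats::predict(model@fit, newdata = nd,
                                       type = "response")),
              nrow(bioclim@wi), ncol(bioclim@wi))
  if (fineFactor > 1L) p <- disaggregateNearest(p, fineFactor)
  p
}

.fractionPredictors <- c("slope", "aspect", "curvature", "twi",
                         "ridgeDistance", "zoneProbability")

#' Assemble the area-fraction training table
#'
#' One row per interior fine cell: the five topographic predictors, the
#' zone occurrence probability, and the observed area fraction of one
#' community. Border cells (incomplete derivative stencils) and flat cells
#' with undefined aspect are dropped.
#'
#' @param terrain a \linkS4class{TerrainGrid}.
#' @param zoneProbabilityFine matrix at fine resolution.
#' @param vegetation a \linkS4class{VegetationMap}.
#' @param community one of "pinusPumila", "snowbed", "fellfield".
#' @return data.frame with the predictors and column \code{fraction}.
#' @export
fractionTrainingTable <- function(terrain, zoneProbabilityFine, vegetation,
                                  community = c("pinusPumila", "snowbed",
                                                "fellfield")) {
  community <- match.arg(community)
  d <- dim(terrain@elevation)
  keep <- trainingMask(d[1], d[2]) & !is.na(terrain@aspect)
  out <- data.frame(
    slope = terrain@slope[keep], aspect = terrain@aspect[keep],
    curvature = terrain@curvature[keep], twi = terrain@twi[keep],
    ridgeDistance = terrain@ridgeDistance[keep],
    zoneProbability = zoneProbabilityFine[keep],
    fraction = slot(vegetation, community)[keep])
  if (any(out$fraction < 0 | out$fraction > 1))
    stop("area fractions must lie in [0, 1]")
  out
}

#' Fit the three community area-fraction forests
#'
#' One random-forest regression per community on the five topographic
#' predictors plus zone probability; 500 trees and floor(p/3) variables per
#' split by default. Deterministic given the seed. Out-of-bag MSE and
#' increased-MSE permutation importance are recorded.
#'
#' @param tables named list of three training tables
#'   (\code{\link{fractionTrainingTable}}) with names pinusPumila, snowbed,
#'   fellfield.
#' @param nTrees trees per forest.
#' @param seed integer.
#' @param nPermutations permutations per variable for the importance.
#' @param maxRows if finite, each table is subsampled (seeded) to at most
#'   this many rows before fitting.
#' @return a \linkS4class{FractionModels}.
#' @export
fitFractionModels <- function(tables, nTrees = 500L, seed = 1L,
                              nPermutations = 5L, maxRows = Inf) {
  need <- c("pinusPumila", "snowbed", "fellfield")
  if (!all(need %in% names(tables)))
    stop("tables must be named pinusPumila, snowbed, fellfield")
  forests <- list(); oob <- numeric(0); imp <- list()
  for (cm in need) {
    tb <- tables[[cm]]
    if (nrow(tb) > maxRows)
      tb <- withSeed(deriveSeed(seed, paste0("sub", cm)),
                     tb[sample.int(nrow(tb), maxRows), , drop = FALSE])
    rf <- withSeed(deriveSeed(seed, cm),
      randomForest::randomForest(
        x = tb[, .fractionPredictors], y = tb$fraction,
        ntree = nTrees, mtry = max(1L, floor(length(.fractionPredictors) / 3))))
    forests[[cm]] <- rf
    oob[cm] <- rf$mse[length(rf$mse)]
    impV <- increasedMseImportance(rf, tb, response = "fraction",
                                   nPermutations = nPermutations,
                                   seed = deriveSeed(seed, paste0("imp", cm)))
    imp[[cm]] <- data.frame(community = cm, variable = names(impV),
                            increasedMse = unname(impV))
  }
  new("FractionModels", forests = forests,
      importance = do.call(rbind, c(imp, list(make.row.names = FALSE))),
      oob = oob, seed = as.integer(seed))
}

#' Increased-MSE permutation importance
#'
#' Importance of a predictor is the mean, over seeded permutations, of the
#' increase in prediction MSE when that predictor's column is permuted,
#' relative to the unpermuted baseline. The response column itself may not
#' be permuted.
#'
#' @param model a fitted regressor with a \code{predict} method (e.g. one
#'   forest from \code{\link{fitFractionModels}}).
#' @param table data.frame holding the predictors and the response.
#' @param response name of the response column (excluded from permutation).
#' @param variables predictor columns to assess (default: all but the
#'   response).
#' @param nPermutations permutations per variable.
#' @param seed integer.
#' @return named numeric of increased MSE per variable.
#' @export
increasedMseImportance <- function(model, table, response,
                                   variables = setdiff(names(table),
                                                       response),
                                   nPermutations = 5L, seed = 1L) {
  if (response %in% variables)
    stop("the response column may not be permuted")
  y <- table[[response]]
  base <- mean((stats::predict(model, table) - y)^2)
  withSeed(seed, vapply(variables, function(v) {
    mean(vapply(seq_len(nPermutations), function(i) {
      tb <- table
      tb[[v]] <- sample(tb[[v]])
      mean((stats::predict(model, tb) - y)^2) - base
    }, numeric(1)))
  }, numeric(1)))
}

#' Predict community area fractions over the landscape
#'
#' Applies the three forests to the terrain predictors and a fine-lattice
#' zone-probability grid. Predictions are clipped to [0, 1]; where the three
#' communities would sum above 1 they are rescaled proportionally (never by
#' truncating one community first).
#'
#' @param model a \linkS4class{FractionModels}.
#' @param terrain a \linkS4class{TerrainGrid}.
#' @param zoneProbabilityFine matrix at fine resolution.
#' @return a \linkS4class{VegetationMap}; attribute \code{"nRescaled"} gives
#'   the number of cells whose fraction sum was rescaled.
#' @export
predictFractions <- function(model, terrain, zoneProbabilityFine) {
  d <- dim(terrain@elevation)
  asp <- terrain@aspect
  asp[is.na(asp)] <- 0           # flat cells: arbitrary but fixed direction
  nd <- data.frame(
    slope = as.vector(terrain@slope), aspect = as.vector(asp),
    curvature = as.vector(terrain@curvature), twi = as.vector(terrain@twi),
    ridgeDistance = as.vector(terrain@ridgeDistance),
    zoneProbability = as.vector(zoneProbabilityFine))
  pred <- lapply(model@forests, function(rf)
    matrix(pmin(pmax(stats::predict(rf, nd), 0), 1), d[1], d[2]))
  tot <- pred$pinusPumila + pred$snowbed + pred$fellfield
  over <- tot > 1
  if (any(over)) {
    sc <- ifelse(over, 1 / tot, 1)
    pred <- lapply(pred, function(f) f * sc)
  }
  out <- new("VegetationMap", origin = terrain@origin,
             cellSize = terrain@cellSize, pinusPumila = pred$pinusPumila,
             snowbed = pred$snowbed, fellfield = pred$fellfield)
  attr(out, "nRescaled") <- sum(over)
  out
}
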