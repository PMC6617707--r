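#' @include vegetation-models.R
NULL

#' Aggregate fine-cell predictors to the territory lattice
#'
#' Each territory cell's community fraction is the mean of its constituent
#' fine-cell fractions (which conserves domain-total community area across
#' resolutions), and its ridge distance is the mean fine-cell distance.
#'
#' @param vegetation a \linkS4class{VegetationMap} at fine resolution.
#' @param terrain a \linkS4class{TerrainGrid} at the same resolution.
#' @param territoryResolutionM territory cell edge (m); an integer multiple
#'   of the fine resolution.
#' @return data.frame: cellRow, cellCol, afPp, afSg, afFf, dr (column-major
#'   cell order).
#' @export
aggregatePredictors <- function(vegetation, terrain,
                                territoryResolutionM = 300) {
  fac <- territoryResolutionM / vegetation@cellSize
  if (fac != round(fac) || fac < 1)
    stop("territory resolution must be an integer multiple of the fine ",
         "resolution")
  agg <- function(m) blockAggregate(m, fac)
  pp <- agg(vegetation@pinusPumila)
  data.frame(
    cellRow = as.vector(row(pp)), cellCol = as.vector(col(pp)),
    afPp = as.vector(pp), afSg = as.vector(agg(vegetation@snowbed)),
    afFf = as.vector(agg(vegetation@fellfield)),
    dr = as.vector(agg(terrain@ridgeDistance)))
}

.habitatFormula <- function(terms, k2, k1, data) {
  rhs <- character(0)
  if ("drPp" %in% terms) {
    k2u <- min(k2, max(4L, nrow(unique(round(data[, c("dr", "afPp")], 8))) - 1L))
    rhs <- c(rhs, sprintf("s(dr, afPp, k = %d)", k2u))
  }
  if ("ff" %in% terms)
    rhs <- c(rhs, sprintf("s(afFf, k = %d)", .kFor(data$afFf, k1)))
  if ("sg" %in% terms)
    rhs <- c(rhs, sprintf("s(afSg, k = %d)", .kFor(data$afSg, k1)))
  rhs <- c(if (length(rhs)) rhs else "1", "offset(log(nSurveys))")
  stats::as.formula(paste("presence ~", paste(rhs, collapse = " + ")))
}

#' Fit the territory habitat model
#'
#' Additive logistic model of territory presence with a bivariate
#' thin-plate smooth of (ridge distance, P. pumila fraction), univariate
#' smooths of the fellfield and snowbed fractions, and
#' \code{log(nSurveys)} as an offset on the linear predictor so unequal
#' survey effort is absorbed rather than confounded with habitat quality.
#'
#' Training metrics (AUC, sensitivity, specificity) and the habitat
#' threshold are computed on predictions standardised at the reference
#' effort (default one survey), so the threshold applies directly to
#' projection maps.
#'
#' @param obs a \linkS4class{TerritoryObservations} or its data.frame.
#' @param k2,k1 smooth basis dimensions (bivariate / univariate).
#' @param cutoff sensitivity cutoff for the habitat threshold (default 0.95).
#' @param referenceEffort survey count at which maps are standardised.
#' @param seed integer for the bootstrap validation.
#' @return a \linkS4class{HabitatModel}.
#' @export
fitHabitatModel <- function(obs, k2 = 25L, k1 = 10L, cutoff = 0.95,
                            referenceEffort = 1, seed = 1L) {
  d <- if (is(obs, "TerritoryObservations")) obs@data else obs
  if (length(unique(d$presence)) < 2L)
    stop("degenerate data: a single presence class")
  if (any(d$nSurveys < 1)) stop("invalid input: zero surveys in a row")
  fit <- mgcv::gam(.habitatFormula(c("drPp", "ff", "sg"), k2, k1, d),
                   family = stats::binomial(), data = d, method = "REML")
  nd <- d; nd$nSurveys <- referenceEffort
  scores <- as.vector(stats::predict(fit, newdata = nd, type = "response"))
  rep <- validationReport(scores, d$presence, cutoff = cutoff, seed = seed)
  new("HabitatModel", fit = fit, threshold = rep$threshold,
      referenceEffort = referenceEffort, metrics = rep, training = d)
}

#' Predict habitat probability at a fixed survey effort
#'
#' Predictions are standardised at \code{effort} surveys; changing the
#' effort shifts every prediction by \code{log(effort)} on the logit scale
#' and nothing else.
#'
#' @param model a \linkS4class{HabitatModel}.
#' @param predictors data.frame with columns afPp, afSg, afFf, dr (e.g.
#'   from \code{\link{aggregatePredictors}}).
#' @param effort reference survey count (default: the model's).
#' @return numeric vector of probabilities in (0, 1).
#' @export
predictHabitatProbability <- function(model, predictors,
                                      effort = model@referenceEffort) {
  nd <- predictors
  nd$nSurveys <- effort
  as.vector(stats::predict(model@fit, newdata = nd, type = "response"))
}

#' Akaike-weight importance of the habitat-model terms
#'
#' Fits all 2^3 = 8 subset models over the candidate terms
#' \{s(DR, AF_Pp), s(AF_Ff), s(AF_Sg)\} (the bivariate term enters as a
#' single unit; the null model retains only the intercept and the effort
#' offset), computes Akaike weights
#' \code{exp(-dAIC/2) / sum(exp(-dAIC/2))}, and reports each term's
#' importance (IOV) as the summed weight of the models containing it.
#' AIC uses the effective degrees of freedom of the penalised smooths.
#'
#' @param obs a \linkS4class{TerritoryObservations} or its data.frame.
#' @param k2,k1 smooth basis dimensions.
#' @return list: \code{models} (data.frame model, aic, deltaAic, weight) and
#'   \code{iov} (named numeric for s(DR,AF_Pp), s(AF_Ff), s(AF_Sg)).
#' @export
iovAkaike <- function(obs, k2 = 25L, k1 = 10L) {
  d <- if (is(obs, "TerritoryObservations")) obs@data else obs
  termSets <- list(
    character(0), "drPp", "ff", "sg", c("drPp", "ff"), c("drPp", "sg"),
    c("ff", "sg"), c("drPp", "ff", "sg"))
  labels <- vapply(termSets, function(ts) {
    if (!length(ts)) return("null")
    paste(c("s(DR,AF_Pp)", "s(AF_Ff)", "s(AF_Sg)")[
      c("drPp", "ff", "sg") %in% ts], collapse = " + ")
  }, character(1))
  aics <- vapply(termSets, function(ts) {
    f <- if (length(ts)) .habitatFormula(ts, k2, k1, d) else
      presence ~ 1 + offset(log(nSurveys))
    stats::AIC(mgcv::gam(f, family = stats::binomial(), data = d,
                         method = "REML"))
  }, numeric(1))
  delta <- aics - min(aics)
  w <- exp(-delta / 2); w <- w / sum(w)
  iov <- vapply(c("drPp", "ff", "sg"), function(tm)
    sum(w[vapply(termSets, function(ts) tm %in% ts, logical(1))]),
    numeric(1))
  names(iov) <- c("s(DR,AF_Pp)", "s(AF_Ff)", "s(AF_Sg)")
  list(models = data.frame(model = labels, aic = aics, deltaAic = delta,
                           weight = w), iov = iov)
}
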