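#' @include grid-methods.R
NULL

.checkLabels <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  if (length(unique(labels)) < 2L)
    stop("undefined metric: labels contain a single class")
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation: the probability that a randomly chosen
#' presence outscores a randomly chosen absence, ties counted one half.
#' Satisfies \code{rocAuc(s, y) + rocAuc(s, 1 - y) == 1} exactly and is
#' invariant under strictly monotone transforms of the scores.
#'
#' @param scores numeric scores (e.g. predicted probabilities).
#' @param labels 0/1 vector with both classes present.
#' @return AUC in [0, 1].
#' @export
rocAuc <- function(scores, labels) {
  .checkLabels(scores, labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Habitat threshold at a fixed training sensitivity
#'
#' The largest threshold t such that at least \code{cutoff} of the presence
#' scores are >= t; cells scoring at or above t are classed as habitat, so
#' training sensitivity is guaranteed to be at least the cutoff. Ties are
#' resolved towards the largest qualifying threshold (the most conservative
#' habitat extent at the required sensitivity).
#'
#' @param scores,labels as in \code{\link{rocAuc}}.
#' @param cutoff required sensitivity (default 0.95).
#' @return the threshold (one of the presence scores).
#' @export
thresholdAtSensitivity <- function(scores, labels, cutoff = 0.95) {
  .checkLabels(scores, labels)
  if (cutoff < 0 || cutoff > 1) stop("cutoff must be in [0, 1]")
  ps <- sort(scores[labels == 1])
  n1 <- length(ps)
  i <- min(floor(n1 * (1 - cutoff)) + 1L, n1)
  ps[i]
}

#' Sensitivity and specificity at a threshold
#'
#' Scores at or above the threshold count as predicted presence.
#'
#' @param scores,labels as in \code{\link{rocAuc}}.
#' @param threshold classification threshold.
#' @return named numeric(2): sensitivity, specificity.
#' @export
sensitivitySpecificity <- function(scores, labels, threshold) {
  .checkLabels(scores, labels)
  pred <- scores >= threshold
  c(sensitivity = mean(pred[labels == 1]),
    specificity = mean(!pred[labels == 0]))
}

#' Bootstrap AUC validation
#'
#' The model is fitted once; validation sets are drawn by resampling the
#' scored training rows with replacement (100 repetitions by default) and
#' the AUC is recomputed on each resample. This validates against bootstrap
#' replicates of the training data, so results can be slightly optimistic.
#'
#' @param scores fitted scores for all training rows (or a fitted model with
#'   a \code{predict} method, together with \code{data}).
#' @param labels 0/1 training labels.
#' @param nReps bootstrap repetitions.
#' @param seed integer; fixes the resampling.
#' @return list(mean, sd, aucs).
#' @export
bootstrapAuc <- function(scores, labels, nReps = 100L, seed = 1L) {
  .checkLabels(scores, labels)
  n <- length(scores)
  aucs <- withSeed(seed, vapply(seq_len(nReps), function(i) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(labels[idx])) == 2L) break
    }
    rocAuc(scores[idx], labels[idx])
  }, numeric(1)))
  list(mean = mean(aucs), sd = stats::sd(aucs), aucs = aucs)
}

#' Spearman rank correlation between predicted and actual values
#'
#' @param predicted,actual numeric vectors of equal length.
#' @return list(rho, p) from the rank correlation test (ties handled by the
#'   normal approximation).
#' @export
spearmanRho <- function(predicted, actual) {
  if (length(predicted) != length(actual))
    stop("predicted and actual must have equal length")
  ct <- suppressWarnings(stats::cor.test(predicted, actual,
                                         method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Training-set validation report for a scored classifier
#'
#' Bundles AUC, the threshold at the sensitivity cutoff, and sensitivity /
#' specificity at that threshold, plus the bootstrap AUC.
#'
#' @param scores,labels as in \code{\link{rocAuc}}.
#' @param cutoff sensitivity cutoff for thresholding.
#' @param nBootstrap bootstrap repetitions.
#' @param seed integer.
#' @return list: auc, aucSd, sensitivity, specificity, threshold,
#'   nBootstrap, cutoff.
#' @export
validationReport <- function(scores, labels, cutoff = 0.95,
                             nBootstrap = 100L, seed = 1L) {
  thr <- thresholdAtSensitivity(scores, labels, cutoff)
  ss <- sensitivitySpecificity(scores, labels, thr)
  bs <- bootstrapAuc(scores, labels, nBootstrap, seed)
  list(auc = rocAuc(scores, labels), aucSd = bs$sd,
       aucBootstrapMean = bs$mean,
       sensitivity = unname(ss["sensitivity"]),
       specificity = unname(ss["specificity"]),
       threshold = thr, nBootstrap = nBootstrap, cutoff = cutoff)
}
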