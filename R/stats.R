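#' @include AllClasses.R
NULL

#' Balanced per-sample class weights
#'
#' Weighting scheme equalizing the total contribution of the two diagnostic
#' classes to the SVM: a sample of class c gets weight N_total / (2 * N_c),
#' so each class sums to N_total / 2. With the study's cohort (286 WBS,
#' 161 NS) the weights are 447/572 and 447/322.
#'
#' @param labels vector of class labels (exactly two distinct values).
#' @return numeric vector of per-sample weights, aligned with
#'   \code{labels}.
#' @export
#' @examples
#' balancedClassWeights(rep(c("WBS", "NS"), c(286, 161)))[c(1, 447)]
balancedClassWeights <- function(labels) {
  tab <- table(labels)
  if (length(tab) < 2L)
    stop("both classes must be present")
  if (length(tab) > 2L)
    stop("exactly two classes expected, got ", length(tab))
  n <- length(labels)
  w <- n / (2 * tab[match(as.character(labels), names(tab))])
  as.numeric(w)
}

## Mann-Whitney U of sample a (number of (a, b) pairs with a > b, ties
## counted 1/2), computed from midranks.
.uStatistic <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

#' Mann-Whitney U test for one feature
#'
#' U is computed from rank sums with midranks for ties. The two-sided p is
#' exact (full enumeration of the rank distribution) when the combined
#' sample size is at most 20 and there are no ties, and otherwise uses the
#' normal approximation with tie correction and continuity correction.
#'
#' @param a,b numeric vectors (both nonempty).
#' @return list with \code{U} (for sample \code{a}) and \code{p}.
#' @export
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
mannWhitneyU <- function(a, b) {
  if (!length(a) || !length(b))
    stop("both groups must be nonempty")
  U <- .uStatistic(a, b)
  if (all(c(a, b) == c(a, b)[1]))
    return(list(U = U, p = 1))
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b) <= 20) && !ties
  p <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
  list(U = U, p = min(1, p))
}

#' Relative accuracy improvement in percent
#'
#' @param accGlobal,accSpecific accuracies (any common scale, e.g. percent).
#' @return 100 * (accSpecific - accGlobal) / accGlobal.
#' @export
#' @examples
#' relativeImprovement(87.30, 93.65) # 7.27
relativeImprovement <- function(accGlobal, accSpecific) {
  if (any(accGlobal <= 0))
    stop("baseline accuracy must be positive")
  100 * (accSpecific - accGlobal) / accGlobal
}

#' Fisher-exact comparison of two classifiers
#'
#' Builds the 2x2 table [[correctA, totalA - correctA], [correctB,
#' totalB - correctB]] and tests it with the two-sided Fisher exact rule
#' (sum of hypergeometric probabilities not exceeding that of the observed
#' table). Also reports both accuracies (percent) and the relative
#' improvement of model B over model A.
#'
#' @param correctA,totalA,correctB,totalB correct counts and cohort sizes
#'   of the two models.
#' @return a \linkS4class{ModelComparison}.
#' @export
#' @examples
#' fisherCompare(381, 447, 404, 447)
fisherCompare <- function(correctA, totalA, correctB, totalB) {
  if (totalA <= 0 || totalB <= 0)
    stop("totals must be positive")
  if (correctA < 0 || correctA > totalA || correctB < 0 || correctB > totalB)
    stop("correct counts must lie within [0, total]")
  counts <- matrix(as.integer(c(correctA, totalA - correctA,
                                correctB, totalB - correctB)),
                   2, 2, byrow = TRUE,
                   dimnames = list(c("A", "B"), c("correct", "incorrect")))
  p <- stats::fisher.test(counts)$p.value
  accA <- 100 * correctA / totalA
  accB <- 100 * correctB / totalB
  new("ModelComparison", counts = counts, pValue = min(1, p),
      accuracies = c(A = accA, B = accB),
      relativeImprovement = if (accA > 0)
        relativeImprovement(accA, accB) else NA_real_)
}

## Rank-based ROC AUC of scores for the positive class (ties credited 1/2).
.rankAuc <- function(scores, truth, positive) {
  pos <- truth == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  .uStatistic(scores[pos], scores[!pos]) / (n1 * n0)
}
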