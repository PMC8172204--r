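#' @include AllClasses.R stats.R
#' @useDynLib FacePheno, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## z-score parameters on training data only; constant features get scale 1
.zParams <- function(X) {
  m <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  s[!is.finite(s) | s < 1e-12] <- 1
  list(m = m, s = s)
}

.zApply <- function(X, zp) sweep(sweep(X, 2, zp$m), 2, zp$s, "/")

.asSignedLabels <- function(y, positive = "NS") {
  ifelse(y == positive, 1L, -1L)
}

#' Fit a weighted linear SVM
#'
#' L2-regularized hinge-loss linear SVM solved by deterministic dual
#' coordinate descent, with per-sample costs \code{C * weights}. Features
#' are z-scored internally; the returned coefficients apply to raw features.
#'
#' @param X numeric matrix, subjects x features.
#' @param y class labels; \code{positive} is coded +1.
#' @param weights per-sample weights (default: balanced class weights).
#' @param C regularization constant (default 1).
#' @param positive label treated as the positive class (default "NS").
#' @return list with \code{w}, \code{b} (raw-feature scale), the z-score
#'   parameters, and \code{decision(Xnew)}.
#' @export
linearSvm <- function(X, y, weights = balancedClassWeights(y), C = 1,
                      positive = "NS") {
  if (!all(is.finite(X)))
    stop("non-finite feature values")
  zp <- .zParams(X)
  Xs <- .zApply(X, zp)
  ys <- .asSignedLabels(y, positive)
  fit <- .cppSvmFit(t(Xs), ys, C * weights)
  wz <- as.numeric(fit$w)
  w <- wz / zp$s
  b <- fit$b - sum(wz * zp$m / zp$s)
  names(w) <- colnames(X)
  list(w = w, b = b, zparams = zp, positive = positive,
       decision = function(Xnew) drop(Xnew %*% w) + b)
}

#' SVM recursive feature elimination ranking
#'
#' Repeatedly fits the class-weighted linear SVM on z-scored features and
#' eliminates the features with smallest absolute coefficient: 10 percent of
#' the remaining features per round while more than \code{keepExact} (64)
#' remain, then one at a time. Ties on |coefficient| are broken in
#' lexicographic feature-name order. Rank 1 is the last-eliminated (most
#' discriminative) feature.
#'
#' @inheritParams linearSvm
#' @param step optional fixed number of features to eliminate per round;
#'   \code{step = ncol(X)} performs a single round so the ranking is the
#'   plain |coefficient| order. Default \code{NULL} uses the 10-percent
#'   schedule.
#' @param keepExact switch to one-at-a-time elimination below this count.
#' @return character vector of feature names, best rank first.
#' @export
svmRfeRanking <- function(X, y, weights = balancedClassWeights(y), C = 1,
                          step = NULL, keepExact = 64, positive = "NS") {
  if (!all(is.finite(X)))
    stop("non-finite feature values")
  if (min(table(y)) < 2)
    stop("at least 2 samples per class required")
  zp <- .zParams(X)
  Xs <- .zApply(X, zp)
  ys <- .asSignedLabels(y, positive)
  tieOrder <- rank(colnames(X), ties.method = "first")
  elim <- .cppRfeRank(t(Xs), ys, C * weights, as.integer(tieOrder),
                      keepExact = as.integer(keepExact),
                      fixedStep = if (is.null(step)) 0L else as.integer(step))
  colnames(X)[rev(elim)]
}

#' Default feature-count grid for LOOCV curves
#'
#' 1..min(40, p) plus the powers of two up to p and p itself.
#'
#' @param p total number of features.
#' @return increasing integer vector.
#' @export
defaultKGrid <- function(p) {
  ks <- seq_len(min(40L, p))
  pw <- 2^(0:30)
  sort(unique(c(ks, pw[pw <= p], p)))
}

#' Leave-one-out cross-validated performance across feature counts
#'
#' For each left-out subject, the z-score parameters, the RFE ranking (under
#' the default \code{nested} protocol) and every SVM fit are computed on the
#' remaining subjects only; the held-out subject is then scored by the
#' top-k model for every k in the grid. Per k, the pooled held-out decision
#' values yield the overall accuracy, per-class accuracies and ROC AUC.
#' The \code{flat} protocol reuses a single full-data ranking in every fold
#' (faster, replicates protocols that tolerate selection leakage).
#'
#' @param fset a \linkS4class{FaceFeatureSet} (or a list with elements
#'   \code{X} subjects x features and \code{y} labels).
#' @param kGrid feature counts to evaluate (default
#'   \code{\link{defaultKGrid}}).
#' @param protocol \code{"nested"} (default) or \code{"flat"}.
#' @param C SVM regularization constant.
#' @param positive positive class label for ROC (default "NS").
#' @return list with \code{curves} (data.frame k / accuracy /
#'   accuracy_NS / accuracy_WBS / auc), \code{scores} (k-grid x subjects
#'   held-out decision values), \code{truth}, and \code{subjects}.
#' @export
loocvCurve <- function(fset, kGrid = NULL, protocol = c("nested", "flat"),
                       C = 1, positive = "NS") {
  protocol <- match.arg(protocol)
  d <- .featureData(fset)
  X <- d$X; y <- d$y
  n <- nrow(X); p <- ncol(X)
  if (n < 10)
    stop("cohort size must be at least 10 for LOOCV curves")
  if (is.null(kGrid)) kGrid <- defaultKGrid(p)
  kGrid <- sort(unique(pmin(as.integer(kGrid), p)))
  flatRank <- if (protocol == "flat") svmRfeRanking(X, y, C = C,
                                                   positive = positive)
  scores <- matrix(NA_real_, length(kGrid), n,
                   dimnames = list(paste0("k", kGrid), rownames(X)))
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (length(unique(ytr)) < 2)
      stop("a training fold lost one class entirely")
    Xtr <- X[-i, , drop = FALSE]
    zp <- .zParams(Xtr)
    Xs <- .zApply(Xtr, zp)
    ys <- .asSignedLabels(ytr, positive)
    Ci <- C * balancedClassWeights(ytr)
    ranking <- if (protocol == "nested") {
      tieOrder <- rank(colnames(X), ties.method = "first")
      elim <- .cppRfeRank(t(Xs), ys, Ci, as.integer(tieOrder))
      colnames(X)[rev(elim)]
    } else flatRank
    Xts <- (X[i, ] - zp$m) / zp$s
    Xst <- t(Xs)
    for (ki in seq_along(kGrid)) {
      sel <- match(ranking[seq_len(kGrid[ki])], colnames(X))
      fit <- .cppSvmFit(Xst[sel, , drop = FALSE], ys, Ci)
      scores[ki, i] <- sum(fit$w * Xts[sel]) + fit$b
    }
  }
  lev <- sort(unique(y))
  curves <- data.frame(k = kGrid)
  pred <- scores > 0
  truthPos <- y == positive
  curves$accuracy <- rowMeans(pred == matrix(truthPos, length(kGrid), n,
                                             byrow = TRUE))
  for (cl in lev) {
    idx <- y == cl
    curves[[paste0("accuracy_", cl)]] <-
      rowMeans(pred[, idx, drop = FALSE] ==
                 matrix(truthPos[idx], length(kGrid), sum(idx), byrow = TRUE))
  }
  curves$auc <- apply(scores, 1, .rankAuc, truth = y, positive = positive)
  list(curves = curves, scores = scores, truth = y,
       subjects = rownames(X), positive = positive)
}

#' Feature count at which the AUC curve converges
#'
#' The chosen count is the smallest k whose AUC is within \code{epsilon} of
#' the maximum over the evaluated grid.
#'
#' @param aucByK named numeric vector (names = k) or a curves data.frame
#'   with columns \code{k} and \code{auc}.
#' @param epsilon AUC convergence tolerance (default 0.005).
#' @return the chosen k (integer).
#' @export
#' @examples
#' optimalK(c(`1` = 0.70, `2` = 0.80, `5` = 0.90, `10` = 0.905,
#'            `20` = 0.906), epsilon = 0.01)
optimalK <- function(aucByK, epsilon = 0.005) {
  if (is.data.frame(aucByK)) {
    k <- aucByK$k; auc <- aucByK$auc
  } else {
    k <- as.integer(names(aucByK)); auc <- as.numeric(aucByK)
  }
  if (!length(auc)) stop("empty AUC curve")
  stopifnot(epsilon > 0)
  o <- order(k)
  k <- k[o]; auc <- auc[o]
  as.integer(k[which(auc >= max(auc) - epsilon)[1]])
}

#' Run the full feature-selection protocol on a cohort
#'
#' Computes the LOOCV performance curves, chooses the optimal feature count
#' by AUC convergence, reports the full-data RFE ranking truncated at that
#' count as the final feature list, and screens each selected feature with
#' the Mann-Whitney U test (raw p-values plus a Benjamini-Hochberg column).
#'
#' @inheritParams loocvCurve
#' @param epsilon AUC convergence tolerance (default 0.005).
#' @param seed integer seed recorded in the result (the protocol itself is
#'   deterministic).
#' @return a \linkS4class{SelectionResult}.
#' @export
selectFeatures <- function(fset, kGrid = NULL,
                           protocol = c("nested", "flat"), C = 1,
                           epsilon = 0.005, positive = "NS", seed = 1L) {
  protocol <- match.arg(protocol)
  d <- .featureData(fset)
  cv <- loocvCurve(fset, kGrid = kGrid, protocol = protocol, C = C,
                   positive = positive)
  ks <- optimalK(cv$curves, epsilon)
  fullRank <- svmRfeRanking(d$X, d$y, C = C, positive = positive)
  selected <- fullRank[seq_len(ks)]
  ki <- match(ks, cv$curves$k)
  sc <- cv$scores[ki, ]
  predLab <- ifelse(sc > 0, positive, setdiff(sort(unique(d$y)), positive))
  preds <- data.frame(subject = cv$subjects, truth = d$y,
                      predicted = predLab, score = sc,
                      row.names = NULL, stringsAsFactors = FALSE)
  fs <- do.call(rbind, lapply(selected, function(f) {
    a <- d$X[d$y == positive, f]
    b <- d$X[d$y != positive, f]
    mw <- mannWhitneyU(a, b)
    data.frame(feature = f, U = mw$U, p = mw$p, stringsAsFactors = FALSE)
  }))
  fs$p_BH <- stats::p.adjust(fs$p, method = "BH")
  new("SelectionResult", ranking = fullRank, curves = cv$curves,
      kStar = as.integer(ks), selectedFeatures = selected,
      predictions = preds, featureStats = fs, protocol = protocol,
      seed = as.integer(seed))
}

#' Global and ethnicity-specific model evaluation
#'
#' Runs the selection + LOOCV protocol once on the pooled cohort (global
#' model) and once per ethnicity stratum (specific models). Reports, per
#' stratum, the accuracy of the global model on that stratum's subjects and
#' of the stratum-specific model, the relative improvement and the
#' Fisher-exact comparison; plus the pooled accountings: the global model's
#' overall accuracy (with per-class accuracies), the specific models' pooled
#' accuracy over evaluated strata, and their overall comparison. Strata
#' missing one class are skipped with a warning.
#'
#' @inheritParams selectFeatures
#' @return a list (JSON-serializable) with elements \code{global},
#'   \code{strata} and \code{overall}.
#' @export
stratifiedEvaluation <- function(fset, kGrid = NULL,
                                 protocol = c("nested", "flat"), C = 1,
                                 epsilon = 0.005, positive = "NS",
                                 seed = 1L) {
  protocol <- match.arg(protocol)
  d <- .featureData(fset)
  strata <- d$strata
  if (is.null(strata))
    stop("stratified evaluation needs per-subject ethnicity strata")
  glob <- selectFeatures(fset, kGrid = kGrid, protocol = protocol, C = C,
                         epsilon = epsilon, positive = positive, seed = seed)
  gp <- loocvPredictions(glob)
  gCorrect <- gp$truth == gp$predicted
  lev <- sort(unique(d$y))
  perClass <- vapply(lev, function(cl) mean(gCorrect[gp$truth == cl]),
                     numeric(1))
  classN <- vapply(lev, function(cl) sum(gp$truth == cl), numeric(1))
  out <- list(
    seed = seed, protocol = protocol,
    global = list(
      k_star = kStar(glob),
      selected_features = selectedFeatures(glob),
      accuracy = 100 * mean(gCorrect),
      accuracy_by_class = as.list(setNames(100 * perClass, lev)),
      accuracy_recombined = 100 * sum(perClass * classN) / sum(classN),
      curves = loocvCurves(glob)
    ),
    strata = list()
  )
  sCorrectTotal <- 0L; gCorrectEval <- 0L; nEval <- 0L
  for (s in sort(unique(strata))) {
    idx <- strata == s
    if (length(unique(d$y[idx])) < 2) {
      warning("stratum '", s, "' lacks one class entirely; skipped")
      next
    }
    if (sum(idx) < 10) {
      warning("stratum '", s, "' has fewer than 10 subjects; skipped")
      next
    }
    sub <- list(X = d$X[idx, , drop = FALSE], y = d$y[idx],
                strata = strata[idx])
    spec <- selectFeatures(sub, kGrid = kGrid, protocol = protocol, C = C,
                           epsilon = epsilon, positive = positive,
                           seed = seed)
    sp <- loocvPredictions(spec)
    nS <- sum(idx)
    cG <- sum(gCorrect[idx])
    cS <- sum(sp$truth == sp$predicted)
    cmp <- fisherCompare(cG, nS, cS, nS)
    out$strata[[s]] <- list(
      n = nS,
      k_star = kStar(spec),
      selected_features = selectedFeatures(spec),
      global_accuracy = 100 * cG / nS,
      specific_accuracy = 100 * cS / nS,
      improvement = cmp@relativeImprovement,
      fisher_p = cmp@pValue,
      counts = list(global_correct = cG, specific_correct = cS)
    )
    sCorrectTotal <- sCorrectTotal + cS
    gCorrectEval <- gCorrectEval + cG
    nEval <- nEval + nS
  }
  if (nEval > 0) {
    cmpAll <- fisherCompare(gCorrectEval, nEval, sCorrectTotal, nEval)
    out$overall <- list(
      n = nEval,
      global_accuracy = 100 * gCorrectEval / nEval,
      specific_accuracy = 100 * sCorrectTotal / nEval,
      improvement = cmpAll@relativeImprovement,
      fisher_p = cmpAll@pValue
    )
  }
  out
}

## Uniform access to X / y / strata for FaceFeatureSet or a plain list
.featureData <- function(fset) {
  out <- if (is(fset, "FaceFeatureSet")) {
    X <- t(SummarizedExperiment::assay(fset, "features"))
    cd <- SummarizedExperiment::colData(fset)
    list(X = X, y = as.character(cd$diagnosis),
         strata = as.character(cd$ethnicity))
  } else if (is.list(fset) && !is.null(fset$X)) {
    list(X = fset$X, y = as.character(fset$y),
         strata = if (!is.null(fset$strata)) as.character(fset$strata))
  } else {
    stop("expected a FaceFeatureSet or a list with X and y")
  }
  if (is.null(rownames(out$X)))
    rownames(out$X) <- sprintf("s%04d", seq_len(nrow(out$X)))
  out
}
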