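#' @include AllClasses.R
NULL

#' @rdname landmarkPoints
#' @export
setGeneric("landmarkPoints", function(x) standardGeneric("landmarkPoints"))

#' @rdname landmarkPoints
#' @export
setGeneric("subjectID", function(x) standardGeneric("subjectID"))

#' @rdname landmarkPoints
#' @export
setGeneric("lateralityPairs", function(x) standardGeneric("lateralityPairs"))

#' @rdname landmarkPoints
#' @export
setGeneric("innerLandmarks", function(x) standardGeneric("innerLandmarks"))

#' @rdname metricDefs
#' @export
setGeneric("metricDefs", function(x) standardGeneric("metricDefs"))

#' @rdname selectionAccessors
#' @export
setGeneric("featureRanking", function(x) standardGeneric("featureRanking"))

#' @rdname selectionAccessors
#' @export
setGeneric("loocvCurves", function(x) standardGeneric("loocvCurves"))

#' @rdname selectionAccessors
#' @export
setGeneric("kStar", function(x) standardGeneric("kStar"))

#' @rdname selectionAccessors
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))

#' @rdname selectionAccessors
#' @export
setGeneric("loocvPredictions", function(x) standardGeneric("loocvPredictions"))

#' @rdname selectionAccessors
#' @export
setGeneric("featureStats", function(x) standardGeneric("featureStats"))

#' @rdname consensusPoints
#' @export
setGeneric("consensusPoints", function(x) standardGeneric("consensusPoints"))

#' Accessors for LandmarkSet
#'
#' @param x a \linkS4class{LandmarkSet}.
#' @return \code{landmarkPoints}: the 44 x 2 coordinate matrix;
#'   \code{subjectID}: the subject identifier; \code{lateralityPairs}: the
#'   two-column left/right pairing matrix; \code{innerLandmarks}: the 33
#'   inner landmark names.
#' @name landmarkPoints
#' @aliases subjectID lateralityPairs innerLandmarks
NULL

#' @rdname landmarkPoints
#' @export
setMethod("landmarkPoints", "LandmarkSet", function(x) x@points)

#' @rdname landmarkPoints
#' @export
setMethod("subjectID", "LandmarkSet", function(x) x@subjectID)

#' @rdname landmarkPoints
#' @export
setMethod("lateralityPairs", "LandmarkSet", function(x) x@lateralityPairs)

#' @rdname landmarkPoints
#' @export
setMethod("innerLandmarks", "LandmarkSet", function(x) x@innerSubset)

#' Accessor for MetricCatalog definitions
#'
#' @param x a \linkS4class{MetricCatalog}.
#' @return the definitions data.frame.
#' @name metricDefs
NULL

#' @rdname metricDefs
#' @export
setMethod("metricDefs", "MetricCatalog", function(x) x@defs)

#' Accessors for SelectionResult
#'
#' @param x a \linkS4class{SelectionResult}.
#' @return \code{featureRanking}: feature names by elimination rank;
#'   \code{loocvCurves}: the per-k accuracy/AUC data.frame; \code{kStar}:
#'   the chosen feature count; \code{selectedFeatures}: the top-kStar
#'   features; \code{loocvPredictions}: per-subject held-out predictions at
#'   kStar; \code{featureStats}: the per-feature Mann-Whitney screen.
#' @name selectionAccessors
NULL

#' @rdname selectionAccessors
#' @export
setMethod("featureRanking", "SelectionResult", function(x) x@ranking)

#' @rdname selectionAccessors
#' @export
setMethod("loocvCurves", "SelectionResult", function(x) x@curves)

#' @rdname selectionAccessors
#' @export
setMethod("kStar", "SelectionResult", function(x) x@kStar)

#' @rdname selectionAccessors
#' @export
setMethod("selectedFeatures", "SelectionResult", function(x) x@selectedFeatures)

#' @rdname selectionAccessors
#' @export
setMethod("loocvPredictions", "SelectionResult", function(x) x@predictions)

#' @rdname selectionAccessors
#' @export
setMethod("featureStats", "SelectionResult", function(x) x@featureStats)

#' Accessor for ConsensusShape points
#'
#' @param x a \linkS4class{ConsensusShape}.
#' @return the consensus coordinate matrix.
#' @name consensusPoints
NULL

#' @rdname consensusPoints
#' @export
setMethod("consensusPoints", "ConsensusShape", function(x) x@points)

setMethod("show", "LandmarkSet", function(object) {
  cat("LandmarkSet '", object@subjectID, "': ",
      nrow(object@points), " landmarks (",
      nrow(object@lateralityPairs), " L/R pairs, ",
      length(object@innerSubset), " inner)\n", sep = "")
  rng <- apply(object@points, 2, range)
  cat(sprintf("  x: [%.1f, %.1f]  y: [%.1f, %.1f]\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2]))
})

setMethod("show", "MetricCatalog", function(object) {
  d <- object@defs
  cat("MetricCatalog:", nrow(d), "metrics (",
      sum(d$laterality == "paired"), "paired,",
      sum(d$laterality == "midline"), "midline;",
      sum(d$kind == "angle"), "angles )\n")
})

setMethod("show", "TexturePatchConfig", function(object) {
  cat("TexturePatchConfig: blocks", paste(object@blockSizes, collapse = "/"),
      "px @200px inter-tragion, rule", object@comparisonRule,
      ", representation", object@representation,
      if (object@scaleNormalize) "(scale-normalized)" else "(fixed px)", "\n")
})

setMethod("show", "SelectionResult", function(object) {
  cat("SelectionResult (protocol ", object@protocol, ", seed ",
      object@seed, ")\n", sep = "")
  cat("  features ranked:", length(object@ranking),
      "  k* =", object@kStar, "\n")
  if (nrow(object@curves)) {
    i <- match(object@kStar, object@curves$k)
    if (!is.na(i))
      cat(sprintf("  at k*: accuracy %.2f%%, AUC %.4f\n",
                  100 * object@curves$accuracy[i], object@curves$auc[i]))
  }
})

setMethod("show", "ModelComparison", function(object) {
  cat(sprintf(
    "ModelComparison: %.2f%% vs %.2f%% (improvement %.2f%%), Fisher p = %.4g\n",
    object@accuracies[1], object@accuracies[2],
    object@relativeImprovement, object@pValue))
})

setMethod("show", "ConsensusShape", function(object) {
  cat("ConsensusShape:", nrow(object@points), "landmarks,",
      length(object@transforms), "aligned inputs\n")
})

setMethod("show", "SyntheticCohort", function(object) {
  md <- object@metadata
  cat("SyntheticCohort:", nrow(md), "subjects")
  if (nrow(md)) {
    tb <- table(md$diagnosis)
    cat(" (", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), ")",
        sep = "")
  }
  cat("\n  strata:", paste(sort(unique(md$ethnicity)), collapse = ", "), "\n")
  cat("  images:", length(object@images), " planted features:",
      length(object@groundTruth$features), "\n")
})
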