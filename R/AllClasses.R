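#' @import methods
#' @importFrom stats setNames
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame
NULL

#' LandmarkSet: a named 44-point facial landmark configuration
#'
#' Holds the 2-D anatomical landmarks of one frontal face photograph in pixel
#' units (origin top-left, x rightward, y downward, 0-based), together with
#' the left/right pairing table used to form symmetric and asymmetry metrics
#' and the 33-name inner subset used for texture description.
#'
#' The five anchor landmarks \code{tragion_L}, \code{tragion_R},
#' \code{nasion}, \code{oral_commissure_L} and \code{oral_commissure_R} must
#' always be present: they define the intrinsic face frame and the two
#' normalization references (ear-to-ear distance and
#' commissure-midpoint-to-nasion distance).
#'
#' @slot subjectID character scalar identifier.
#' @slot points 44 x 2 numeric matrix, rownames = landmark names,
#'   columns \code{x}, \code{y}.
#' @slot lateralityPairs two-column character matrix (\code{left},
#'   \code{right}) of paired landmark names.
#' @slot innerSubset character vector of the 33 inner landmark names.
#' @export
setClass("LandmarkSet",
  representation(
    subjectID = "character",
    points = "matrix",
    lateralityPairs = "matrix",
    innerSubset = "character"
  )
)

setValidity("LandmarkSet", function(object) {
  p <- object@points
  msg <- character()
  if (length(object@subjectID) != 1L || is.na(object@subjectID))
    msg <- c(msg, "subjectID must be a single non-NA string")
  if (!is.numeric(p) || ncol(p) != 2L)
    msg <- c(msg, "points must be a numeric matrix with 2 columns")
  if (nrow(p) != 44L)
    msg <- c(msg, sprintf("exactly 44 landmarks required, got %d", nrow(p)))
  if (is.null(rownames(p)) || anyDuplicated(rownames(p)))
    msg <- c(msg, "points must have unique rownames")
  if (!all(is.finite(p)))
    msg <- c(msg, "all coordinates must be finite")
  anchors <- c("tragion_L", "tragion_R", "nasion",
               "oral_commissure_L", "oral_commissure_R")
  missA <- setdiff(anchors, rownames(p))
  if (length(missA))
    msg <- c(msg, paste("missing anchor landmark(s):",
                        paste(missA, collapse = ", ")))
  lp <- object@lateralityPairs
  if (ncol(lp) != 2L) {
    msg <- c(msg, "lateralityPairs must have two columns")
  } else {
    unresolved <- setdiff(as.vector(lp), rownames(p))
    if (length(unresolved))
      msg <- c(msg, paste("laterality pair name(s) not present:",
                          paste(unresolved, collapse = ", ")))
    if (any(lp[, 1L] == lp[, 2L]))
      msg <- c(msg, "left and right members of a pair must be distinct")
  }
  inner <- object@innerSubset
  if (length(inner) != 33L)
    msg <- c(msg, sprintf("innerSubset must have 33 names, got %d",
                          length(inner)))
  missI <- setdiff(inner, rownames(p))
  if (length(missI))
    msg <- c(msg, paste("innerSubset name(s) not present:",
                        paste(missI, collapse = ", ")))
  outerish <- grepl("^(tragion|ear_|gonion|zygion|menton)", inner)
  if (any(outerish))
    msg <- c(msg, paste("innerSubset must exclude ear/contour landmarks:",
                        paste(inner[outerish], collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' MetricCatalog: declarative definitions of geometric facial measurements
#'
#' Each record names a measurement of kind \code{horizontal_distance},
#' \code{vertical_distance} or \code{angle} (vertex listed second), the
#' landmarks it is evaluated on, whether it is measured once on the facial
#' midline or once per side (\code{paired}), and which reference length
#' normalizes it (\code{horizontal_ref} = inter-tragion distance,
#' \code{vertical_ref} = commissure-midpoint-to-nasion distance,
#' \code{none} for angles, which are reported in degrees).
#'
#' @slot defs data.frame with columns \code{name}, \code{kind}, \code{lm1},
#'   \code{lm2}, \code{lm3} (NA for distances), \code{laterality},
#'   \code{normalization}.
#' @export
setClass("MetricCatalog", representation(defs = "data.frame"))

setValidity("MetricCatalog", function(object) {
  d <- object@defs
  msg <- character()
  need <- c("name", "kind", "lm1", "lm2", "lm3", "laterality", "normalization")
  missc <- setdiff(need, colnames(d))
  if (length(missc))
    return(paste("missing catalog column(s):", paste(missc, collapse = ", ")))
  if (anyDuplicated(d$name))
    msg <- c(msg, "metric names must be unique")
  badk <- !d$kind %in% c("horizontal_distance", "vertical_distance", "angle")
  if (any(badk))
    msg <- c(msg, paste("unknown kind:", paste(unique(d$kind[badk]),
                                               collapse = ", ")))
  badl <- !d$laterality %in% c("paired", "midline")
  if (any(badl))
    msg <- c(msg, paste("unknown laterality:",
                        paste(unique(d$laterality[badl]), collapse = ", ")))
  badn <- !d$normalization %in% c("horizontal_ref", "vertical_ref", "none")
  if (any(badn))
    msg <- c(msg, paste("unknown normalization:",
                        paste(unique(d$normalization[badn]), collapse = ", ")))
  ang <- d$kind == "angle"
  if (any(ang & d$normalization != "none"))
    msg <- c(msg, "angles must carry normalization = none")
  if (any(!ang & d$normalization == "none"))
    msg <- c(msg, "distances must carry a normalization reference")
  if (any(ang & is.na(d$lm3)))
    msg <- c(msg, "angles need three landmarks (vertex second)")
  if (any(!ang & !is.na(d$lm3)))
    msg <- c(msg, "distances take exactly two landmarks")
  if (length(msg)) msg else TRUE
})

#' TexturePatchConfig: multi-resolution block-LBP settings
#'
#' Local texture around each inner landmark is coded by comparing the mean
#' intensity of a central square patch against its eight neighboring patches
#' in a 3x3 tiling, at three nested resolutions R1 < R2 < R3.
#'
#' @slot blockSizes three increasing odd patch side lengths in pixels,
#'   stated for a face with a 200-px inter-tragion distance (default 3, 5, 9).
#' @slot comparisonRule \code{"ge"} (neighbor >= center, classical LBP tie
#'   rule, default) or \code{"gt"}.
#' @slot representation \code{"bits"} (8 comparison bits per landmark per
#'   resolution, default) or \code{"histogram"} (normalized 256-bin code
#'   histogram over a local window).
#' @slot scaleNormalize when TRUE (default) the block sizes are rescaled by
#'   the subject's inter-tragion distance / 200 so descriptors are comparable
#'   across image resolutions; rescaled sizes are rounded to the nearest odd
#'   integer >= 3.
#' @export
setClass("TexturePatchConfig",
  representation(
    blockSizes = "numeric",
    comparisonRule = "character",
    representation = "character",
    scaleNormalize = "logical"
  ),
  prototype(
    blockSizes = c(3, 5, 9),
    comparisonRule = "ge",
    representation = "bits",
    scaleNormalize = TRUE
  )
)

setValidity("TexturePatchConfig", function(object) {
  b <- object@blockSizes
  msg <- character()
  if (length(b) != 3L || !all(is.finite(b)))
    msg <- c(msg, "blockSizes must be three finite numbers")
  else {
    if (any(diff(b) <= 0))
      msg <- c(msg, "blockSizes must be strictly increasing")
    if (any(round(b) < 3))
      msg <- c(msg, "blockSizes must each be >= 3")
    if (any(round(b) %% 2 != 1))
      msg <- c(msg, "blockSizes must be odd after rounding")
  }
  if (!object@comparisonRule %in% c("ge", "gt"))
    msg <- c(msg, "comparisonRule must be 'ge' or 'gt'")
  if (!object@representation %in% c("bits", "histogram"))
    msg <- c(msg, "representation must be 'bits' or 'histogram'")
  if (length(msg)) msg else TRUE
})

#' FaceFeatureSet: subjects x features with cohort metadata
#'
#' A \linkS4class{SummarizedExperiment} whose single assay \code{"features"}
#' holds the feature matrix (rows = features named \code{geom.*} /
#' \code{lbp.*}, columns = subjects) and whose \code{colData} carries the
#' per-subject diagnosis (\code{NS} or \code{WBS}), ethnicity stratum,
#' age group, and sex.
#'
#' @export
setClass("FaceFeatureSet", contains = "SummarizedExperiment")

setValidity("FaceFeatureSet", function(object) {
  msg <- character()
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    return("assay 'features' required")
  m <- SummarizedExperiment::assay(object, "features")
  if (anyNA(m))
    msg <- c(msg, "feature matrix must not contain missing values")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    msg <- c(msg, "feature names must be present and unique")
  cd <- SummarizedExperiment::colData(object)
  need <- c("diagnosis", "ethnicity", "age_group", "sex")
  missc <- setdiff(need, colnames(cd))
  if (length(missc))
    msg <- c(msg, paste("missing colData column(s):",
                        paste(missc, collapse = ", ")))
  if ("diagnosis" %in% colnames(cd)) {
    bad <- !cd$diagnosis %in% c("NS", "WBS")
    if (any(bad))
      msg <- c(msg, "diagnosis values must be 'NS' or 'WBS'")
  }
  if ("ethnicity" %in% colnames(cd)) {
    bad <- !cd$ethnicity %in%
      c("African", "Asian", "Caucasian", "LatinAmerican")
    if (any(bad))
      msg <- c(msg, "unknown ethnicity stratum value(s)")
  }
  if (length(msg)) msg else TRUE
})

#' SelectionResult: SVM-RFE ranking and LOOCV evaluation curves
#'
#' @slot ranking all feature names ordered by elimination order
#'   (rank 1 = last eliminated, most discriminative).
#' @slot curves data.frame with one row per evaluated feature count
#'   \code{k}: \code{accuracy}, \code{accuracy_NS}, \code{accuracy_WBS},
#'   \code{auc}.
#' @slot kStar feature count chosen by AUC convergence.
#' @slot selectedFeatures top-\code{kStar} features of the full-data ranking.
#' @slot predictions per-subject LOOCV prediction at \code{kStar}
#'   (\code{subject}, \code{truth}, \code{predicted}, \code{score}).
#' @slot featureStats per-selected-feature Mann-Whitney screen
#'   (\code{feature}, \code{U}, \code{p}, \code{p_BH}).
#' @slot protocol \code{"nested"} or \code{"flat"}.
#' @slot seed integer seed recorded for the run.
#' @export
setClass("SelectionResult",
  representation(
    ranking = "character",
    curves = "data.frame",
    kStar = "integer",
    selectedFeatures = "character",
    predictions = "data.frame",
    featureStats = "data.frame",
    protocol = "character",
    seed = "integer"
  )
)

setValidity("SelectionResult", function(object) {
  msg <- character()
  if (length(object@kStar) == 1L &&
      length(object@selectedFeatures) != object@kStar)
    msg <- c(msg, "selectedFeatures must have length kStar")
  if (nrow(object@predictions) &&
      anyDuplicated(object@predictions$subject))
    msg <- c(msg, "per-sample predictions must cover each subject once")
  if (length(msg)) msg else TRUE
})

#' ModelComparison: Fisher-exact comparison of two classifiers
#'
#' @slot counts 2x2 integer matrix, rows = models A and B, columns =
#'   correct / incorrect on the same evaluated cohort.
#' @slot pValue two-sided Fisher exact p-value.
#' @slot accuracies accuracies of A and B in percent.
#' @slot relativeImprovement percent relative improvement of B over A.
#' @export
setClass("ModelComparison",
  representation(
    counts = "matrix",
    pValue = "numeric",
    accuracies = "numeric",
    relativeImprovement = "numeric"
  )
)

setValidity("ModelComparison", function(object) {
  msg <- character()
  if (!all(dim(object@counts) == c(2L, 2L)))
    msg <- c(msg, "counts must be a 2x2 matrix")
  else if (any(object@counts < 0))
    msg <- c(msg, "counts must be non-negative")
  if (length(object@pValue) == 1L &&
      (object@pValue <= 0 || object@pValue > 1))
    msg <- c(msg, "p-value must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' ConsensusShape: Procrustes mean landmark configuration
#'
#' @slot points 44 x 2 matrix of consensus landmark positions in the
#'   canonical frame (centroid at the origin, unit centroid size,
#'   inter-tragion axis horizontal).
#' @slot transforms per-input similarity transforms (list of lists with
#'   \code{rotation}, \code{scale}, \code{translation}).
#' @export
setClass("ConsensusShape",
  representation(points = "matrix", transforms = "list")
)

setValidity("ConsensusShape", function(object) {
  p <- object@points
  msg <- character()
  if (ncol(p) != 2L || is.null(rownames(p)))
    msg <- c(msg, "points must be an n x 2 matrix with rownames")
  ctr <- colMeans(p)
  if (max(abs(ctr)) > 1e-6)
    msg <- c(msg, "consensus centroid must be at the origin")
  cs <- sqrt(sum(sweep(p, 2, ctr)^2))
  if (abs(cs - 1) > 1e-6)
    msg <- c(msg, "consensus must have unit centroid size")
  if (length(msg)) msg else TRUE
})

#' SyntheticCohort: generated images, landmarks, metadata and ground truth
#'
#' @slot images named list of grayscale image matrices (rows = y).
#' @slot landmarks named list of \linkS4class{LandmarkSet} objects.
#' @slot metadata data.frame with subject_id, diagnosis, ethnicity,
#'   age_group, sex.
#' @slot groundTruth list: planted feature names, per-stratum standardized
#'   effect sizes, calibration details and the planted-model Bayes accuracy.
#' @slot config the generating \code{SyntheticCohortConfig} (as a list).
#' @export
setClass("SyntheticCohort",
  representation(
    images = "list",
    landmarks = "list",
    metadata = "data.frame",
    groundTruth = "list",
    config = "list"
  )
)

setValidity("SyntheticCohort", function(object) {
  msg <- character()
  n <- nrow(object@metadata)
  if (length(object@landmarks) != n)
    msg <- c(msg, "one LandmarkSet per metadata row required")
  if (length(object@images) && length(object@images) != n)
    msg <- c(msg, "images, when present, must cover every subject")
  if (n && anyDuplicated(object@metadata$subject_id))
    msg <- c(msg, "subject ids must be unique")
  if (length(msg)) msg else TRUE
})
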