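#' @include AllClasses.R
NULL

## Default 44-landmark naming scheme: 33 inner (14 periocular/eyebrow,
## 9 nasal, 10 perioral) + 11 outer (ears, jaw, face contour).
## "L"/"R" are anatomical left/right as seen in the image with the subject's
## left at smaller x; the face frame orients metrics, so the convention only
## has to be consistent within a cohort.

.periocular <- c(
  "eyebrow_inner_L", "eyebrow_inner_R", "eyebrow_mid_L", "eyebrow_mid_R",
  "eyebrow_outer_L", "eyebrow_outer_R", "canthus_inner_L", "canthus_inner_R",
  "canthus_outer_L", "canthus_outer_R", "eyelid_upper_L", "eyelid_upper_R",
  "eyelid_lower_L", "eyelid_lower_R"
)
.nasal <- c(
  "nasion", "nose_bridge", "nose_tip", "subnasale", "columella",
  "ala_outer_L", "ala_outer_R", "ala_base_L", "ala_base_R"
)
.perioral <- c(
  "oral_commissure_L", "oral_commissure_R", "cupid_bow_L", "cupid_bow_R",
  "cupid_bow_mid", "philtrum_L", "philtrum_R", "philtrum_mid",
  "stomion", "lower_lip_mid"
)
.outer <- c(
  "tragion_L", "tragion_R", "ear_superior_L", "ear_superior_R",
  "ear_inferior_L", "ear_inferior_R", "gonion_L", "gonion_R",
  "zygion_L", "zygion_R", "menton"
)

.pairedStems <- c(
  "eyebrow_inner", "eyebrow_mid", "eyebrow_outer", "canthus_inner",
  "canthus_outer", "eyelid_upper", "eyelid_lower", "ala_outer", "ala_base",
  "oral_commissure", "cupid_bow", "philtrum", "tragion", "ear_superior",
  "ear_inferior", "gonion", "zygion"
)

#' Default landmark naming scheme
#'
#' @return a list with \code{names} (all 44 landmark names), \code{inner}
#'   (the 33 inner names used for texture), \code{pairs} (two-column
#'   left/right matrix) and \code{midline} (unpaired names).
#' @export
#' @examples
#' s <- defaultLandmarkScheme()
#' length(s$names); length(s$inner); nrow(s$pairs)
defaultLandmarkScheme <- function() {
  nm <- c(.periocular, .nasal, .perioral, .outer)
  pairs <- cbind(left = paste0(.pairedStems, "_L"),
                 right = paste0(.pairedStems, "_R"))
  list(names = nm,
       inner = c(.periocular, .nasal, .perioral),
       pairs = pairs,
       midline = setdiff(nm, as.vector(pairs)))
}

#' Construct a LandmarkSet
#'
#' @param subjectID subject identifier.
#' @param points numeric matrix (44 x 2) of pixel coordinates with landmark
#'   names as rownames; origin top-left, x rightward, y downward, 0-based.
#' @param lateralityPairs optional two-column left/right pairing matrix
#'   (defaults to the default scheme's pairs).
#' @param innerSubset optional character vector of the 33 inner landmark
#'   names (defaults to the default scheme's inner subset).
#' @return a validated \linkS4class{LandmarkSet}.
#' @export
#' @examples
#' ls <- templateFace()$landmarks
#' ls
LandmarkSet <- function(subjectID, points, lateralityPairs = NULL,
                        innerSubset = NULL) {
  scheme <- defaultLandmarkScheme()
  if (is.null(lateralityPairs)) lateralityPairs <- scheme$pairs
  if (is.null(innerSubset)) innerSubset <- scheme$inner
  storage.mode(points) <- "double"
  colnames(points) <- c("x", "y")
  new("LandmarkSet", subjectID = as.character(subjectID), points = points,
      lateralityPairs = lateralityPairs, innerSubset = innerSubset)
}

#' Read landmarks from a CSV or JSON file
#'
#' CSV files must have the header \code{landmark,x,y}; JSON files are a map
#' from landmark name to a two-element \code{[x, y]} array. The subject id is
#' taken from the file name (without extension) unless given.
#'
#' @param path file path (.csv or .json).
#' @param subjectID optional explicit subject id.
#' @inheritParams LandmarkSet
#' @return a \linkS4class{LandmarkSet}.
#' @export
readLandmarks <- function(path, subjectID = NULL, lateralityPairs = NULL,
                          innerSubset = NULL) {
  if (is.null(subjectID))
    subjectID <- sub("\\.[^.]+$", "", basename(path))
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "json") {
    m <- jsonlite::fromJSON(path)
    pts <- do.call(rbind, m)
    rownames(pts) <- names(m)
  } else if (ext == "csv") {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("landmark", "x", "y")
    if (!all(need %in% colnames(d)))
      stop("landmark CSV must have columns landmark,x,y: ", path)
    pts <- as.matrix(d[, c("x", "y")])
    rownames(pts) <- d$landmark
  } else {
    stop("unsupported landmark file extension: ", ext)
  }
  LandmarkSet(subjectID, pts, lateralityPairs, innerSubset)
}

#' Write landmarks to a CSV file
#'
#' Writes the \code{landmark,x,y} format read back by
#' \code{\link{readLandmarks}}.
#'
#' @param ls a \linkS4class{LandmarkSet}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeLandmarks <- function(ls, path) {
  p <- landmarkPoints(ls)
  d <- data.frame(landmark = rownames(p),
                  x = .fmtNum(p[, 1]), y = .fmtNum(p[, 2]))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## 9-significant-digit decimal formatting used by every CSV writer
.fmtNum <- function(x) {
  out <- formatC(x, digits = 9, format = "g")
  trimws(out)
}

.getPoint <- function(ls, name) {
  p <- ls@points
  i <- match(name, rownames(p))
  if (is.na(i))
    stop("landmark '", name, "' not present in subject '",
         ls@subjectID, "'")
  p[i, ]
}

## Map a landmark name to its opposite side through the pairing table;
## midline names map to themselves.
.mirrorName <- function(ls, name) {
  lp <- ls@lateralityPairs
  i <- match(name, lp[, 1L])
  if (!is.na(i)) return(lp[i, 2L])
  i <- match(name, lp[, 2L])
  if (!is.na(i)) return(lp[i, 1L])
  name
}
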