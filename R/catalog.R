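#' @include AllClasses.R landmarks.R
NULL

#' Construct a MetricCatalog
#'
#' @param defs data.frame with columns \code{name}, \code{kind} (one of
#'   \code{horizontal_distance}, \code{vertical_distance}, \code{angle}),
#'   \code{lm1}, \code{lm2}, \code{lm3} (NA except for angles; vertex is
#'   \code{lm2}), \code{laterality} (\code{paired}/\code{midline}) and
#'   \code{normalization} (\code{horizontal_ref}/\code{vertical_ref}/
#'   \code{none}).
#' @return a validated \linkS4class{MetricCatalog}.
#' @export
MetricCatalog <- function(defs) {
  defs$lm3[!nzchar(as.character(defs$lm3)) | is.na(defs$lm3)] <- NA_character_
  defs <- as.data.frame(lapply(defs, as.character), stringsAsFactors = FALSE)
  new("MetricCatalog", defs = defs)
}

#' The default catalog of 23 facial metrics
#'
#' A reconstruction of the classical frontal-face anthropometric measurement
#' set: canthal distances, palpebral fissure length/height/slant, orbital rim
#' (brow-to-eyelid) height, nasal bridge offset, nose length and width, ala
#' length, philtrum length, cupid's bow width and depth, mouth width, lip
#' thicknesses, ear-canthus angle, eyebrow and face-frame distances. Paired
#' metrics are measured once per side and additionally yield a normalized
#' left/right asymmetry feature. Horizontal distances are normalized by the
#' inter-tragion (ear-to-ear) distance, vertical distances by the distance
#' from the oral-commissure midpoint to the nasion; angles are in degrees and
#' unnormalized.
#'
#' @return a \linkS4class{MetricCatalog} with 23 metrics.
#' @export
#' @examples
#' metricDefs(defaultMetricCatalog())
defaultMetricCatalog <- function() {
  M <- function(name, kind, lm1, lm2, lm3, lat, norm)
    data.frame(name = name, kind = kind, lm1 = lm1, lm2 = lm2, lm3 = lm3,
               laterality = lat, normalization = norm,
               stringsAsFactors = FALSE)
  H <- "horizontal_distance"; V <- "vertical_distance"; A <- "angle"
  defs <- rbind(
    M("intercanthal_outer", H, "canthus_outer_L", "canthus_outer_R", NA,
      "midline", "horizontal_ref"),
    M("intercanthal_inner", H, "canthus_inner_L", "canthus_inner_R", NA,
      "midline", "horizontal_ref"),
    M("fissure_length", H, "canthus_inner_L", "canthus_outer_L", NA,
      "paired", "horizontal_ref"),
    M("fissure_height", V, "eyelid_upper_L", "eyelid_lower_L", NA,
      "paired", "vertical_ref"),
    M("fissure_slant", A, "canthus_outer_L", "canthus_inner_L",
      "tragion_L", "paired", "none"),
    M("orbital_rim_height", V, "eyebrow_mid_L", "eyelid_upper_L", NA,
      "paired", "vertical_ref"),
    M("nasal_bridge_offset", H, "nasion", "nose_bridge", NA,
      "midline", "horizontal_ref"),
    M("nose_length", V, "nasion", "nose_tip", NA, "midline", "vertical_ref"),
    M("nose_width", H, "ala_outer_L", "ala_outer_R", NA,
      "midline", "horizontal_ref"),
    M("ala_length", H, "ala_base_L", "ala_outer_L", NA,
      "paired", "horizontal_ref"),
    M("philtrum_length", V, "subnasale", "cupid_bow_mid", NA,
      "midline", "vertical_ref"),
    M("cupids_bow_width", H, "cupid_bow_L", "cupid_bow_R", NA,
      "midline", "horizontal_ref"),
    M("cupids_bow_depth", V, "cupid_bow_L", "cupid_bow_mid", NA,
      "paired", "vertical_ref"),
    M("mouth_width", H, "oral_commissure_L", "oral_commissure_R", NA,
      "midline", "horizontal_ref"),
    M("upper_lip_thickness", V, "cupid_bow_mid", "stomion", NA,
      "midline", "vertical_ref"),
    M("lower_lip_thickness", V, "stomion", "lower_lip_mid", NA,
      "midline", "vertical_ref"),
    M("ear_canthus_angle", A, "canthus_outer_L", "tragion_L",
      "gonion_L", "paired", "none"),
    M("eyebrow_length", H, "eyebrow_inner_L", "eyebrow_outer_L", NA,
      "paired", "horizontal_ref"),
    M("interbrow_distance", H, "eyebrow_inner_L", "eyebrow_inner_R", NA,
      "midline", "horizontal_ref"),
    M("midface_width", H, "zygion_L", "zygion_R", NA,
      "midline", "horizontal_ref"),
    M("jaw_width", H, "gonion_L", "gonion_R", NA,
      "midline", "horizontal_ref"),
    M("lower_face_height", V, "subnasale", "menton", NA,
      "midline", "vertical_ref"),
    M("ear_length", V, "ear_superior_L", "ear_inferior_L", NA,
      "paired", "vertical_ref")
  )
  MetricCatalog(defs)
}

#' Read / write a metric catalog file
#'
#' The catalog file is a plain CSV with one record per metric holding the
#' \linkS4class{MetricCatalog} fields; \code{writeMetricCatalog} followed by
#' \code{readMetricCatalog} round-trips the catalog exactly.
#'
#' @param path catalog file path.
#' @return \code{readMetricCatalog}: a \linkS4class{MetricCatalog}.
#' @export
readMetricCatalog <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  need <- c("name", "kind", "lm1", "lm2", "lm3", "laterality",
            "normalization")
  missc <- setdiff(need, colnames(d))
  if (length(missc))
    stop("catalog file missing column(s): ", paste(missc, collapse = ", "))
  MetricCatalog(d[, need])
}

#' @rdname readMetricCatalog
#' @param catalog a \linkS4class{MetricCatalog} to write.
#' @export
writeMetricCatalog <- function(catalog, path) {
  d <- metricDefs(catalog)
  d$lm3[is.na(d$lm3)] <- ""
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
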