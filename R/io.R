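#' @include AllClasses.R landmarks.R catalog.R geometry.R texture.R selection.R synthetic.R atlas.R
NULL

## ---- images (ASCII PGM) ---------------------------------------------------

#' Read / write ASCII PGM (P2) grayscale images
#'
#' Plain-text portable graymap is the image format used throughout the
#' package (no binary image codecs are required). \code{writePgm} rounds
#' intensities to integers in [0, maxval].
#'
#' @param path file path.
#' @return \code{readPgm}: a numeric matrix (rows = y, columns = x).
#' @export
readPgm <- function(path) {
  txt <- readLines(path)
  txt <- txt[!grepl("^#", txt)]
  tok <- scan(text = paste(txt, collapse = " "), what = character(),
              quiet = TRUE)
  if (tok[1] != "P2")
    stop("only ASCII PGM (P2) images are supported: ", path)
  w <- as.integer(tok[2]); h <- as.integer(tok[3])
  vals <- as.numeric(tok[-(1:4)])
  if (length(vals) != w * h)
    stop("corrupt PGM: expected ", w * h, " pixels, got ", length(vals))
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' @rdname readPgm
#' @param image numeric matrix of intensities.
#' @param maxval maximum gray value written to the header (default 255).
#' @export
writePgm <- function(image, path, maxval = 255) {
  v <- round(pmin(pmax(image, 0), maxval))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(image), nrow(image)), as.character(maxval)),
             con)
  writeLines(apply(v, 1, paste, collapse = " "), con)
  invisible(path)
}

## ---- metadata -------------------------------------------------------------

#' Read and validate a cohort metadata table
#'
#' The CSV must have columns \code{subject_id}, \code{diagnosis} (NS/WBS),
#' \code{ethnicity} (African/Asian/Caucasian/LatinAmerican),
#' \code{age_group} and \code{sex}. Unknown diagnosis or ethnicity tokens
#' and duplicate subject ids are rejected with the offending rows named.
#'
#' @param path metadata CSV path.
#' @return validated data.frame.
#' @export
readMetadata <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  need <- c("subject_id", "diagnosis", "ethnicity", "age_group", "sex")
  missc <- setdiff(need, colnames(d))
  if (length(missc))
    stop("metadata missing column(s): ", paste(missc, collapse = ", "))
  dup <- d$subject_id[duplicated(d$subject_id)]
  if (length(dup))
    stop("duplicate subject id(s): ", paste(unique(dup), collapse = ", "))
  badD <- which(!d$diagnosis %in% c("NS", "WBS"))
  if (length(badD))
    stop("unknown diagnosis token(s) at row(s) ",
         paste(badD, collapse = ", "), ": ",
         paste(unique(d$diagnosis[badD]), collapse = ", "))
  badE <- which(!d$ethnicity %in%
                  c("African", "Asian", "Caucasian", "LatinAmerican"))
  if (length(badE))
    stop("unknown ethnicity token(s) at row(s) ",
         paste(badE, collapse = ", "), ": ",
         paste(unique(d$ethnicity[badE]), collapse = ", "))
  d
}

## ---- feature extraction ---------------------------------------------------

#' Build a FaceFeatureSet from a feature matrix and metadata
#'
#' @param features numeric matrix, subjects x features.
#' @param metadata data.frame with subject_id, diagnosis, ethnicity,
#'   age_group, sex (one row per subject, aligned with \code{features}).
#' @return a \linkS4class{FaceFeatureSet}.
#' @export
FaceFeatureSet <- function(features, metadata) {
  stopifnot(nrow(features) == nrow(metadata))
  cd <- S4Vectors::DataFrame(metadata[, c("diagnosis", "ethnicity",
                                          "age_group", "sex")],
                             row.names = metadata$subject_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = t(features)), colData = cd)
  new("FaceFeatureSet", se)
}

#' Extract the per-subject feature table of a cohort
#'
#' Runs the geometry and texture modules over every subject: the normalized
#' geometric features (\code{geom.*}) from the metric catalog followed by
#' the multi-resolution block-LBP features (\code{lbp.*}), joined to the
#' cohort metadata. Input is either an in-memory
#' \linkS4class{SyntheticCohort} or a dataset directory laid out by
#' \code{\link{writeCohort}} (images/, landmarks/, metadata.csv).
#'
#' @param cohort a \linkS4class{SyntheticCohort} or a dataset directory
#'   path.
#' @param catalog a \linkS4class{MetricCatalog}.
#' @param texture a \linkS4class{TexturePatchConfig}, or NULL to skip
#'   texture features (geometry only).
#' @return a \linkS4class{FaceFeatureSet}.
#' @export
extractFeatures <- function(cohort, catalog = defaultMetricCatalog(),
                            texture = TexturePatchConfig()) {
  if (is(cohort, "SyntheticCohort")) {
    meta <- cohort@metadata
    getLs <- function(id) cohort@landmarks[[id]]
    getImg <- function(id) cohort@images[[id]]
    hasImages <- length(cohort@images) > 0
  } else {
    meta <- readMetadata(file.path(cohort, "metadata.csv"))
    getLs <- function(id) {
      f <- file.path(cohort, "landmarks", paste0(id, ".csv"))
      if (!file.exists(f)) stop("missing landmark file for subject ", id)
      readLandmarks(f, subjectID = id)
    }
    getImg <- function(id) {
      f <- file.path(cohort, "images", paste0(id, ".pgm"))
      if (!file.exists(f)) stop("missing image file for subject ", id)
      readPgm(f)
    }
    hasImages <- dir.exists(file.path(cohort, "images"))
  }
  useTexture <- !is.null(texture) && hasImages
  rows <- lapply(meta$subject_id, function(id) {
    ls <- getLs(id)
    g <- extractGeometricFeatures(ls, catalog)
    if (useTexture) c(g, landmarkDescriptor(getImg(id), ls, texture)) else g
  })
  X <- do.call(rbind, rows)
  rownames(X) <- meta$subject_id
  FaceFeatureSet(X, meta)
}

#' Write / read the feature table CSV
#'
#' One row per subject: \code{subject_id}, the four metadata columns, then
#' every feature (9 significant digits). Reading reproduces the
#' \linkS4class{FaceFeatureSet}.
#'
#' @param fset a \linkS4class{FaceFeatureSet}.
#' @param path CSV path.
#' @export
writeFeatureTable <- function(fset, path) {
  X <- t(SummarizedExperiment::assay(fset, "features"))
  cd <- as.data.frame(SummarizedExperiment::colData(fset))
  d <- data.frame(subject_id = rownames(X), cd,
                  row.names = NULL, check.names = FALSE)
  for (j in colnames(X)) d[[j]] <- .fmtNum(X[, j])
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  metaCols <- c("subject_id", "diagnosis", "ethnicity", "age_group", "sex")
  featCols <- setdiff(colnames(d), metaCols)
  X <- as.matrix(d[, featCols, drop = FALSE])
  rownames(X) <- d$subject_id
  FaceFeatureSet(X, d[, metaCols])
}

## ---- pipeline -------------------------------------------------------------

## Polynomial fingerprint of the serialized config (mod 2^31 - 1)
.configHash <- function(x) {
  s <- as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = 10,
                                     force = TRUE))
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' End-to-end pipeline run
#'
#' Extracts features (or uses a prebuilt feature table), runs the
#' stratified selection + LOOCV evaluation, and optionally builds the
#' per-(diagnosis x ethnicity) population-average images. Writes a JSON
#' report (with the config hash and seed embedded), a Table-4-shaped
#' accuracy CSV, a per-k performance-curve CSV, and the atlases as PGM.
#'
#' @param cohort a \linkS4class{SyntheticCohort} or dataset directory.
#' @param outDir output directory.
#' @param catalog metric catalog.
#' @param texture texture configuration (NULL = geometry only).
#' @param protocol,C,epsilon,kGrid selection settings (see
#'   \code{\link{selectFeatures}}).
#' @param atlases also write population mean images (default FALSE; needs
#'   images).
#' @param seed integer seed recorded in every artifact.
#' @param quiet suppress progress messages.
#' @return the report list, invisibly.
#' @export
runPipeline <- function(cohort, outDir, catalog = defaultMetricCatalog(),
                        texture = TexturePatchConfig(),
                        protocol = "nested", C = 1, epsilon = 0.005,
                        kGrid = NULL, atlases = FALSE, seed = 1L,
                        quiet = FALSE) {
  t0 <- Sys.time()
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  cfgList <- list(protocol = protocol, C = C, epsilon = epsilon,
                  kGrid = kGrid, seed = seed)
  hash <- .configHash(cfgList)
  say("[extract] computing feature table")
  fset <- extractFeatures(cohort, catalog, texture)
  writeFeatureTable(fset, file.path(outDir, "features.csv"))
  say("[evaluate] stratified selection + LOOCV (protocol %s)", protocol)
  rep <- stratifiedEvaluation(fset, kGrid = kGrid, protocol = protocol,
                              C = C, epsilon = epsilon, seed = seed)
  rep$config_hash <- hash
  rep$timing_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  acc <- do.call(rbind, lapply(names(rep$strata), function(s) {
    st <- rep$strata[[s]]
    data.frame(ethnicity = s, n = st$n,
               global_model = st$global_accuracy,
               specific_model = st$specific_accuracy,
               improvement = st$improvement, p_value = st$fisher_p)
  }))
  if (!is.null(rep$overall))
    acc <- rbind(acc, data.frame(
      ethnicity = "Global", n = rep$overall$n,
      global_model = rep$overall$global_accuracy,
      specific_model = rep$overall$specific_accuracy,
      improvement = rep$overall$improvement,
      p_value = rep$overall$fisher_p))
  utils::write.csv(acc, file.path(outDir, "accuracy_table.csv"),
                   row.names = FALSE)
  utils::write.csv(rep$global$curves, file.path(outDir, "loocv_curves.csv"),
                   row.names = FALSE)
  jsonlite::write_json(rep, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (atlases && is(cohort, "SyntheticCohort") && length(cohort@images)) {
    say("[atlas] population mean images")
    md <- cohort@metadata
    for (cl in unique(md$diagnosis)) for (s in unique(md$ethnicity)) {
      ids <- md$subject_id[md$diagnosis == cl & md$ethnicity == s]
      if (!length(ids)) next
      atl <- populationMeanImage(cohort@images[ids],
                                 cohort@landmarks[ids])
      writePgm(atl$image, file.path(outDir,
                                    sprintf("atlas_%s_%s.pgm", cl, s)))
    }
  }
  say("[done] %.1f s (config %s, seed %d)", rep$timing_s, hash, seed)
  invisible(rep)
}
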