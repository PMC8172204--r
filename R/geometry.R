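#' @include AllClasses.R landmarks.R catalog.R
NULL

#' Intrinsic face frame of a landmark set
#'
#' All "horizontal" and "vertical" measurements are evaluated in the face's
#' own frame rather than along image axes, which removes head-roll
#' sensitivity: the origin is the midpoint between the two tragions, the
#' x-axis is the unit vector from the left to the right tragion, and the
#' y-axis is the x-axis rotated 90 degrees toward the chin (using the oral
#' commissure midpoint to resolve the chin side).
#'
#' @param ls a \linkS4class{LandmarkSet}.
#' @return a list with \code{origin}, \code{xaxis}, \code{yaxis} (unit
#'   vectors in image coordinates).
#' @export
#' @examples
#' faceFrame(templateFace()$landmarks)
faceFrame <- function(ls) {
  tl <- .getPoint(ls, "tragion_L")
  tr <- .getPoint(ls, "tragion_R")
  v <- tr - tl
  len <- sqrt(sum(v^2))
  if (len < 1e-9)
    stop("degenerate geometry: tragions are coincident")
  xaxis <- v / len
  origin <- (tl + tr) / 2
  chin <- (.getPoint(ls, "oral_commissure_L") +
           .getPoint(ls, "oral_commissure_R")) / 2 - origin
  perp <- unname(c(-xaxis[2], xaxis[1]))
  if (sum(perp * chin) < 0) perp <- -perp
  list(origin = origin, xaxis = xaxis, yaxis = perp)
}

#' Normalization reference lengths
#'
#' \code{horizontal_ref} is the ear-to-ear (inter-tragion) Euclidean
#' distance; \code{vertical_ref} is the Euclidean distance from the midpoint
#' between the oral commissures to the nasion (nose root).
#'
#' @param ls a \linkS4class{LandmarkSet}.
#' @return named numeric vector \code{c(horizontal_ref=, vertical_ref=)}.
#' @export
referenceLengths <- function(ls) {
  tl <- .getPoint(ls, "tragion_L")
  tr <- .getPoint(ls, "tragion_R")
  h <- sqrt(sum((tr - tl)^2))
  cm <- (.getPoint(ls, "oral_commissure_L") +
         .getPoint(ls, "oral_commissure_R")) / 2
  v <- sqrt(sum((cm - .getPoint(ls, "nasion"))^2))
  if (h < 1e-9 || v < 1e-9)
    stop("degenerate geometry: zero-length normalization reference")
  c(horizontal_ref = h, vertical_ref = v)
}

.frameCoords <- function(frame, p) {
  d <- p - frame$origin
  c(u = sum(d * frame$xaxis), v = sum(d * frame$yaxis))
}

.angleAt <- function(a, vertex, b) {
  u <- a - vertex
  w <- b - vertex
  nu <- sqrt(sum(u^2)); nw <- sqrt(sum(w^2))
  if (nu < 1e-12 || nw < 1e-12)
    stop("degenerate geometry: zero-length angle arm")
  cosv <- sum(u * w) / (nu * nw)
  acos(min(1, max(-1, cosv))) * 180 / pi
}

.evalOneSide <- function(ls, frame, kind, nms) {
  if (kind == "angle")
    return(.angleAt(.getPoint(ls, nms[1]), .getPoint(ls, nms[2]),
                    .getPoint(ls, nms[3])))
  a <- .frameCoords(frame, .getPoint(ls, nms[1]))
  b <- .frameCoords(frame, .getPoint(ls, nms[2]))
  if (kind == "horizontal_distance") abs(a["u"] - b["u"]) else
    abs(a["v"] - b["v"])
}

#' Evaluate one metric definition on a landmark set
#'
#' Horizontal/vertical distances are absolute coordinate differences along
#' the intrinsic face frame axes; angles are interior angles (degrees) at the
#' vertex landmark. Paired metrics are evaluated on both sides (right-side
#' landmark names resolved through the pairing table) and return
#' \code{c(left=, right=)}; midline metrics return one value.
#'
#' @param ls a \linkS4class{LandmarkSet}.
#' @param def one row of a catalog definitions data.frame (or a list with
#'   the same fields).
#' @param frame optional precomputed \code{\link{faceFrame}}.
#' @return named numeric vector of raw (unnormalized) values.
#' @export
evaluateMetric <- function(ls, def, frame = faceFrame(ls)) {
  nms <- c(def$lm1, def$lm2, if (!is.na(def$lm3)) def$lm3)
  val <- .evalOneSide(ls, frame, def$kind, nms)
  if (def$laterality == "paired") {
    rnms <- vapply(nms, function(n) .mirrorName(ls, n), character(1))
    valR <- .evalOneSide(ls, frame, def$kind, rnms)
    c(left = unname(val), right = unname(valR))
  } else {
    c(value = unname(val))
  }
}

#' Extract the normalized geometric feature vector
#'
#' For a paired metric with per-side raw values (L, R), the symmetric
#' feature \code{geom.<metric>.sym} is mean(L, R) divided by its
#' normalization reference (angles undivided) and the asymmetry feature
#' \code{geom.<metric>.asym} is |L - R| / mean(L, R). Midline metrics yield
#' only the \code{.sym} feature. Output order follows the catalog order.
#' The resulting features are invariant to translation, rotation and uniform
#' scaling of the landmark set.
#'
#' @param ls a \linkS4class{LandmarkSet}.
#' @param catalog a \linkS4class{MetricCatalog}
#'   (default \code{\link{defaultMetricCatalog}()}).
#' @return named numeric vector of \code{geom.*} features.
#' @export
#' @examples
#' extractGeometricFeatures(templateFace()$landmarks)[1:5]
extractGeometricFeatures <- function(ls, catalog = defaultMetricCatalog()) {
  defs <- metricDefs(catalog)
  frame <- faceFrame(ls)
  refs <- referenceLengths(ls)
  out <- numeric(0)
  for (i in seq_len(nrow(defs))) {
    def <- defs[i, ]
    raw <- evaluateMetric(ls, def, frame)
    ref <- switch(def$normalization,
                  horizontal_ref = refs[["horizontal_ref"]],
                  vertical_ref = refs[["vertical_ref"]],
                  none = 1)
    if (def$laterality == "paired") {
      m <- mean(raw)
      if (def$kind != "angle" && m < 1e-6 * refs[["horizontal_ref"]])
        stop("degenerate geometry: near-zero paired mean for metric '",
             def$name, "'")
      sym <- m / ref
      asym <- abs(raw[["left"]] - raw[["right"]]) / m
      out[paste0("geom.", def$name, ".sym")] <- sym
      out[paste0("geom.", def$name, ".asym")] <- asym
    } else {
      out[paste0("geom.", def$name, ".sym")] <- raw[["value"]] / ref
    }
  }
  out
}
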