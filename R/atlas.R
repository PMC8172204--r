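#' @include AllClasses.R landmarks.R geometry.R
NULL

## ---- generalized Procrustes alignment -------------------------------------

.centerScale <- function(P) {
  ctr <- colMeans(P)
  Pc <- sweep(P, 2, ctr)
  cs <- sqrt(sum(Pc^2))
  list(P = Pc / cs, centroid = ctr, size = cs)
}

## Optimal rotation (no reflection) + scale aligning unit-size X onto ref
.alignOnto <- function(X, ref) {
  M <- crossprod(X, ref)
  sv <- svd(M)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, d))
  R <- sv$u %*% D %*% t(sv$v)
  s <- sum(diag(D) * sv$d) / sum(X^2)
  list(R = R, s = s, aligned = s * X %*% R)
}

#' Procrustes mean shape of a set of landmark configurations
#'
#' Generalized Procrustes analysis under similarity transforms (translation,
#' rotation, uniform scale; no reflection): configurations are centered and
#' scaled to unit centroid size, then iteratively rotated onto the running
#' consensus until the consensus changes by less than \code{tol} (default
#' 1e-8) or 100 iterations. The result is canonicalized to centroid at the
#' origin, unit centroid size, and a horizontal left-to-right inter-tragion
#' axis, and is independent of the input order.
#'
#' @param shapes list of \linkS4class{LandmarkSet} objects or coordinate
#'   matrices with identical rownames.
#' @param tol convergence tolerance on the consensus update.
#' @return a \linkS4class{ConsensusShape}.
#' @export
meanShape <- function(shapes, tol = 1e-8) {
  if (length(shapes) < 2)
    stop("at least 2 landmark sets required")
  mats <- lapply(shapes, function(s)
    if (is(s, "LandmarkSet")) landmarkPoints(s) else s)
  nms <- rownames(mats[[1]])
  for (m in mats)
    if (!identical(rownames(m), nms))
      stop("landmark names (and order) must match across inputs")
  norm0 <- lapply(mats, .centerScale)
  cur <- lapply(norm0, `[[`, "P")
  ref <- .centerScale(Reduce(`+`, cur) / length(cur))$P
  for (iter in seq_len(100)) {
    cur <- lapply(cur, function(P) .alignOnto(P, ref)$aligned)
    newRef <- .centerScale(Reduce(`+`, cur) / length(cur))$P
    delta <- sqrt(sum((newRef - ref)^2))
    ref <- newRef
    if (delta < tol) break
  }
  ## canonical orientation: inter-tragion axis horizontal, left at smaller x,
  ## chin (commissure midpoint) toward +y
  iL <- match("tragion_L", nms); iR <- match("tragion_R", nms)
  if (!is.na(iL) && !is.na(iR)) {
    v <- ref[iR, ] - ref[iL, ]
    ang <- atan2(v[2], v[1])
    R <- matrix(c(cos(-ang), sin(-ang), -sin(-ang), cos(-ang)), 2, 2)
    ref <- ref %*% R
    icl <- match("oral_commissure_L", nms)
    icr <- match("oral_commissure_R", nms)
    inas <- match("nasion", nms)
    if (!is.na(icl) && !is.na(icr) && !is.na(inas) &&
        (ref[icl, 2] + ref[icr, 2]) / 2 < ref[inas, 2])
      ref[, 2] <- -ref[, 2]
    ref <- .centerScale(ref)$P
  }
  transforms <- lapply(seq_along(mats), function(i) {
    al <- .alignOnto(norm0[[i]]$P, ref)
    list(rotation = al$R, scale = al$s / norm0[[i]]$size,
         translation = norm0[[i]]$centroid)
  })
  names(transforms) <- names(shapes)
  new("ConsensusShape", points = ref, transforms = transforms)
}

## ---- Delaunay triangulation (Bowyer-Watson) -------------------------------

.circumcircle <- function(a, b, c) {
  D <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) +
            c[1] * (a[2] - b[2]))
  if (abs(D) < 1e-12) return(NULL)
  a2 <- sum(a^2); b2 <- sum(b^2); c2 <- sum(c^2)
  ux <- (a2 * (b[2] - c[2]) + b2 * (c[2] - a[2]) + c2 * (a[2] - b[2])) / D
  uy <- (a2 * (c[1] - b[1]) + b2 * (a[1] - c[1]) + c2 * (b[1] - a[1])) / D
  c(ux, uy, (a[1] - ux)^2 + (a[2] - uy)^2)
}

#' Delaunay triangulation of a 2-D point set
#'
#' Bowyer-Watson incremental triangulation; adequate for landmark-sized
#' point sets (tens of points).
#'
#' @param pts n x 2 coordinate matrix.
#' @return integer matrix (m x 3) of point indices per triangle.
#' @export
delaunayTriangulation <- function(pts) {
  n <- nrow(pts)
  if (n < 3) stop("at least 3 points required")
  mn <- apply(pts, 2, min); mx <- apply(pts, 2, max)
  d <- max(mx - mn, 1e-9); mid <- (mn + mx) / 2
  P <- rbind(pts,
             mid + c(-30 * d, -2 * d),
             mid + c(30 * d, -2 * d),
             mid + c(0, 30 * d))
  tris <- list(c(n + 1L, n + 2L, n + 3L))
  ccs <- list(.circumcircle(P[n + 1, ], P[n + 2, ], P[n + 3, ]))
  for (i in seq_len(n)) {
    p <- P[i, ]
    bad <- vapply(ccs, function(cc)
      !is.null(cc) && (p[1] - cc[1])^2 + (p[2] - cc[2])^2 <= cc[3] * (1 + 1e-12),
      logical(1))
    edges <- do.call(rbind, lapply(tris[bad], function(t)
      rbind(sort(t[c(1, 2)]), sort(t[c(2, 3)]), sort(t[c(1, 3)]))))
    if (is.null(edges)) next
    key <- paste(edges[, 1], edges[, 2])
    boundary <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
    tris <- tris[!bad]; ccs <- ccs[!bad]
    for (e in seq_len(nrow(boundary))) {
      tri <- c(boundary[e, ], i)
      cc <- .circumcircle(P[tri[1], ], P[tri[2], ], P[tri[3], ])
      if (is.null(cc)) next
      tris <- c(tris, list(tri)); ccs <- c(ccs, list(cc))
    }
  }
  keep <- vapply(tris, function(t) all(t <= n), logical(1))
  out <- do.call(rbind, tris[keep])
  if (is.null(out) || nrow(out) == 0)
    stop("degenerate (collinear) point set: triangulation failed")
  out
}

## ---- piecewise-affine warping ---------------------------------------------

## Consensus points in canvas pixel coordinates: inter-tragion distance
## scaled to `interTragion` px, centroid at the canvas center.
.shapeToCanvas <- function(shape, canvas = c(256, 256), interTragion = 160) {
  p <- consensusPoints(shape)
  it <- sqrt(sum((p["tragion_R", ] - p["tragion_L", ])^2))
  s <- interTragion / it
  sweep(p * s, 2, c(canvas[1] / 2, canvas[2] / 2), "+")
}

.borderAnchors <- function(w, h) {
  cbind(x = c(0, w / 2, w - 1, 0, w - 1, 0, w / 2, w - 1),
        y = c(0, 0, 0, h / 2, h / 2, h - 1, h - 1, h - 1))
}

.bilinear <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  x <- pmin(pmax(x, 0), w - 1); y <- pmin(pmax(y, 0), h - 1)
  x0 <- floor(x); y0 <- floor(y)
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  fx <- x - x0; fy <- y - y0
  i00 <- img[cbind(y0 + 1, x0 + 1)]; i10 <- img[cbind(y0 + 1, x1 + 1)]
  i01 <- img[cbind(y1 + 1, x0 + 1)]; i11 <- img[cbind(y1 + 1, x1 + 1)]
  (1 - fy) * ((1 - fx) * i00 + fx * i10) + fy * ((1 - fx) * i01 + fx * i11)
}

#' Warp an image onto a consensus shape
#'
#' Piecewise-affine warp over a Delaunay triangulation of the landmarks plus
#' eight fixed canvas-border anchors, with bilinear sampling; output pixels
#' outside every triangle are set to \code{background}.
#'
#' @param image grayscale matrix (or RGB array) to warp.
#' @param src \linkS4class{LandmarkSet} of the image.
#' @param dst \linkS4class{ConsensusShape} target.
#' @param canvas output width/height in pixels (default 256 x 256; the
#'   consensus is rendered with a 160-px inter-tragion distance).
#' @param interTragion target inter-tragion distance in canvas pixels.
#' @param background fill value outside the triangulated region.
#' @return warped grayscale matrix (canvas[2] rows x canvas[1] columns).
#' @export
warpToShape <- function(image, src, dst, canvas = c(256, 256),
                        interTragion = 160, background = 0) {
  img <- toGrayscale(image)
  dstPts <- .shapeToCanvas(dst, canvas, interTragion)
  srcPts <- landmarkPoints(src)[rownames(dstPts), , drop = FALSE]
  dstAll <- rbind(dstPts, .borderAnchors(canvas[1], canvas[2]))
  srcAll <- rbind(srcPts, .borderAnchors(ncol(img), nrow(img)))
  tri <- delaunayTriangulation(dstAll)
  out <- matrix(background, canvas[2], canvas[1])
  for (t in seq_len(nrow(tri))) {
    d1 <- dstAll[tri[t, 1], ]; d2 <- dstAll[tri[t, 2], ]
    d3 <- dstAll[tri[t, 3], ]
    s1 <- srcAll[tri[t, 1], ]; s2 <- srcAll[tri[t, 2], ]
    s3 <- srcAll[tri[t, 3], ]
    xr <- max(0, floor(min(d1[1], d2[1], d3[1]))):
          min(canvas[1] - 1, ceiling(max(d1[1], d2[1], d3[1])))
    yr <- max(0, floor(min(d1[2], d2[2], d3[2]))):
          min(canvas[2] - 1, ceiling(max(d1[2], d2[2], d3[2])))
    if (!length(xr) || !length(yr)) next
    px <- rep(xr, times = length(yr))
    py <- rep(yr, each = length(xr))
    det <- (d2[2] - d3[2]) * (d1[1] - d3[1]) +
           (d3[1] - d2[1]) * (d1[2] - d3[2])
    if (abs(det) < 1e-12) next
    l1 <- ((d2[2] - d3[2]) * (px - d3[1]) +
           (d3[1] - d2[1]) * (py - d3[2])) / det
    l2 <- ((d3[2] - d1[2]) * (px - d3[1]) +
           (d1[1] - d3[1]) * (py - d3[2])) / det
    l3 <- 1 - l1 - l2
    tolb <- 1e-9
    ins <- l1 >= -tolb & l2 >= -tolb & l3 >= -tolb
    if (!any(ins)) next
    sx <- l1[ins] * s1[1] + l2[ins] * s2[1] + l3[ins] * s3[1]
    sy <- l1[ins] * s1[2] + l2[ins] * s2[2] + l3[ins] * s3[2]
    out[cbind(py[ins] + 1, px[ins] + 1)] <- .bilinear(img, sx, sy)
  }
  out
}

#' Population-average appearance image
#'
#' Aligns the cohort's landmarks to their Procrustes consensus shape, warps
#' each subject's image onto it, and averages pixel-wise. With a single
#' subject the consensus is that subject's own shape.
#'
#' @param images list of grayscale images (matrices).
#' @param landmarks list of \linkS4class{LandmarkSet}, parallel to
#'   \code{images}.
#' @param shape optional precomputed \linkS4class{ConsensusShape}; computed
#'   from \code{landmarks} when NULL.
#' @inheritParams warpToShape
#' @return list with \code{image} (the atlas matrix), \code{shape} and
#'   \code{n}.
#' @export
populationMeanImage <- function(images, landmarks, shape = NULL,
                                canvas = c(256, 256), interTragion = 160) {
  if (!length(images))
    stop("empty selection: no images to average")
  if (length(images) != length(landmarks))
    stop("images and landmarks must be parallel lists")
  if (is.null(shape)) {
    shape <- if (length(landmarks) >= 2) meanShape(landmarks) else {
      cs <- .centerScale(landmarkPoints(landmarks[[1]]))
      new("ConsensusShape", points = cs$P, transforms = list())
    }
  }
  acc <- matrix(0, canvas[2], canvas[1])
  for (i in seq_along(images))
    acc <- acc + warpToShape(images[[i]], landmarks[[i]], shape,
                             canvas, interTragion)
  list(image = acc / length(images), shape = shape, n = length(images))
}
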