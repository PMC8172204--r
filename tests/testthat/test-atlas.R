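tf <- templateFace()

randomSim <- function(pts, seed) {
  set.seed(seed)
  applySimilarity(pts, runif(1, -pi, pi), runif(1, 0.5, 2),
                  runif(1, -30, 30), runif(1, -30, 30))
}

## full Procrustes distance between two configurations (translation,
## rotation, scale removed)
procDist <- function(A, B) {
  cs <- function(P) { P <- sweep(P, 2, colMeans(P)); P / sqrt(sum(P^2)) }
  A <- cs(A); B <- cs(B)
  sv <- svd(crossprod(A, B))
  sqrt(max(0, 1 - sum(sv$d)^2))
}

test_that("consensus of similarity-transformed copies is the common shape", {
  pts <- landmarkPoints(tf$landmarks)
  shapes <- lapply(1:5, function(s)
    LandmarkSet(paste0("s", s), randomSim(pts, s)))
  cons <- meanShape(shapes)
  expect_lt(procDist(consensusPoints(cons), pts), 1e-7)
  ## canonical frame invariants are enforced by the class validity
  expect_true(validObject(cons))
})

test_that("consensus is independent of subject order", {
  pts <- landmarkPoints(tf$landmarks)
  set.seed(1)
  shapes <- lapply(1:6, function(s) {
    p <- pts + matrix(rnorm(length(pts), 0, 3), nrow(pts))
    LandmarkSet(paste0("s", s), randomSim(p, s + 10))
  })
  c1 <- meanShape(shapes)
  c2 <- meanShape(rev(shapes))
  expect_lt(max(abs(consensusPoints(c1) - consensusPoints(c2))), 1e-6)
})

test_that("two-shape consensus lies midway in Procrustes coordinates", {
  pts <- landmarkPoints(tf$landmarks)
  set.seed(2)
  p2 <- pts + matrix(rnorm(length(pts), 0, 4), nrow(pts))
  cons <- meanShape(list(LandmarkSet("a", pts), LandmarkSet("b", p2)))
  d1 <- procDist(consensusPoints(cons), pts)
  d2 <- procDist(consensusPoints(cons), p2)
  expect_equal(d1, d2, tolerance = 1e-6)
})

test_that("pairwise alignment agrees with vegan's Procrustes residual", {
  skip_if_not_installed("vegan")
  pts <- landmarkPoints(tf$landmarks)
  set.seed(3)
  p2 <- randomSim(pts + matrix(rnorm(length(pts), 0, 3), nrow(pts)), 77)
  cs <- function(P) { P <- sweep(P, 2, colMeans(P)); P / sqrt(sum(P^2)) }
  al <- FacePheno:::.alignOnto(cs(p2), cs(pts))
  ours <- sum((al$aligned - cs(pts))^2)
  v <- vegan::procrustes(cs(pts), cs(p2), symmetric = FALSE)
  expect_equal(ours, v$ss, tolerance = 1e-8)
})

test_that("Delaunay triangulation covers the hull and respects empty circles", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.5, 0.5))
  tri <- delaunayTriangulation(sq)
  expect_equal(nrow(tri), 4)
  area <- function(t) abs(det(rbind(sq[t[2], ] - sq[t[1], ],
                                    sq[t[3], ] - sq[t[1], ]))) / 2
  expect_equal(sum(apply(tri, 1, area)), 1, tolerance = 1e-12)

  set.seed(4)
  pts <- cbind(runif(25), runif(25))
  tri2 <- delaunayTriangulation(pts)
  a2 <- function(t) abs(det(rbind(pts[t[2], ] - pts[t[1], ],
                                  pts[t[3], ] - pts[t[1], ]))) / 2
  hull <- grDevices::chull(pts)
  hullArea <- abs(sum(vapply(seq_along(hull), function(i) {
    j <- if (i == length(hull)) 1 else i + 1
    pts[hull[i], 1] * pts[hull[j], 2] - pts[hull[j], 1] * pts[hull[i], 2]
  }, numeric(1)))) / 2
  expect_equal(sum(apply(tri2, 1, a2)), hullArea, tolerance = 1e-9)

  expect_error(delaunayTriangulation(rbind(c(0, 0), c(1, 1), c(2, 2))),
               "degenerate|collinear")
})

test_that("identity warp reproduces the input over the triangulated region", {
  cons <- meanShape(list(tf$landmarks, tf$landmarks))
  w <- warpToShape(tf$image, tf$landmarks, cons)
  ## the consensus canvas re-centers the face; warp the warped image once
  ## more with src = its own rendered landmark positions: instead check
  ## src = dst directly by building a consensus from the template itself and
  ## rendering at the identical geometry
  dstPix <- FacePheno:::.shapeToCanvas(cons)
  ## template landmarks equal the canvas positions up to a rigid shift;
  ## compare against a rendering at the consensus geometry
  ref <- renderFace(LandmarkSet("c", dstPix))
  inner <- w > 0
  expect_gt(cor(w[inner], ref[inner]), 0.96)

  ## strict identity: source landmarks already on the consensus canvas
  lsC <- LandmarkSet("c", dstPix)
  imgC <- renderFace(lsC)
  wId <- warpToShape(imgC, lsC, cons)
  expect_lt(max(abs(wId - imgC)), 1e-6)
})

test_that("a uniformly scaled face warps back onto the unscaled rendering", {
  ctr <- c(128, 140)
  pts <- sweep(1.2 * sweep(landmarkPoints(tf$landmarks), 2, ctr), 2, ctr,
               "+")
  big <- LandmarkSet("big", pts)
  imgBig <- renderFace(big, canvas = c(256, 256))
  cons <- meanShape(list(tf$landmarks, tf$landmarks))
  wBig <- warpToShape(imgBig, big, cons)
  wRef <- warpToShape(tf$image, tf$landmarks, cons)
  ## correspondence is guaranteed inside the landmark hull (outside it the
  ## warp is border-anchor filler): compare there
  dstPix <- FacePheno:::.shapeToCanvas(cons)
  tri <- delaunayTriangulation(dstPix)
  mask <- matrix(FALSE, 256, 256)
  for (t in seq_len(nrow(tri))) {
    v <- dstPix[tri[t, ], ]
    xr <- floor(min(v[, 1])):ceiling(max(v[, 1]))
    yr <- floor(min(v[, 2])):ceiling(max(v[, 2]))
    px <- rep(xr, times = length(yr)); py <- rep(yr, each = length(xr))
    dt <- (v[2, 2] - v[3, 2]) * (v[1, 1] - v[3, 1]) +
          (v[3, 1] - v[2, 1]) * (v[1, 2] - v[3, 2])
    l1 <- ((v[2, 2] - v[3, 2]) * (px - v[3, 1]) +
             (v[3, 1] - v[2, 1]) * (py - v[3, 2])) / dt
    l2 <- ((v[3, 2] - v[1, 2]) * (px - v[3, 1]) +
             (v[1, 1] - v[3, 1]) * (py - v[3, 2])) / dt
    ins <- l1 >= 0 & l2 >= 0 & (1 - l1 - l2) >= 0
    mask[cbind(py[ins] + 1, px[ins] + 1)] <- TRUE
  }
  expect_gt(cor(wBig[mask], wRef[mask]), 0.99)
  expect_lt(mean(abs(wBig[mask] - wRef[mask])), 2)
})

test_that("displacing one landmark only repaints its incident triangles", {
  cons <- meanShape(list(tf$landmarks, tf$landmarks))
  w0 <- warpToShape(tf$image, tf$landmarks, cons)
  moved <- landmarkPoints(tf$landmarks)
  moved["nose_tip", ] <- moved["nose_tip", ] + c(6, 0)
  w1 <- warpToShape(tf$image, LandmarkSet("m", moved), cons)
  diffIdx <- which(abs(w1 - w0) > 1e-9, arr.ind = TRUE)
  expect_gt(nrow(diffIdx), 0)
  ## all changed pixels lie near the nose tip's position on the canvas
  dstPix <- FacePheno:::.shapeToCanvas(cons)
  ctr <- dstPix["nose_tip", ]
  d <- sqrt((diffIdx[, 2] - 1 - ctr[1])^2 + (diffIdx[, 1] - 1 - ctr[2])^2)
  expect_lt(max(d), 60)
})

test_that("population mean image: bounds, identity, order independence", {
  set.seed(6)
  shapes <- lapply(1:3, function(s) {
    p <- landmarkPoints(tf$landmarks) +
      matrix(rnorm(88, 0, 2), 44)
    LandmarkSet(paste0("s", s), p)
  })
  imgs <- lapply(shapes, renderFace)
  atl <- populationMeanImage(imgs, shapes)
  expect_equal(dim(atl$image), c(256, 256))
  expect_gte(min(atl$image), 0)
  expect_lte(max(atl$image), 255)
  atl2 <- populationMeanImage(rev(imgs), rev(shapes))
  expect_lt(max(abs(atl$image - atl2$image)), 1e-6)

  one <- populationMeanImage(imgs[c(1, 1)], shapes[c(1, 1)])
  single <- warpToShape(imgs[[1]], shapes[[1]], one$shape)
  expect_equal(one$image, single)

  expect_error(populationMeanImage(list(), list()), "empty")
})
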