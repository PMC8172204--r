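tpl <- templateFace(render = FALSE)$landmarks

## landmark set with prescribed anchors for reference-length checks
anchoredSet <- function(tragL = c(0, 0), tragR = c(100, 0),
                        comL = c(40, 80), comR = c(60, 80),
                        nas = c(50, 20)) {
  pts <- landmarkPoints(tpl)
  pts["tragion_L", ] <- tragL; pts["tragion_R", ] <- tragR
  pts["oral_commissure_L", ] <- comL; pts["oral_commissure_R", ] <- comR
  pts["nasion", ] <- nas
  LandmarkSet("anchored", pts)
}

test_that("face frame: axis-aligned case, rotation equivariance, degeneracy", {
  ls <- anchoredSet(tragL = c(0, 0), tragR = c(10, 0),
                    comL = c(4, 8), comR = c(6, 8), nas = c(5, 2))
  fr <- faceFrame(ls)
  expect_equal(fr$origin, c(x = 5, y = 0))
  expect_equal(fr$xaxis, c(x = 1, y = 0))
  expect_equal(fr$yaxis, c(0, 1))

  ## same face rotated 30 degrees: frame-relative coordinates unchanged
  pts <- landmarkPoints(tpl)
  rot <- applySimilarity(pts, pi / 6, 1, 0, 0)
  fr1 <- faceFrame(tpl); fr2 <- faceFrame(LandmarkSet("r", rot))
  rel <- function(fr, p) cbind((p[, 1] - fr$origin[1]) * fr$xaxis[1] +
                                 (p[, 2] - fr$origin[2]) * fr$xaxis[2],
                               (p[, 1] - fr$origin[1]) * fr$yaxis[1] +
                                 (p[, 2] - fr$origin[2]) * fr$yaxis[2])
  expect_equal(rel(fr1, pts), rel(fr2, rot), tolerance = 1e-9)

  degenerate <- landmarkPoints(tpl)
  degenerate["tragion_R", ] <- degenerate["tragion_L", ]
  expect_error(faceFrame(LandmarkSet("d", degenerate)), "degenerate")
})

test_that("reference lengths follow the two stated normalization rules", {
  ls <- anchoredSet()
  refs <- referenceLengths(ls)
  expect_equal(unname(refs["horizontal_ref"]), 100)
  expect_equal(unname(refs["vertical_ref"]), 60)

  ## homogeneity: uniform 2x scaling doubles both references
  ls2 <- LandmarkSet("x2", 2 * landmarkPoints(ls))
  expect_equal(referenceLengths(ls2), 2 * refs)

  bad <- landmarkPoints(ls)
  bad["nasion", ] <- (bad["oral_commissure_L", ] +
                        bad["oral_commissure_R", ]) / 2
  expect_error(referenceLengths(LandmarkSet("b", bad)), "degenerate")
})

test_that("evaluateMetric: frame-axis distances and interior angles", {
  pts <- landmarkPoints(tpl)
  pts["nose_tip", ] <- c(10, 50); pts["subnasale", ] <- c(40, 70)
  ls <- LandmarkSet("m", pts)
  defH <- list(name = "t", kind = "horizontal_distance", lm1 = "nose_tip",
               lm2 = "subnasale", lm3 = NA, laterality = "midline",
               normalization = "horizontal_ref")
  expect_equal(unname(evaluateMetric(ls, defH)), 30)

  pts2 <- landmarkPoints(tpl)
  pts2["columella", ] <- c(0, 0); pts2["nose_tip", ] <- c(1, 0)
  pts2["nose_bridge", ] <- c(0, 1)
  defA <- list(name = "a", kind = "angle", lm1 = "nose_tip",
               lm2 = "columella", lm3 = "nose_bridge",
               laterality = "midline", normalization = "none")
  expect_equal(unname(evaluateMetric(LandmarkSet("a", pts2), defA)), 90)

  defV <- list(name = "v", kind = "vertical_distance", lm1 = "tragion_L",
               lm2 = "tragion_R", lm3 = NA, laterality = "midline",
               normalization = "vertical_ref")
  expect_equal(unname(evaluateMetric(tpl, defV)), 0)

  defMiss <- defH; defMiss$lm1 <- "no_such_landmark"
  expect_error(evaluateMetric(ls, defMiss), "no_such_landmark")
})

test_that("paired feature formulas: sym = mean/ref, asym = |L-R|/mean", {
  pts <- landmarkPoints(tpl)
  pts["tragion_L", ] <- c(0, 0); pts["tragion_R", ] <- c(100, 0)
  pts["ala_base_L", ] <- c(10, 50); pts["ala_outer_L", ] <- c(13, 50)
  pts["ala_base_R", ] <- c(90, 50); pts["ala_outer_R", ] <- c(89, 50)
  cat1 <- MetricCatalog(data.frame(
    name = "ala_length", kind = "horizontal_distance", lm1 = "ala_base_L",
    lm2 = "ala_outer_L", lm3 = NA, laterality = "paired",
    normalization = "horizontal_ref", stringsAsFactors = FALSE))
  g <- extractGeometricFeatures(LandmarkSet("p", pts), cat1)
  expect_equal(unname(g["geom.ala_length.sym"]), 0.02)  # mean(3,1)/100
  expect_equal(unname(g["geom.ala_length.asym"]), 1.0)  # |3-1|/2
})

test_that("mirror symmetry nulls every asymmetry feature", {
  g <- extractGeometricFeatures(tpl)
  asym <- g[grep("\\.asym$", names(g))]
  expect_true(all(abs(asym) < 1e-12))

  ## a mirrored landmark set also yields identical features
  pts <- landmarkPoints(tpl)
  mir <- pts; mir[, 1] <- 256 - mir[, 1]
  expect_equal(extractGeometricFeatures(LandmarkSet("m", mir)), g)
})

test_that("geometric features are similarity-invariant (tol 1e-9)", {
  g0 <- extractGeometricFeatures(tpl)
  set.seed(42)
  for (i in 1:20) {
    pts <- applySimilarity(landmarkPoints(tpl), runif(1, -pi, pi),
                           runif(1, 0.3, 3), runif(1, -50, 50),
                           runif(1, -50, 50))
    g <- extractGeometricFeatures(LandmarkSet("t", pts))
    expect_lt(max(abs(g - g0)), 1e-9)
  }
})

test_that("raw distances scale linearly; normalized features do not", {
  ls2 <- LandmarkSet("x2", 2 * landmarkPoints(tpl))
  def <- metricDefs(defaultMetricCatalog())
  mw <- def[def$name == "mouth_width", ]
  expect_equal(evaluateMetric(ls2, mw), 2 * evaluateMetric(tpl, mw))
  expect_equal(extractGeometricFeatures(ls2), extractGeometricFeatures(tpl))
})

test_that("swapping the left and right sides leaves sym and asym unchanged", {
  pts <- landmarkPoints(tpl)
  set.seed(7)
  pts <- pts + matrix(rnorm(length(pts), 0, 2), nrow(pts))
  pairs <- defaultLandmarkScheme()$pairs
  swapped <- pts
  swapped[pairs[, 1], ] <- pts[pairs[, 2], ]
  swapped[pairs[, 2], ] <- pts[pairs[, 1], ]
  ## mirror x so the swapped set is a legal face (left still at smaller x)
  swapped[, 1] <- 256 - swapped[, 1]
  g1 <- extractGeometricFeatures(LandmarkSet("a", pts))
  g2 <- extractGeometricFeatures(LandmarkSet("b", swapped))
  expect_equal(g1, g2, tolerance = 1e-12)
})
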