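test_that("template face validates, is deterministic and mirror-symmetric", {
  tf1 <- templateFace()
  tf2 <- templateFace()
  expect_true(validObject(tf1$landmarks))
  expect_identical(tf1$image, tf2$image)
  expect_identical(landmarkPoints(tf1$landmarks),
                   landmarkPoints(tf2$landmarks))
  g <- extractGeometricFeatures(tf1$landmarks)
  expect_true(all(abs(g[grep("\\.asym$", names(g))]) < 1e-12))
  refs <- referenceLengths(tf1$landmarks)
  expect_equal(unname(refs["horizontal_ref"]), 160)
})

test_that("null config reproduces the template exactly", {
  cfg <- frozenConfig(groupSizesMatrix(1),
                      effects = data.frame(metric = "mouth_width",
                                           effect = 0))
  sub <- generateSubject(cfg, "WBS", "Caucasian",
                         calibration = list(offsetPx = 0))
  tf <- templateFace()
  expect_equal(landmarkPoints(sub$landmarks),
               landmarkPoints(tf$landmarks))
  expect_equal(sub$image, tf$image)
})

test_that("cohorts are seed-deterministic with stable ground truth", {
  gs <- groupSizesMatrix(2)
  cfg <- geomOnlyConfig(gs, seed = 3L)
  c1 <- generateCohort(cfg, renderImages = FALSE)
  c2 <- generateCohort(cfg, renderImages = FALSE)
  expect_identical(lapply(c1@landmarks, landmarkPoints),
                   lapply(c2@landmarks, landmarkPoints))
  expect_identical(c1@metadata, c2@metadata)

  c3 <- generateCohort(geomOnlyConfig(gs, seed = 4L), renderImages = FALSE)
  expect_false(identical(landmarkPoints(c1@landmarks[[1]]),
                         landmarkPoints(c3@landmarks[[1]])))
  expect_identical(c1@groundTruth$features, c3@groundTruth$features)
  expect_identical(c1@groundTruth$effectSizes, c3@groundTruth$effectSizes)
})

test_that("group sizes are honored, including empty cells", {
  gs <- groupSizesMatrix(2)
  gs["NS", "Asian"] <- 0
  co <- generateCohort(geomOnlyConfig(gs, seed = 5L), renderImages = FALSE)
  tab <- table(co@metadata$diagnosis, co@metadata$ethnicity)
  expect_equal(sum(co@metadata$diagnosis == "NS" &
                     co@metadata$ethnicity == "Asian"), 0)
  expect_equal(nrow(co@metadata), sum(gs))
  expect_true(all(c(co@metadata$age_group) %in%
                    c("infant", "toddler", "child", "adolescent", "adult")))
  ## pipeline still runs on the cohort with a missing cell
  fs <- extractFeatures(co, texture = NULL)
  expect_equal(ncol(SummarizedExperiment::assay(fs)), sum(gs))
})

test_that("planted standardized effects are realized within 10%", {
  gs <- matrix(c(0, 0, 400, 0, 0, 0, 400, 0), 2, 4, byrow = TRUE,
               dimnames = list(c("NS", "WBS"), strataNames))
  co <- generateCohort(geomOnlyConfig(gs, seed = 1L), renderImages = FALSE)
  fs <- extractFeatures(co, texture = NULL)
  X <- featureMatrixOf(fs); y <- diagnosisOf(fs)
  gt <- co@groundTruth
  for (f in gt$geometricFeatures) {
    a <- X[y == "WBS", f]; b <- X[y == "NS", f]
    d <- (mean(a) - mean(b)) / sqrt((var(a) + var(b)) / 2)
    expect_lt(abs(d / gt$effectSizes[f, "Caucasian"] - 1), 0.10,
              label = paste("relative effect-size error for", f))
  }
})

test_that("random similarity transforms never leak into geometric features", {
  ## jitter and noise off, transforms on: extracted geometric features must
  ## be constant within each class (they exist to prove end-to-end
  ## pose invariance)
  cfg <- geomOnlyConfig(groupSizesMatrix(0, c(0, 0, 12, 0)),
                        landmarkJitterSD = 0, intensityNoiseSD = 0,
                        seed = 6L)
  co <- generateCohort(cfg, renderImages = FALSE)
  fs <- extractFeatures(co, texture = NULL)
  X <- featureMatrixOf(fs)
  spread <- apply(X, 2, function(v) diff(range(v)))
  expect_lt(max(spread), 1e-9)
})

test_that("a cohort with no planted effects yields chance-level LOOCV", {
  aucs <- vapply(1:10, function(s) {
    cfg <- geomOnlyConfig(groupSizesMatrix(c(0, 0, 20, 0)),
                          effects = data.frame(metric = "mouth_width",
                                               effect = 0),
                          seed = 100L + s)
    co <- generateCohort(cfg, renderImages = FALSE)
    fs <- extractFeatures(co, texture = NULL)
    cv <- loocvCurve(fs, kGrid = c(4, 16, 32))
    mean(cv$curves$auc)
  }, numeric(1))
  expect_gte(mean(aucs), 0.4)
  expect_lte(mean(aucs), 0.6)
})

test_that("written cohorts restore identically through the file layout", {
  gs <- groupSizesMatrix(c(0, 2, 2, 0))
  co <- generateCohort(geomOnlyConfig(gs, seed = 7L), renderImages = TRUE)
  dir <- withr::local_tempdir()
  writeCohort(co, dir)
  expect_true(file.exists(file.path(dir, "metadata.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  fsMem <- extractFeatures(co)
  fsDisk <- extractFeatures(dir)
  ## PGM quantizes intensities to integers; geometric features match
  ## exactly, texture bits agree for nearly all comparisons
  gm <- grepl("^geom", rownames(SummarizedExperiment::assay(fsMem)))
  expect_equal(SummarizedExperiment::assay(fsDisk)[gm, ],
               SummarizedExperiment::assay(fsMem)[gm, ], tolerance = 1e-6)
  agree <- mean(SummarizedExperiment::assay(fsDisk)[!gm, ] ==
                  SummarizedExperiment::assay(fsMem)[!gm, ])
  expect_gt(agree, 0.97)
})
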