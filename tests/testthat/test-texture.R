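test_that("grayscale conversion uses BT.601 luminance weights", {
  rgb <- array(0, c(1, 1, 3))
  rgb[1, 1, ] <- 255
  expect_equal(toGrayscale(rgb)[1, 1], 255)
  red <- array(0, c(1, 1, 3)); red[1, 1, 1] <- 255
  expect_equal(toGrayscale(red)[1, 1], 76.245)
  g <- matrix(runif(12, 0, 255), 3)
  expect_identical(toGrayscale(g), g)
  expect_error(toGrayscale(matrix(numeric(0), 0, 0)), "empty")
})

test_that("block means tile 3x3 around the center with edge replication", {
  img <- matrix(7, 20, 20)
  expect_equal(blockMeans(img, c(10, 10), 3), matrix(7, 3, 3))

  ## left half 0 / right half 255, center on the boundary column, block 3:
  ## direct pixel-mean oracle
  img2 <- cbind(matrix(0, 9, 5), matrix(255, 9, 4))
  bm <- blockMeans(img2, c(4, 4), 3)   # 0-based col 4 = last zero column
  oracle <- function(cx, cy) {
    xs <- pmin(pmax((cx - 1):(cx + 1), 0), 8) + 1
    ys <- pmin(pmax((cy - 1):(cy + 1), 0), 8) + 1
    mean(img2[ys, xs])
  }
  for (j in -1:1) for (i in -1:1)
    expect_equal(bm[j + 2, i + 2], oracle(4 + 3 * i, 4 + 3 * j))
  expect_equal(bm[, 1], rep(0, 3))
  expect_equal(bm[, 3], rep(255, 3))

  ## corner center: replication keeps it well-defined
  expect_equal(blockMeans(img, c(0, 0), 5), matrix(7, 3, 3))
  expect_error(blockMeans(img, c(25, 3), 3), "bounds")
})

test_that("mblbp code follows the clockwise big-endian bit convention", {
  g <- matrix(10, 3, 3)
  ## clockwise from top-left: TL,T,TR,R,BR,B,BL,L = 11,9,10,12,8,10,10,13
  g[1, 1] <- 11; g[1, 2] <- 9; g[1, 3] <- 10; g[2, 3] <- 12
  g[3, 3] <- 8; g[3, 2] <- 10; g[3, 1] <- 10; g[2, 1] <- 13
  r <- mblbpCode(g, "ge")
  expect_equal(r$bits, c(1, 0, 1, 1, 0, 1, 1, 1))
  expect_equal(r$code, 183)

  const <- matrix(5, 3, 3)
  expect_equal(mblbpCode(const, "ge")$code, 255)
  expect_equal(mblbpCode(const, "gt")$code, 0)
})

test_that("codes are invariant under increasing affine intensity maps", {
  set.seed(3)
  for (i in 1:25) {
    img <- matrix(runif(400, 0, 255), 20)
    ctr <- c(sample(5:14, 1), sample(5:14, 1))
    g1 <- blockMeans(img, ctr, 3)
    g2 <- blockMeans(1.7 * img + 12, ctr, 3)
    expect_equal(mblbpCode(g1, "gt")$code, mblbpCode(g2, "gt")$code)
    expect_equal(mblbpCode(g1, "ge")$code, mblbpCode(g2, "ge")$code)
  }
})

test_that("descriptor: 792 bits, constant-image ties, determinism", {
  tf <- templateFace()
  const <- matrix(100, 256, 256)
  d <- landmarkDescriptor(const, tf$landmarks)
  expect_length(d, 792)
  expect_true(all(d == 1))   # rule ge: every comparison ties

  d1 <- landmarkDescriptor(tf$image, tf$landmarks)
  d2 <- landmarkDescriptor(tf$image, tf$landmarks)
  expect_identical(d1, d2)

  ## monotone intensity transform, gt rule
  cfgGt <- TexturePatchConfig(comparisonRule = "gt")
  expect_identical(landmarkDescriptor(tf$image, tf$landmarks, cfgGt),
                   landmarkDescriptor(0.5 * tf$image + 20, tf$landmarks,
                                      cfgGt))

  oob <- landmarkPoints(tf$landmarks)
  oob["nose_tip", ] <- c(500, 500)
  expect_error(
    landmarkDescriptor(tf$image, LandmarkSet("o", oob)), "nose_tip")
})

test_that("a local intensity edit only changes the edited landmark's bits", {
  tf <- templateFace()
  edited <- tf$image
  ## small dark patch right on eyebrow_outer_L (66, 88); every other inner
  ## landmark's largest block window stays clear of it
  edited[87:91, 65:69] <- 0
  d0 <- landmarkDescriptor(tf$image, tf$landmarks)
  d1 <- landmarkDescriptor(edited, tf$landmarks)
  changed <- unique(sub("^lbp\\.([^.]+(_L|_R)?.*?)\\.R[123]\\.b[0-7]$", "\\1",
                        names(d0)[d0 != d1]))
  changed <- unique(sub("\\.R[123]\\.b[0-7]$", "", names(d0)[d0 != d1]))
  expect_true(length(changed) >= 1)
  expect_equal(changed, "lbp.eyebrow_outer_L")
})

test_that("histogram representation is normalized per landmark-resolution", {
  tf <- templateFace()
  cfgH <- TexturePatchConfig(representation = "histogram",
                             scaleNormalize = FALSE)
  d <- landmarkDescriptor(tf$image, tf$landmarks, cfgH)
  expect_length(d, 33 * 3 * 256)
  sums <- tapply(d, sub("\\.h[0-9]+$", "", names(d)), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_true(all(d >= 0))
})
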