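#' @include AllClasses.R landmarks.R geometry.R texture.R
NULL

## ---- template landmarks and renderer --------------------------------------

.templatePoints <- function() {
  co <- rbind(
    eyebrow_inner_L = c(104, 88), eyebrow_inner_R = c(152, 88),
    eyebrow_mid_L = c(84, 82), eyebrow_mid_R = c(172, 82),
    eyebrow_outer_L = c(66, 88), eyebrow_outer_R = c(190, 88),
    canthus_inner_L = c(106, 108), canthus_inner_R = c(150, 108),
    canthus_outer_L = c(72, 106), canthus_outer_R = c(184, 106),
    eyelid_upper_L = c(89, 102), eyelid_upper_R = c(167, 102),
    eyelid_lower_L = c(89, 112), eyelid_lower_R = c(167, 112),
    nasion = c(128, 102), nose_bridge = c(128, 122),
    nose_tip = c(128, 150), subnasale = c(128, 162),
    columella = c(128, 156),
    ala_outer_L = c(110, 150), ala_outer_R = c(146, 150),
    ala_base_L = c(114, 158), ala_base_R = c(142, 158),
    oral_commissure_L = c(98, 184), oral_commissure_R = c(158, 184),
    cupid_bow_L = c(120, 178), cupid_bow_R = c(136, 178),
    cupid_bow_mid = c(128, 180), philtrum_L = c(120, 166),
    philtrum_R = c(136, 166), philtrum_mid = c(128, 170),
    stomion = c(128, 188), lower_lip_mid = c(128, 200),
    tragion_L = c(48, 120), tragion_R = c(208, 120),
    ear_superior_L = c(50, 96), ear_superior_R = c(206, 96),
    ear_inferior_L = c(52, 146), ear_inferior_R = c(204, 146),
    gonion_L = c(72, 186), gonion_R = c(184, 186),
    zygion_L = c(58, 132), zygion_R = c(198, 132),
    menton = c(128, 234)
  )
  colnames(co) <- c("x", "y")
  co[defaultLandmarkScheme()$names, ]
}

.gaussBlur <- function(img, sigma = 1.2) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  h <- nrow(img); w <- ncol(img)
  pad <- function(n, r) c(rep(1, r), seq_len(n), rep(n, r))
  tmp <- img[pad(h, r), ]
  tmp <- apply(tmp, 2, function(col) stats::filter(col, k)[(r + 1):(r + h)])
  tmp <- tmp[, pad(w, r)]
  t(apply(tmp, 1, function(row) stats::filter(row, k)[(r + 1):(r + w)]))
}

.drawStroke <- function(img, poly, width, delta, soft = TRUE) {
  h <- nrow(img); w <- ncol(img)
  mask <- matrix(0, h, w)
  for (s in seq_len(nrow(poly) - 1)) {
    p1 <- poly[s, ]; p2 <- poly[s + 1, ]
    pad <- width + 2
    xr <- max(0, floor(min(p1[1], p2[1]) - pad)):
          min(w - 1, ceiling(max(p1[1], p2[1]) + pad))
    yr <- max(0, floor(min(p1[2], p2[2]) - pad)):
          min(h - 1, ceiling(max(p1[2], p2[2]) + pad))
    if (!length(xr) || !length(yr)) next
    gx <- matrix(rep(xr, each = length(yr)), length(yr))
    gy <- matrix(rep(yr, times = length(xr)), length(yr))
    d21 <- p2 - p1
    len2 <- max(sum(d21^2), 1e-12)
    tt <- ((gx - p1[1]) * d21[1] + (gy - p1[2]) * d21[2]) / len2
    tt <- pmin(pmax(tt, 0), 1)
    dist <- sqrt((gx - (p1[1] + tt * d21[1]))^2 +
                 (gy - (p1[2] + tt * d21[2]))^2)
    m <- if (soft) pmax(0, 1 - (dist / width)^2) else (dist <= width) * 1
    sub <- mask[yr + 1, xr + 1]
    mask[yr + 1, xr + 1] <- pmax(sub, m)
  }
  img - delta * mask
}

.drawDisk <- function(img, center, radius, delta) {
  .drawStroke(img, rbind(center, center + 1e-6), radius, delta)
}

## Ellipse mask in face-frame coordinates (rotation-equivariant)
.drawEllipseUV <- function(img, U, V, cu, cv, a, b, delta) {
  r2 <- ((U - cu) / a)^2 + ((V - cv) / b)^2
  img - delta * pmax(0, 1 - r2)
}

#' Render a smooth synthetic face from a landmark configuration
#'
#' Deterministic rendering (no randomness): ellipsoidal skin shading with
#' darkened eyebrow, eye, nostril and lip regions, all positioned and
#' oriented from the landmark coordinates, followed by a Gaussian blur.
#' Every inner landmark sits on nontrivial intensity structure so its block
#' LBP codes are informative.
#'
#' @param ls a \linkS4class{LandmarkSet}.
#' @param canvas image width/height in pixels.
#' @return grayscale image matrix (canvas[2] rows x canvas[1] columns),
#'   intensities in [0, 255].
#' @export
renderFace <- function(ls, canvas = c(256, 256)) {
  w <- canvas[1]; h <- canvas[2]
  pts <- landmarkPoints(ls)
  fr <- faceFrame(ls)
  it <- referenceLengths(ls)[["horizontal_ref"]]
  X <- matrix(rep(0:(w - 1), each = h), h)
  Y <- matrix(rep(0:(h - 1), times = w), h)
  U <- (X - fr$origin[1]) * fr$xaxis[1] + (Y - fr$origin[2]) * fr$xaxis[2]
  V <- (X - fr$origin[1]) * fr$yaxis[1] + (Y - fr$origin[2]) * fr$yaxis[2]
  uv <- function(nm) {
    d <- pts[nm, ] - fr$origin
    c(sum(d * fr$xaxis), sum(d * fr$yaxis))
  }
  sc <- it / 160   # primitive sizes track the face scale
  img <- matrix(40, h, w)
  ## skin: shaded ellipse over the face
  r2 <- (U / (0.62 * it))^2 + ((V - 0.22 * it) / (0.82 * it))^2
  inside <- r2 < 1
  img[inside] <- 195 - 55 * r2[inside]
  ## eyebrows
  for (side in c("L", "R"))
    img <- .drawStroke(img, pts[paste0(c("eyebrow_inner_", "eyebrow_mid_",
                                         "eyebrow_outer_"), side), ],
                       2.5 * sc, 70)
  ## eyes: socket + fissure + iris
  for (side in c("L", "R")) {
    ci <- uv(paste0("canthus_inner_", side))
    co <- uv(paste0("canthus_outer_", side))
    eu <- uv(paste0("eyelid_upper_", side))
    el <- uv(paste0("eyelid_lower_", side))
    ctr <- c((ci[1] + co[1]) / 2, (eu[2] + el[2]) / 2)
    a <- max(abs(ci[1] - co[1]) / 2, 2)
    b <- max(abs(eu[2] - el[2]) / 2, 1.5)
    img <- .drawEllipseUV(img, U, V, ctr[1], ctr[2], a * 1.5, b * 2.4, 20)
    img <- .drawEllipseUV(img, U, V, ctr[1], ctr[2], a, b, 85)
    img <- .drawEllipseUV(img, U, V, ctr[1], ctr[2], b * 0.8, b * 0.8, 55)
  }
  ## nose: bright ridge, alar shading, nostrils
  img <- .drawStroke(img, pts[c("nasion", "nose_bridge", "nose_tip"), ],
                     2 * sc, -22)
  for (side in c("L", "R"))
    img <- .drawStroke(img, pts[paste0(c("ala_outer_", "ala_base_"), side), ],
                       2 * sc, 30)
  img <- .drawDisk(img, pts["ala_base_L", ], 2 * sc, 70)
  img <- .drawDisk(img, pts["ala_base_R", ], 2 * sc, 70)
  ## philtrum groove
  img <- .drawStroke(img, pts[c("subnasale", "philtrum_mid",
                                "cupid_bow_mid"), ], 1.5 * sc, 12)
  ## lips
  upperW <- max(abs(uv("cupid_bow_mid")[2] - uv("stomion")[2]) * 0.8, 1.5)
  lowerW <- max(abs(uv("lower_lip_mid")[2] - uv("stomion")[2]) * 0.8, 1.5)
  img <- .drawStroke(img, pts[c("oral_commissure_L", "cupid_bow_L",
                                "cupid_bow_mid", "cupid_bow_R",
                                "oral_commissure_R"), ], upperW, 45)
  lowMid <- (pts["stomion", ] + pts["lower_lip_mid", ]) / 2
  img <- .drawStroke(img, rbind(pts["oral_commissure_L", ], lowMid,
                                pts["oral_commissure_R", ]), lowerW, 38)
  img <- .drawStroke(img, pts[c("oral_commissure_L", "stomion",
                                "oral_commissure_R"), ], max(1 * sc, 0.8), 45)
  img <- .gaussBlur(img, max(1.2 * sc, 0.5))
  pmin(pmax(img, 0), 255)
}

#' Canonical template face
#'
#' The deterministic 44-landmark layout on a 256 x 256 canvas with a 160-px
#' inter-tragion distance, mirror-symmetric about the facial midline, and
#' its rendering.
#'
#' @param render also render the template image (default TRUE).
#' @return list with \code{landmarks} (a \linkS4class{LandmarkSet}) and
#'   \code{image} (matrix, or NULL when \code{render = FALSE}).
#' @export
#' @examples
#' tf <- templateFace(render = FALSE)
#' tf$landmarks
templateFace <- function(render = TRUE) {
  ls <- LandmarkSet("template", .templatePoints())
  list(landmarks = ls, image = if (render) renderFace(ls))
}

## ---- planted effects ------------------------------------------------------

.anchorNames <- c("tragion_L", "tragion_R", "nasion",
                  "oral_commissure_L", "oral_commissure_R")

## Displace template-frame landmarks so that `metric` changes by about
## `delta` px (axis-aligned template assumed: applied before the random
## similarity transform). Anchor landmarks are left in place (the free
## landmark absorbs the full displacement), except the symmetric
## commissure-separation case which preserves both references.
.applyGeomEffect <- function(pts, def, delta, pairs) {
  mirror <- function(nm) {
    i <- match(nm, pairs[, 1]); if (!is.na(i)) return(pairs[i, 2])
    i <- match(nm, pairs[, 2]); if (!is.na(i)) return(pairs[i, 1])
    nm
  }
  if (def$kind == "angle") {
    rot <- function(pts, arm, vertex, deg) {
      v <- pts[arm, ] - pts[vertex, ]
      th <- deg * pi / 180
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      pts[arm, ] <- pts[vertex, ] + as.numeric(R %*% v)
      pts
    }
    ang0 <- .angleAt(pts[def$lm1, ], pts[def$lm2, ], pts[def$lm3, ])
    trial <- rot(pts, def$lm1, def$lm2, abs(delta))
    ang1 <- .angleAt(trial[def$lm1, ], trial[def$lm2, ], trial[def$lm3, ])
    sgn <- if ((ang1 - ang0) * delta >= 0) 1 else -1
    pts <- rot(pts, def$lm1, def$lm2, sgn * abs(delta))
    if (def$laterality == "paired") {
      a <- mirror(def$lm1); v <- mirror(def$lm2); b <- mirror(def$lm3)
      ang0 <- .angleAt(pts[a, ], pts[v, ], pts[b, ])
      trial <- rot(pts, a, v, abs(delta))
      ang1 <- .angleAt(trial[a, ], trial[v, ], trial[b, ])
      sgn <- if ((ang1 - ang0) * delta >= 0) 1 else -1
      pts <- rot(pts, a, v, sgn * abs(delta))
    }
    return(pts)
  }
  axis <- if (def$kind == "horizontal_distance") 1 else 2
  move <- function(pts, n1, n2, delta) {
    sgn <- sign(pts[n1, axis] - pts[n2, axis])
    if (sgn == 0) sgn <- 1
    free1 <- !(n1 %in% .anchorNames); free2 <- !(n2 %in% .anchorNames)
    bothCommissures <- setequal(c(n1, n2),
                                c("oral_commissure_L", "oral_commissure_R"))
    if (bothCommissures && axis == 1) { free1 <- TRUE; free2 <- TRUE }
    if (free1 && free2) {
      pts[n1, axis] <- pts[n1, axis] + sgn * delta / 2
      pts[n2, axis] <- pts[n2, axis] - sgn * delta / 2
    } else if (free1) {
      pts[n1, axis] <- pts[n1, axis] + sgn * delta
    } else if (free2) {
      pts[n2, axis] <- pts[n2, axis] - sgn * delta
    } else {
      stop("cannot plant effect on metric with two anchor landmarks: ",
           def$name)
    }
    pts
  }
  pts <- move(pts, def$lm1, def$lm2, delta)
  if (def$laterality == "paired")
    pts <- move(pts, mirror(def$lm1), mirror(def$lm2), delta)
  pts
}

## ---- configuration --------------------------------------------------------

#' Synthetic cohort configuration
#'
#' Defaults mirror the study cohort: 286 WBS + 161 NS subjects split over
#' four ethnicity strata (WBS 28/26/121/111 and NS 35/40/40/46 for African /
#' Asian / Caucasian / Latin American), with six planted geometric class
#' differences of standardized effect size 1.5 (NS: wider inner-canthal
#' spacing, higher brow; WBS: wider mouth, thicker lower lip, shorter nose,
#' more down-slanted fissures), per-stratum effect modulation that zeroes
#' the fissure-slant effect for the African and Latin American strata and
#' the inner-canthal effect for the Asian stratum, class-dependent local
#' texture stamps, landmark jitter, random similarity transforms, and
#' additive intensity noise.
#'
#' @param groupSizes 2 x 4 matrix of counts, rownames \code{NS}/\code{WBS},
#'   colnames the four strata.
#' @param geometricEffects data.frame(metric, effect): planted class-mean
#'   offsets (WBS minus NS) in units of the feature's noise SD.
#' @param textureEffects data.frame(landmark, pattern, contrast): local
#'   patterns stamped on WBS subjects near the named landmark
#'   (pattern \code{"stripes"} or \code{"spots"}; contrast in intensity
#'   units).
#' @param stratumModulation matrix (effects x strata) of multipliers on the
#'   geometric effect sizes.
#' @param landmarkJitterSD per-landmark Gaussian jitter SD in pixels.
#' @param rotationRange max |rotation| of the random similarity transform
#'   (degrees).
#' @param scaleRange c(min, max) uniform scale factor range.
#' @param translationRange max |translation| per axis (pixels).
#' @param intensityNoiseSD additive Gaussian image noise SD (intensity
#'   units).
#' @param seed integer RNG seed.
#' @return a validated config (list with class
#'   \code{"SyntheticCohortConfig"}).
#' @export
SyntheticCohortConfig <- function(
    groupSizes = NULL,
    geometricEffects = NULL,
    textureEffects = NULL,
    stratumModulation = NULL,
    landmarkJitterSD = 1.2,
    rotationRange = 8,
    scaleRange = c(0.9, 1.1),
    translationRange = 10,
    intensityNoiseSD = 6,
    seed = 1L) {
  strata <- c("African", "Asian", "Caucasian", "LatinAmerican")
  if (is.null(groupSizes)) {
    groupSizes <- rbind(NS = c(35, 40, 40, 46), WBS = c(28, 26, 121, 111))
    colnames(groupSizes) <- strata
  }
  if (is.null(geometricEffects))
    geometricEffects <- data.frame(
      metric = c("intercanthal_inner", "orbital_rim_height", "mouth_width",
                 "lower_lip_thickness", "nose_length", "fissure_slant"),
      effect = c(-1.5, -1.5, 1.5, 1.5, -1.5, 1.5),
      stringsAsFactors = FALSE)
  if (is.null(textureEffects))
    textureEffects <- data.frame(
      landmark = c("philtrum_mid", "nose_bridge"),
      pattern = c("stripes", "spots"),
      contrast = c(10, 10),
      stringsAsFactors = FALSE)
  if (is.null(stratumModulation)) {
    stratumModulation <- matrix(1, nrow(geometricEffects), length(strata),
                                dimnames = list(geometricEffects$metric,
                                                strata))
    if ("fissure_slant" %in% rownames(stratumModulation)) {
      stratumModulation["fissure_slant", c("African", "LatinAmerican")] <- 0
    }
    if ("intercanthal_inner" %in% rownames(stratumModulation))
      stratumModulation["intercanthal_inner", "Asian"] <- 0
  }
  cfg <- list(groupSizes = groupSizes, geometricEffects = geometricEffects,
              textureEffects = textureEffects,
              stratumModulation = stratumModulation,
              landmarkJitterSD = landmarkJitterSD,
              rotationRange = rotationRange, scaleRange = scaleRange,
              translationRange = translationRange,
              intensityNoiseSD = intensityNoiseSD, seed = as.integer(seed))
  class(cfg) <- "SyntheticCohortConfig"
  stopifnot(all(cfg$groupSizes >= 0), landmarkJitterSD >= 0,
            intensityNoiseSD >= 0, all(scaleRange > 0),
            scaleRange[1] <= scaleRange[2],
            nrow(stratumModulation) == nrow(geometricEffects))
  cfg
}

## Run expr with a private RNG stream, restoring the caller's state
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

.randomSimilarity <- function(cfg, canvas = c(256, 256)) {
  th <- stats::runif(1, -cfg$rotationRange, cfg$rotationRange) * pi / 180
  s <- stats::runif(1, cfg$scaleRange[1], cfg$scaleRange[2])
  t <- stats::runif(2, -cfg$translationRange, cfg$translationRange)
  ctr <- canvas / 2
  function(pts) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    sweep(s * sweep(pts, 2, ctr) %*% t(R), 2, ctr + t, "+")
  }
}

.jitterTransformTemplate <- function(cfg, pts) {
  pts <- pts + matrix(stats::rnorm(length(pts), 0, cfg$landmarkJitterSD),
                      nrow(pts), 2)
  .randomSimilarity(cfg)(pts)
}

.stampPattern <- function(img, center, pattern, contrast, frame, size = 6) {
  h <- nrow(img); w <- ncol(img)
  r <- ceiling(3 * size)
  xr <- max(0, floor(center[1] - r)):min(w - 1, ceiling(center[1] + r))
  yr <- max(0, floor(center[2] - r)):min(h - 1, ceiling(center[2] + r))
  if (!length(xr) || !length(yr)) return(img)
  gx <- matrix(rep(xr, each = length(yr)), length(yr))
  gy <- matrix(rep(yr, times = length(xr)), length(yr))
  du <- (gx - center[1]) * frame$xaxis[1] + (gy - center[2]) * frame$xaxis[2]
  dv <- (gx - center[1]) * frame$yaxis[1] + (gy - center[2]) * frame$yaxis[2]
  win <- exp(-(du^2 + dv^2) / (2 * size^2))
  tex <- switch(pattern,
                stripes = sin(2 * pi * du / 4),
                spots = cos(2 * pi * du / 5) * cos(2 * pi * dv / 5),
                stop("unknown texture pattern: ", pattern))
  img[yr + 1, xr + 1] <- img[yr + 1, xr + 1] + contrast * tex * win
  img
}

## ---- calibration ----------------------------------------------------------

.CAL_SEED <- 104729L
.calCache <- new.env(parent = emptyenv())

## Landmark-space calibration: per planted geometric feature, the noise SD
## under jitter + random transform and the px-offset -> feature slope at the
## template; offsets realizing the configured standardized effects follow.
## Deterministic (fixed internal seed) and memoized on the config fields it
## depends on, so repeated cohort generation does not repeat the Monte Carlo.
.calibrateGeometric <- function(cfg, catalog = defaultMetricCatalog(),
                                nCal = 2000) {
  key <- paste(utils::capture.output(str(list(
    cfg$geometricEffects, cfg$landmarkJitterSD, cfg$rotationRange,
    cfg$scaleRange, cfg$translationRange, nCal))), collapse = "|")
  if (!is.null(.calCache[[key]])) return(.calCache[[key]])
  defs <- metricDefs(catalog)
  tpl <- .templatePoints()
  pairs <- defaultLandmarkScheme()$pairs
  eff <- cfg$geometricEffects
  feat <- paste0("geom.", eff$metric, ".sym")
  base <- extractGeometricFeatures(LandmarkSet("t", tpl), catalog)
  missing <- setdiff(eff$metric, defs$name)
  if (length(missing))
    stop("planted metric(s) not in catalog: ", paste(missing, collapse = ", "))
  sds <- .withSeed(.CAL_SEED, {
    sims <- vapply(seq_len(nCal), function(i) {
      p <- .jitterTransformTemplate(cfg, tpl)
      extractGeometricFeatures(LandmarkSet("c", p), catalog)[feat]
    }, numeric(length(feat)))
    if (length(feat) == 1L) stats::sd(sims) else apply(sims, 1, stats::sd)
  })
  ## Jacobian J[j, k] = d(feature_k) / d(offset_j): planted effects can
  ## cross-talk (they share landmarks), so the offsets realizing the target
  ## mean differences are obtained by solving the full linear system rather
  ## than assuming one effect per feature.
  hstep <- 4
  J <- t(vapply(seq_len(nrow(eff)), function(j) {
    def <- defs[defs$name == eff$metric[j], ]
    fp <- extractGeometricFeatures(
      LandmarkSet("p", .applyGeomEffect(tpl, def, hstep, pairs)),
      catalog)[feat]
    fm <- extractGeometricFeatures(
      LandmarkSet("m", .applyGeomEffect(tpl, def, -hstep, pairs)),
      catalog)[feat]
    (fp - fm) / (2 * hstep)
  }, numeric(length(feat))))
  if (abs(det(J)) < 1e-20)
    stop("degenerate offset->feature response during calibration")
  targets <- eff$effect * as.numeric(sds)
  offsetPx <- as.numeric(solve(t(J), targets))
  out <- list(features = feat, sd = as.numeric(sds),
              slope = diag(as.matrix(J)), jacobian = J,
              offsetPx = offsetPx)
  .calCache[[key]] <- out
  out
}

## Image-space calibration of the texture channel: class-conditional rates
## of every comparison bit at the stamped landmarks, estimated on rendered
## subjects with no geometric effects. Bits whose rates differ by >= 0.25
## are listed as planted lbp features.
.calibrateTexture <- function(cfg, nTex = 60, texCfg = TexturePatchConfig()) {
  te <- cfg$textureEffects
  if (is.null(te) || nrow(te) == 0)
    return(list(features = character(), rates = NULL))
  key <- paste(utils::capture.output(str(list(
    te, cfg$landmarkJitterSD, cfg$rotationRange, cfg$scaleRange,
    cfg$translationRange, cfg$intensityNoiseSD, nTex))), collapse = "|")
  if (!is.null(.calCache[[key]])) return(.calCache[[key]])
  tpl <- .templatePoints()
  bitNames <- as.vector(vapply(te$landmark, function(lm)
    paste0("lbp.", lm, ".R", rep(1:3, each = 8), ".b", rep(0:7, 3)),
    character(24)))
  sampleBits <- function(stamped) {
    vapply(seq_len(nTex), function(i) {
      pts <- .jitterTransformTemplate(cfg, tpl)
      ls <- LandmarkSet("c", pts)
      img <- renderFace(ls)
      if (stamped) {
        fr <- faceFrame(ls)
        for (j in seq_len(nrow(te)))
          img <- .stampPattern(img, pts[te$landmark[j], ], te$pattern[j],
                               te$contrast[j], fr)
      }
      img <- img + matrix(stats::rnorm(length(img), 0, cfg$intensityNoiseSD),
                          nrow(img))
      img <- pmin(pmax(img, 0), 255)
      landmarkDescriptor(img, ls, texCfg)[bitNames]
    }, numeric(length(bitNames)))
  }
  rates <- .withSeed(.CAL_SEED + 1L, {
    b0 <- sampleBits(FALSE)   # NS (unstamped)
    b1 <- sampleBits(TRUE)    # WBS (stamped)
    cbind(p0 = rowMeans(b0), p1 = rowMeans(b1))
  })
  keep <- abs(rates[, "p1"] - rates[, "p0"]) >= 0.25
  out <- list(features = bitNames[keep], rates = rates[keep, , drop = FALSE])
  .calCache[[key]] <- out
  out
}

## Bayes accuracy of the planted model under the independent-channel
## approximation: the geometric channel is Gaussian with per-stratum
## Mahalanobis separation Delta_s, the texture channel Bernoulli with the
## calibrated rates; accuracy of the likelihood-ratio rule by Monte Carlo.
.bayesAccuracy <- function(cfg, texRates, nMC = 4000) {
  strata <- colnames(cfg$groupSizes)
  d <- cfg$geometricEffects$effect
  wS <- colSums(cfg$groupSizes)
  accS <- .withSeed(.CAL_SEED + 2L, vapply(strata, function(s) {
    ds <- d * cfg$stratumModulation[, s]
    Delta <- sqrt(sum(ds^2))
    llrG1 <- stats::rnorm(nMC, Delta^2 / 2, Delta)    # WBS samples
    llrG0 <- stats::rnorm(nMC, -Delta^2 / 2, Delta)   # NS samples
    if (!is.null(texRates) && nrow(texRates)) {
      p0 <- pmin(pmax(texRates[, "p0"], 0.02), 0.98)
      p1 <- pmin(pmax(texRates[, "p1"], 0.02), 0.98)
      lOn <- log(p1 / p0); lOff <- log((1 - p1) / (1 - p0))
      for (j in seq_along(p0)) {
        b1 <- stats::rbinom(nMC, 1, p1[j])
        b0 <- stats::rbinom(nMC, 1, p0[j])
        llrG1 <- llrG1 + ifelse(b1 == 1, lOn[j], lOff[j])
        llrG0 <- llrG0 + ifelse(b0 == 1, lOn[j], lOff[j])
      }
    }
    (mean(llrG1 > 0) + mean(llrG0 < 0)) / 2
  }, numeric(1)))
  list(byStratum = accS, overall = sum(accS * wS) / sum(wS))
}

## ---- subject and cohort generation ----------------------------------------

#' Generate one synthetic subject
#'
#' Starting from the template, the planted geometric effects of the
#' subject's class (scaled by its stratum's modulation) displace landmarks;
#' independent Gaussian jitter and a random similarity transform follow; the
#' face is re-rendered from the deformed landmarks; WBS subjects receive the
#' configured local texture stamps; Gaussian intensity noise is added.
#' Consumes the current RNG stream (seed it for reproducibility).
#'
#' @param cfg a \code{\link{SyntheticCohortConfig}}.
#' @param diagnosis \code{"NS"} or \code{"WBS"}.
#' @param ethnicity one of the configured strata.
#' @param calibration precomputed geometric calibration (internal; computed
#'   on the fly when NULL).
#' @param render render the image (default TRUE; landmarks only when FALSE).
#' @return list with \code{image}, \code{landmarks}, \code{metadata}.
#' @export
generateSubject <- function(cfg, diagnosis = c("NS", "WBS"),
                            ethnicity = "Caucasian", calibration = NULL,
                            render = TRUE) {
  diagnosis <- match.arg(diagnosis)
  if (is.null(calibration)) calibration <- .calibrateGeometric(cfg)
  catalog <- defaultMetricCatalog()
  defs <- metricDefs(catalog)
  pairs <- defaultLandmarkScheme()$pairs
  pts <- .templatePoints()
  clsSign <- if (diagnosis == "WBS") 1 else -1
  eff <- cfg$geometricEffects
  for (j in seq_len(nrow(eff))) {
    mod <- cfg$stratumModulation[j, ethnicity]
    delta <- clsSign * calibration$offsetPx[j] * mod / 2
    if (delta != 0)
      pts <- .applyGeomEffect(pts, defs[defs$name == eff$metric[j], ],
                              delta, pairs)
  }
  pts <- .jitterTransformTemplate(cfg, pts)
  ls <- LandmarkSet("subject", pts)
  img <- NULL
  if (render) {
    img <- renderFace(ls)
    te <- cfg$textureEffects
    if (diagnosis == "WBS" && !is.null(te) && nrow(te)) {
      fr <- faceFrame(ls)
      for (j in seq_len(nrow(te)))
        img <- .stampPattern(img, pts[te$landmark[j], ], te$pattern[j],
                             te$contrast[j], fr)
    }
    if (cfg$intensityNoiseSD > 0)
      img <- img + matrix(stats::rnorm(length(img), 0,
                                       cfg$intensityNoiseSD), nrow(img))
    img <- pmin(pmax(img, 0), 255)
  }
  list(image = img, landmarks = ls,
       metadata = data.frame(diagnosis = diagnosis, ethnicity = ethnicity,
                             stringsAsFactors = FALSE))
}

## Age-group and sex sampling probabilities per diagnosis (study cohort
## composition)
.ageGroups <- c("infant", "toddler", "child", "adolescent", "adult")
.agePropNS <- c(45, 29, 47, 18, 22) / 161
.agePropWBS <- c(49, 47, 71, 28, 91) / 286
.sexPropNS <- c(M = 93, F = 68) / 161
.sexPropWBS <- c(M = 150, F = 136) / 286

#' Generate a full synthetic cohort
#'
#' Generates every subject of the configured (diagnosis x ethnicity) cells,
#' after calibrating the landmark offsets that realize the configured
#' standardized effect sizes (a one-off Monte-Carlo calibration with a
#' fixed internal seed, so the planted ground truth is identical across
#' cohort seeds). The ground truth lists the planted \code{geom.*} features
#' (with their per-stratum standardized effect sizes), the planted
#' \code{lbp.*} bit features (with their calibrated class-conditional
#' rates), and the Bayes accuracy of the planted model.
#'
#' @param cfg a \code{\link{SyntheticCohortConfig}}.
#' @param renderImages render face images (default TRUE; set FALSE for fast
#'   landmark/geometry-only cohorts).
#' @return a \linkS4class{SyntheticCohort}.
#' @export
generateCohort <- function(cfg = SyntheticCohortConfig(),
                           renderImages = TRUE) {
  calG <- .calibrateGeometric(cfg)
  calT <- if (renderImages) .calibrateTexture(cfg)
          else list(features = character(), rates = NULL)
  bayes <- .bayesAccuracy(cfg, calT$rates)
  effSizes <- outer(cfg$geometricEffects$effect,
                    rep(1, ncol(cfg$stratumModulation))) *
    cfg$stratumModulation
  dimnames(effSizes) <- list(calG$features, colnames(cfg$stratumModulation))
  ## pooled standardized effect over strata: the class-mean gap shrinks by
  ## the stratum-weighted modulation and the within-class SD inflates by the
  ## between-stratum spread of the planted means
  wS <- colSums(cfg$groupSizes) / sum(cfg$groupSizes)
  pooledG <- vapply(seq_len(nrow(effSizes)), function(j) {
    ds <- effSizes[j, ]
    dbar <- sum(wS * ds)
    dbar / sqrt(1 + sum(wS * ((ds - dbar) / 2)^2))
  }, numeric(1))
  names(pooledG) <- calG$features
  pooledT <- if (!is.null(calT$rates) && nrow(calT$rates)) {
    pbar <- (calT$rates[, "p0"] + calT$rates[, "p1"]) / 2
    stats::setNames((calT$rates[, "p1"] - calT$rates[, "p0"]) /
                      sqrt(pmax(pbar * (1 - pbar), 1e-6)), calT$features)
  } else numeric(0)
  gt <- list(features = c(calG$features, calT$features),
             pooledEffectSizes = c(pooledG, pooledT),
             geometricFeatures = calG$features,
             lbpFeatures = calT$features,
             effectSizes = effSizes,
             lbpRates = calT$rates,
             offsetPx = stats::setNames(calG$offsetPx, calG$features),
             noiseSD = stats::setNames(calG$sd, calG$features),
             bayesAccuracy = bayes$overall,
             bayesByStratum = bayes$byStratum)
  images <- list(); landmarks <- list(); meta <- list()
  .withSeed(cfg$seed, {
    for (s in colnames(cfg$groupSizes)) {
      for (cl in rownames(cfg$groupSizes)) {
        nCell <- cfg$groupSizes[cl, s]
        for (i in seq_len(nCell)) {
          id <- sprintf("%s_%s_%03d", cl, s, i)
          sub <- generateSubject(cfg, cl, s, calibration = calG,
                                 render = renderImages)
          sub$landmarks@subjectID <- id
          landmarks[[id]] <- sub$landmarks
          if (renderImages) images[[id]] <- sub$image
          ageP <- if (cl == "NS") .agePropNS else .agePropWBS
          sexP <- if (cl == "NS") .sexPropNS else .sexPropWBS
          meta[[id]] <- data.frame(
            subject_id = id, diagnosis = cl, ethnicity = s,
            age_group = sample(.ageGroups, 1, prob = ageP),
            sex = sample(names(sexP), 1, prob = sexP),
            stringsAsFactors = FALSE)
        }
      }
    }
  })
  new("SyntheticCohort", images = images, landmarks = landmarks,
      metadata = do.call(rbind, c(meta, list(make.row.names = FALSE))),
      groundTruth = gt, config = unclass(cfg))
}

#' Write a synthetic cohort to a dataset directory
#'
#' Lays out the directory the extraction pipeline consumes: one ASCII PGM
#' image and one landmark CSV per subject (file name = subject id),
#' \code{metadata.csv}, and \code{ground_truth.json}.
#'
#' @param cohort a \linkS4class{SyntheticCohort}.
#' @param dir destination directory (created if needed).
#' @return invisibly, \code{dir}.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "images"), showWarnings = FALSE)
  dir.create(file.path(dir, "landmarks"), showWarnings = FALSE)
  for (id in names(cohort@landmarks)) {
    writeLandmarks(cohort@landmarks[[id]],
                   file.path(dir, "landmarks", paste0(id, ".csv")))
    if (length(cohort@images))
      writePgm(cohort@images[[id]],
               file.path(dir, "images", paste0(id, ".pgm")))
  }
  utils::write.csv(cohort@metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE, quote = FALSE)
  gt <- cohort@groundTruth
  gt$effectSizes <- as.data.frame(gt$effectSizes)
  gt$lbpRates <- if (!is.null(gt$lbpRates)) as.data.frame(gt$lbpRates)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
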