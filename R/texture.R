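#' @include AllClasses.R landmarks.R
NULL

#' Construct a TexturePatchConfig
#'
#' @param blockSizes three increasing odd patch sizes (pixels at a 200-px
#'   inter-tragion reference face). Default \code{c(3, 5, 9)}.
#' @param comparisonRule \code{"ge"} (default) or \code{"gt"}.
#' @param representation \code{"bits"} (default) or \code{"histogram"}.
#' @param scaleNormalize rescale block sizes by inter-tragion distance / 200
#'   (default TRUE).
#' @return a validated \linkS4class{TexturePatchConfig}.
#' @export
TexturePatchConfig <- function(blockSizes = c(3, 5, 9),
                               comparisonRule = c("ge", "gt"),
                               representation = c("bits", "histogram"),
                               scaleNormalize = TRUE) {
  new("TexturePatchConfig", blockSizes = as.numeric(blockSizes),
      comparisonRule = match.arg(comparisonRule),
      representation = match.arg(representation),
      scaleNormalize = isTRUE(scaleNormalize))
}

#' Convert an image to a grayscale intensity grid
#'
#' RGB input (an H x W x 3 array) is reduced with the ITU-R BT.601 luminance
#' weights Y = 0.299 R + 0.587 G + 0.114 B; grayscale input (an H x W
#' matrix) passes through unchanged. Intensities are expected on the 0-255
#' scale and are returned as doubles.
#'
#' @param image numeric matrix (grayscale) or H x W x 3 array (RGB).
#' @return numeric matrix of intensities.
#' @export
toGrayscale <- function(image) {
  if (length(image) == 0)
    stop("empty image")
  if (is.matrix(image)) {
    storage.mode(image) <- "double"
    return(image)
  }
  if (length(dim(image)) == 3L && dim(image)[3] == 3L) {
    out <- 0.299 * image[, , 1] + 0.587 * image[, , 2] +
      0.114 * image[, , 3]
    if (!is.matrix(out)) out <- matrix(out, dim(image)[1], dim(image)[2])
    return(out)
  }
  stop("image must be a matrix or an H x W x 3 array")
}

## Clamp 0-based pixel indices to the image and return the replicated range
.clampIdx <- function(idx, n) pmin(pmax(idx, 0L), n - 1L) + 1L

#' Mean intensities of a 3x3 tiling of square patches
#'
#' Nine mean intensities of the \code{blockSize} x \code{blockSize} patches
#' tiled 3 x 3 and centered on \code{center} (0-based pixel coordinates,
#' x = column, y = row). Pixels outside the image are handled by edge
#' replication. Returned as a 3 x 3 matrix in image orientation (row 1 = the
#' top tiles), with the central patch at \code{[2, 2]}.
#'
#' @param image grayscale matrix (rows = y).
#' @param center numeric \code{c(x, y)}, 0-based; must lie inside the image.
#' @param blockSize odd patch side length in pixels.
#' @return 3 x 3 numeric matrix of patch means.
#' @export
blockMeans <- function(image, center, blockSize) {
  h <- nrow(image); w <- ncol(image)
  cx <- round(center[1]); cy <- round(center[2])
  if (cx < 0 || cx > w - 1 || cy < 0 || cy > h - 1)
    stop("landmark out of image bounds at (", center[1], ", ", center[2], ")")
  half <- (blockSize - 1L) / 2L
  out <- matrix(0, 3, 3)
  for (j in -1:1) {      # tile row (y)
    for (i in -1:1) {    # tile column (x)
      xs <- .clampIdx(seq(cx + i * blockSize - half,
                          cx + i * blockSize + half), w)
      ys <- .clampIdx(seq(cy + j * blockSize - half,
                          cy + j * blockSize + half), h)
      out[j + 2, i + 2] <- mean(image[ys, xs])
    }
  }
  out
}

#' Multi-scale block LBP code from a 3x3 grid of patch means
#'
#' The eight neighbor patches are enumerated clockwise from the top-left
#' tile; bit i (i = 0..7) is 1 iff neighbor_i compares true against the
#' central patch under the rule (\code{ge}: >=, \code{gt}: >), and the code
#' is the big-endian byte sum(bit_i * 2^(7 - i)).
#'
#' @param grid 3 x 3 numeric matrix (image orientation) of patch means.
#' @param rule \code{"ge"} or \code{"gt"}.
#' @return list with \code{code} (0..255) and \code{bits} (integer vector
#'   of length 8).
#' @export
#' @examples
#' g <- matrix(10, 3, 3); g[1, 1] <- 11
#' mblbpCode(g, "ge")$code
mblbpCode <- function(grid, rule = c("ge", "gt")) {
  rule <- match.arg(rule)
  if (!all(is.finite(grid)))
    stop("non-finite patch means")
  ## clockwise from top-left: TL, T, TR, R, BR, B, BL, L as (row, col)
  ord <- rbind(c(1, 1), c(1, 2), c(1, 3), c(2, 3),
               c(3, 3), c(3, 2), c(3, 1), c(2, 1))
  ctr <- grid[2, 2]
  nb <- grid[ord]
  bits <- if (rule == "ge") as.integer(nb >= ctr) else as.integer(nb > ctr)
  list(code = sum(bits * 2L^(7:0)), bits = bits)
}

## Effective (odd, >=3) block sizes for a subject
.effectiveBlocks <- function(cfg, ls) {
  b <- cfg@blockSizes
  if (cfg@scaleNormalize) {
    d <- referenceLengths(ls)[["horizontal_ref"]]
    b <- b * d / 200
  }
  b <- 2 * floor(b / 2) + 1
  pmax(b, 3)
}

#' Multi-resolution block-LBP descriptor around the inner landmarks
#'
#' For each of the 33 inner landmarks and each of the three resolutions the
#' local appearance is coded by comparing the mean intensity of the central
#' patch against its eight neighbors. In \code{bits} mode the descriptor is
#' the 8 comparison bits per landmark per resolution (33 x 3 x 8 = 792
#' features named \code{lbp.<landmark>.R<k>.b<i>}); in \code{histogram} mode
#' it is the normalized 256-bin histogram of codes computed at every pixel
#' of a (3 * blockSize)^2 window around the landmark
#' (\code{lbp.<landmark>.R<k>.h<j>}).
#'
#' @param image grayscale matrix or RGB array (see
#'   \code{\link{toGrayscale}}).
#' @param ls a \linkS4class{LandmarkSet}; all inner landmarks must lie
#'   inside the image.
#' @param cfg a \linkS4class{TexturePatchConfig}.
#' @return named numeric vector of \code{lbp.*} features.
#' @export
landmarkDescriptor <- function(image, ls, cfg = TexturePatchConfig()) {
  img <- toGrayscale(image)
  blocks <- .effectiveBlocks(cfg, ls)
  inner <- innerLandmarks(ls)
  pts <- landmarkPoints(ls)[inner, , drop = FALSE]
  h <- nrow(img); w <- ncol(img)
  oob <- pts[, 1] < 0 | pts[, 1] > w - 1 | pts[, 2] < 0 | pts[, 2] > h - 1
  if (any(oob))
    stop("inner landmark(s) out of image bounds: ",
         paste(inner[oob], collapse = ", "))
  out <- numeric(0)
  for (li in seq_along(inner)) {
    for (k in 1:3) {
      b <- blocks[k]
      if (cfg@representation == "bits") {
        bits <- mblbpCode(blockMeans(img, pts[li, ], b),
                          cfg@comparisonRule)$bits
        nms <- paste0("lbp.", inner[li], ".R", k, ".b", 0:7)
        out[nms] <- bits
      } else {
        win <- (3 * b - 1) / 2
        cx <- round(pts[li, 1]); cy <- round(pts[li, 2])
        counts <- integer(256)
        for (y in (cy - win):(cy + win)) {
          for (x in (cx - win):(cx + win)) {
            xx <- min(max(x, 0), w - 1); yy <- min(max(y, 0), h - 1)
            code <- mblbpCode(blockMeans(img, c(xx, yy), b),
                              cfg@comparisonRule)$code
            counts[code + 1L] <- counts[code + 1L] + 1L
          }
        }
        nms <- paste0("lbp.", inner[li], ".R", k, ".h", 0:255)
        out[nms] <- counts / sum(counts)
      }
    }
  }
  out
}
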