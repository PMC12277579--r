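## Raster convention: a grayscale image is a numeric height x width matrix,
## an RGB image a height x width x 3 array, intensities in [0, 255].
## Row 1 is the top of the image; (row, col) indices are 1-based.

.assert_raster <- function(image, what = "image") {
  if (is.matrix(image)) return("gray")
  if (is.array(image) && length(dim(image)) == 3L && dim(image)[3L] == 3L)
    return("rgb")
  stop(what, " must be a numeric matrix (gray) or height x width x 3 array (RGB)")
}

#' Halve image resolution by bilinear interpolation
#'
#' Replaces every non-overlapping 2x2 pixel window by a single pixel whose
#' channel intensities are the bilinear interpolation of the window at its
#' midpoint, which reduces to the per-channel mean of the four pixels.
#' Output dimensions are \code{floor(dim/2)}; a trailing odd row/column is
#' dropped. Values are rounded half-up to integers in [0, 255].
#'
#' @param image grayscale matrix or RGB array, intensities in [0, 255].
#' @return raster of the same kind with halved width and height.
#' @examples
#' m <- matrix(c(10, 30, 20, 40), 2, 2)
#' downsampleBilinear(m)  # single pixel, value 25
#' @export
downsampleBilinear <- function(image) {
  kind <- .assert_raster(image)
  h <- dim(image)[1L]; w <- dim(image)[2L]
  if (h < 2L || w < 2L)
    stop("image must be at least 2x2 pixels to downsample")
  h2 <- h %/% 2L; w2 <- w %/% 2L
  ri <- seq.int(1L, by = 2L, length.out = h2)
  ci <- seq.int(1L, by = 2L, length.out = w2)
  half <- function(m) {
    s <- m[ri, ci, drop = FALSE] + m[ri + 1L, ci, drop = FALSE] +
         m[ri, ci + 1L, drop = FALSE] + m[ri + 1L, ci + 1L, drop = FALSE]
    floor(s / 4 + 0.5)  # round half-up for cross-platform determinism
  }
  if (kind == "gray") return(half(image))
  out <- array(0, dim = c(h2, w2, 3L))
  for (ch in 1:3) out[, , ch] <- half(image[, , ch])
  out
}

.gaussian_kernel1d <- function(kernel, sigma) {
  half <- (kernel - 1L) / 2L
  x <- seq(-half, half)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

## reflective (mirror, edge not repeated) index vector of length n + 2*pad
.reflect_idx <- function(n, pad) {
  if (n == 1L) return(rep(1L, n + 2L * pad))
  core <- seq_len(n)
  left <- rev(seq_len(pad) + 1L)         # 2, 3, ... reflected
  right <- n - seq_len(pad)              # n-1, n-2, ...
  idx <- c(left, core, right)
  idx[idx < 1L] <- 1L; idx[idx > n] <- n
  idx
}

.convolve_sep <- function(m, k) {
  pad <- (length(k) - 1L) / 2L
  h <- nrow(m); w <- ncol(m)
  # rows
  mp <- m[.reflect_idx(h, pad), , drop = FALSE]
  out <- matrix(0, h, w)
  for (i in seq_along(k))
    out <- out + k[i] * mp[seq_len(h) + (i - 1L), , drop = FALSE]
  # cols
  mp <- out[, .reflect_idx(w, pad), drop = FALSE]
  out <- matrix(0, h, w)
  for (i in seq_along(k))
    out <- out + k[i] * mp[, seq_len(w) + (i - 1L), drop = FALSE]
  out
}

#' Gaussian smoothing
#'
#' Per-channel convolution with a normalized, separable Gaussian kernel;
#' borders are handled by mirror reflection, so constant images are mapped
#' to themselves exactly.
#'
#' @param image grayscale matrix or RGB array.
#' @param kernel odd kernel width in pixels (default 5).
#' @param sigma Gaussian standard deviation in pixels; by default derived
#'   from the kernel size as \code{0.3 * ((kernel - 1) / 2 - 1) + 0.8}.
#' @return smoothed raster of the same kind and dimensions (not rounded).
#' @export
gaussianSmooth <- function(image, kernel = 5L,
                           sigma = 0.3 * ((kernel - 1) / 2 - 1) + 0.8) {
  kind <- .assert_raster(image)
  kernel <- as.integer(kernel)
  if (kernel < 1L || kernel %% 2L == 0L)
    stop("kernel size must be an odd integer >= 1")
  if (sigma <= 0) stop("sigma must be positive")
  if (kernel == 1L) return(image)
  k <- .gaussian_kernel1d(kernel, sigma)
  if (kind == "gray") return(.convolve_sep(image, k))
  out <- image
  for (ch in 1:3) out[, , ch] <- .convolve_sep(image[, , ch], k)
  out
}

#' Convert an RGB raster to HSV
#'
#' Standard RGB to HSV transform (via \code{grDevices::rgb2hsv}); the three
#' channels of the result hold hue, saturation and value, each rescaled to
#' [0, 255] (hue: 0-255 spans the full 0-360 degree circle). Separating
#' grains from a white paper background is much easier in HSV: paper has
#' near-zero saturation while grains saturate strongly.
#'
#' @param image RGB array, intensities in [0, 255].
#' @return array of the same dimensions with channels (hue, saturation,
#'   value) in [0, 255].
#' @export
rgbToHsv <- function(image) {
  if (.assert_raster(image) != "rgb")
    stop("rgbToHsv requires a 3-channel RGB image")
  d <- dim(image)
  hsv <- grDevices::rgb2hsv(r = as.vector(image[, , 1L]),
                            g = as.vector(image[, , 2L]),
                            b = as.vector(image[, , 3L]),
                            maxColorValue = 255)
  out <- array(0, dim = d)
  out[, , 1L] <- hsv[1L, ] * 255
  out[, , 2L] <- hsv[2L, ] * 255
  out[, , 3L] <- hsv[3L, ] * 255
  out
}

#' Mean-shift color smoothing
#'
#' Edge-preserving piecewise flattening of color regions: each pixel is
#' iteratively replaced by the mean position/color of the pixels inside the
#' joint spatial-color window (spatial radius \code{spatialRadius}, color
#' radius \code{colorRadius} in Euclidean channel distance) until the shift
#' converges or \code{maxIter} is reached. Flat regions are fixed points;
#' regions whose colors differ by much more than \code{colorRadius} never
#' mix.
#'
#' @param image RGB (or generally 3-channel) array.
#' @param spatialRadius spatial window radius in pixels (default 10).
#' @param colorRadius color window radius in intensity units (default 20).
#' @param maxIter maximum mean-shift iterations per pixel (default 5).
#' @return smoothed 3-channel array of the same dimensions.
#' @export
meanshiftSmooth <- function(image, spatialRadius = 10, colorRadius = 20,
                            maxIter = 5L) {
  if (.assert_raster(image) != "rgb")
    stop("meanshiftSmooth requires a 3-channel image")
  if (spatialRadius <= 0 || colorRadius <= 0)
    stop("spatialRadius and colorRadius must be positive")
  d <- dim(image)
  out <- meanshift_filter_cpp(image[, , 1L], image[, , 2L], image[, , 3L],
                              as.integer(spatialRadius), colorRadius,
                              as.integer(maxIter))
  res <- array(0, dim = d)
  res[, , 1L] <- out[[1L]]; res[, , 2L] <- out[[2L]]; res[, , 3L] <- out[[3L]]
  res
}

#' Otsu binarization
#'
#' Thresholds a grayscale image at the level maximizing the between-class
#' variance of its 256-bin histogram, and returns a binary mask in which
#' the grain side is foreground. Which side is the grain side depends on
#' the grayscale feature: grains are \emph{bright} in the saturation
#' channel (white paper has saturation ~0) but \emph{dark} in the value or
#' luma channel.
#'
#' @param image grayscale matrix, intensities in [0, 255].
#' @param foreground \code{"bright"} if grains are the above-threshold
#'   class, \code{"dark"} if below (default \code{"bright"}, matching the
#'   saturation channel used by \code{\link{preprocessPipeline}}).
#' @return integer matrix of 0 (background) / 1 (grain) with an attribute
#'   \code{threshold} holding the Otsu level.
#' @export
binarizeOtsu <- function(image, foreground = c("bright", "dark")) {
  if (.assert_raster(image) != "gray")
    stop("binarizeOtsu requires a grayscale image")
  foreground <- match.arg(foreground)
  v <- image[is.finite(image)]
  if (max(v) - min(v) < .Machine$double.eps * 255)
    stop("constant image: no Otsu threshold exists")
  # between-class variance scan over the 256-bin integer histogram;
  # threshold t splits at (value > t), ties resolved to the lowest t
  h <- tabulate(pmin(pmax(as.integer(round(v)), 0L), 255L) + 1L,
                nbins = 256L)
  n <- sum(h)
  lev <- 0:255
  w0 <- cumsum(h)
  m0 <- cumsum(h * lev)
  mu_t <- m0[256L] / n
  w1 <- n - w0
  bcv <- ifelse(w0 > 0L & w1 > 0L,
                (mu_t * w0 - m0)^2 / (as.numeric(w0) * as.numeric(w1)), -1)
  thr <- lev[which.max(bcv)]
  mask <- if (foreground == "bright") image > thr else image <= thr
  mask <- matrix(as.integer(mask), nrow(image), ncol(image))
  attr(mask, "threshold") <- thr
  mask
}

#' Preprocessing configuration
#'
#' Bundles the tunable preprocessing parameters. Defaults follow the
#' pipeline's working choices: 2x downsampling, a 5x5 Gaussian, mean-shift
#' smoothing with spatial radius 10 px and color radius 20, Otsu on the
#' saturation channel, and suppression of connected components smaller
#' than 30 px.
#'
#' @param downsampleFactor 1 (no downsampling) or 2.
#' @param gaussianKernel odd Gaussian kernel width (pixels).
#' @param gaussianSigma Gaussian sigma; \code{NULL} derives it from the
#'   kernel size.
#' @param meanshiftSpatialRadius,meanshiftColorRadius mean-shift window
#'   radii.
#' @param grayChannel which scalar feeds Otsu: \code{"saturation"}
#'   (default) or \code{"value"} of the mean-shifted HSV image, or
#'   \code{"luma"} (0.299R + 0.587G + 0.114B of the Gaussian-smoothed RGB
#'   image).
#' @param minComponentArea connected components smaller than this (pixels,
#'   post-downsampling) are discarded as noise.
#' @param crfRadius disk radius R of the corner response function.
#' @param crfThreshold CRF corner cutoff.
#' @param maxSegments largest segment count for which the exact partition
#'   search is attempted; beyond it the cp estimate is used.
#' @param lambda weight of the center-dispersion penalty in the partition
#'   error.
#' @param minGrainArea smallest plausible grain (ellipse) area in pixels;
#'   partition subsets fitting smaller ellipses are rejected.
#' @return a named list of class \code{grainConfig}.
#' @export
grainConfig <- function(downsampleFactor = 2L, gaussianKernel = 5L,
                        gaussianSigma = NULL, meanshiftSpatialRadius = 10,
                        meanshiftColorRadius = 20,
                        grayChannel = c("saturation", "value", "luma"),
                        minComponentArea = 30, crfRadius = 7L,
                        crfThreshold = 0.6, maxSegments = 10L, lambda = 1,
                        minGrainArea = 30) {
  grayChannel <- match.arg(grayChannel)
  if (!downsampleFactor %in% c(1L, 2L))
    stop("downsampleFactor must be 1 or 2")
  if (gaussianKernel %% 2L == 0L) stop("gaussianKernel must be odd")
  structure(list(downsampleFactor = as.integer(downsampleFactor),
                 gaussianKernel = as.integer(gaussianKernel),
                 gaussianSigma = gaussianSigma,
                 meanshiftSpatialRadius = meanshiftSpatialRadius,
                 meanshiftColorRadius = meanshiftColorRadius,
                 grayChannel = grayChannel,
                 minComponentArea = minComponentArea,
                 crfRadius = as.integer(crfRadius),
                 crfThreshold = crfThreshold,
                 maxSegments = as.integer(maxSegments),
                 lambda = lambda, minGrainArea = minGrainArea),
            class = "grainConfig")
}

.drop_small_components <- function(mask, minArea) {
  lab <- .label_components(mask)
  if (max(lab) == 0L) return(mask)
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= minArea)
  matrix(as.integer(lab %in% keep), nrow(mask), ncol(mask))
}

## connected-component labeling via EBImage (transpose: EBImage is x,y)
.label_components <- function(mask) {
  lab <- EBImage::bwlabel(t(mask))
  matrix(as.integer(t(EBImage::imageData(lab))), nrow(mask), ncol(mask))
}

#' Full preprocessing pipeline: photograph to grain mask
#'
#' Chains the preprocessing stages: bilinear 2x downsampling, Gaussian
#' smoothing, HSV conversion, mean-shift smoothing, extraction of the
#' configured grayscale channel, Otsu binarization with grain polarity,
#' and suppression of sub-threshold components.
#'
#' @param image RGB array, intensities in [0, 255].
#' @param config a \code{\link{grainConfig}}.
#' @return binary mask (integer matrix, 1 = grain) with attributes
#'   \code{downsampled} (the downsampled RGB image, for overlays) and
#'   \code{threshold} (the Otsu level).
#' @export
preprocessPipeline <- function(image, config = grainConfig()) {
  if (.assert_raster(image) != "rgb")
    stop("preprocessPipeline requires an RGB image")
  img <- image
  if (config$downsampleFactor == 2L) img <- downsampleBilinear(img)
  down <- img
  sigma <- config$gaussianSigma
  img <- if (is.null(sigma)) gaussianSmooth(img, config$gaussianKernel)
         else gaussianSmooth(img, config$gaussianKernel, sigma)
  hsv <- rgbToHsv(img)
  hsv <- meanshiftSmooth(hsv, config$meanshiftSpatialRadius,
                         config$meanshiftColorRadius)
  gray <- switch(config$grayChannel,
    saturation = hsv[, , 2L],
    value = hsv[, , 3L],
    luma = 0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L])
  polarity <- if (config$grayChannel == "saturation") "bright" else "dark"
  mask <- binarizeOtsu(gray, foreground = polarity)
  thr <- attr(mask, "threshold")
  mask <- .drop_small_components(mask, config$minComponentArea)
  attr(mask, "downsampled") <- down
  attr(mask, "threshold") <- thr
  mask
}
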