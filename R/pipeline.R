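#' Read an image file as an RGB raster
#'
#' Reads a PNG/JPEG/TIFF image via EBImage and returns it in the package's
#' raster convention: a \code{height x width x 3} array with intensities
#' in [0, 255]. Grayscale files are replicated across the three channels.
#'
#' @param path image file path.
#' @return RGB array.
#' @export
readImageRGB <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  im <- EBImage::readImage(path)
  dat <- EBImage::imageData(im)
  if (length(dim(dat)) == 2L) dat <- array(rep(dat, 3L), c(dim(dat), 3L))
  if (dim(dat)[3L] > 3L) dat <- dat[, , 1:3]  # drop alpha
  out <- array(0, dim = c(dim(dat)[2L], dim(dat)[1L], 3L))
  for (ch in 1:3) out[, , ch] <- t(dat[, , ch]) * 255
  out
}

#' Write a binary mask as a PNG
#'
#' @param mask integer/logical matrix.
#' @param path output PNG path.
#' @return the path, invisibly.
#' @export
writeMaskPNG <- function(mask, path) {
  EBImage::writeImage(EBImage::Image(t(mask != 0L) * 1), path)
  invisible(path)
}

#' Count grains in an image or synthetic scene
#'
#' The end-to-end pipeline: preprocessing and binarization, contour
#' extraction, per-contour corner detection and ellipse-partition counting
#' (cpe), with the corner-count estimate (cp) and a watershed count as
#' baselines. Contours whose segment count exceeds the search limit fall
#' back, flagged, to the cp estimate.
#'
#' @param x a file path, an RGB array (\code{height x width x 3}, [0, 255]),
#'   or a \linkS4class{GrainScene}.
#' @param config a \code{\link{grainConfig}}.
#' @return a \linkS4class{GrainCountResult}.
#' @examples
#' sc <- generateScene(4, imageSize = c(700, 500), seed = 3)
#' res <- runPipeline(sc)
#' grainCount(res)
#' @export
runPipeline <- function(x, config = grainConfig()) {
  image <- if (is(x, "GrainScene")) sceneImage(x)
           else if (is.character(x)) readImageRGB(x)
           else x
  .assert_raster(image, "input")
  mask <- preprocessPipeline(image, config)
  contours <- extractContours(mask, minArea = config$minComponentArea)
  labels <- attr(contours, "labels")
  n <- length(contours)
  rows <- vector("list", n)
  ell <- vector("list", n); assign <- vector("list", n)
  for (i in seq_len(n)) {
    res <- countGrainsCpe(contours[[i]], labels, config)
    rows[[i]] <- data.frame(contour_id = i, area = contours[[i]]@area,
                            n_corners = res$n_corners,
                            n_segments = res$n_segments,
                            count_cp = res$count_cp,
                            count_cpe = res$count_cpe,
                            fallback_used = res$fallback)
    ell[[i]] <- if (!is.null(res$partition)) res$partition@fits else list()
    assign[[i]] <- res$assignment
  }
  perContour <- if (n) do.call(rbind, rows) else
    data.frame(contour_id = integer(0), area = numeric(0),
               n_corners = integer(0), n_segments = integer(0),
               count_cp = integer(0), count_cpe = integer(0),
               fallback_used = logical(0))
  totals <- c(n_contours = n,
              count_cp = sum(perContour$count_cp),
              count_cpe = sum(perContour$count_cpe),
              count_watershed = countWatershed(
                mask, minArea = config$minComponentArea))
  new("GrainCountResult", perContour = perContour, ellipses = ell,
      assignments = assign, contours = contours, totals = totals,
      mask = .strip_attrs(mask))
}

.strip_attrs <- function(mask) {
  matrix(as.integer(mask), nrow(mask), ncol(mask))
}

#' Accuracy row for one image (Table-style report)
#'
#' One CSV-ready row comparing the pipeline's counts against a known true
#' count: cp, cpe and watershed counts with their CR accuracies.
#'
#' @param result a \linkS4class{GrainCountResult}.
#' @param nTrue true grain count.
#' @param imageId identifier for the image/scene.
#' @return one-row data.frame with columns \code{image_id}, \code{n_true},
#'   \code{n_cp}, \code{n_cpe}, \code{n_watershed}, \code{cr_cp},
#'   \code{cr_cpe}, \code{cr_w}.
#' @export
accuracyRow <- function(result, nTrue, imageId = "image") {
  t <- result@totals
  data.frame(image_id = imageId, n_true = nTrue,
             n_cp = t[["count_cp"]], n_cpe = t[["count_cpe"]],
             n_watershed = t[["count_watershed"]],
             cr_cp = countAccuracy(t[["count_cp"]], nTrue)$cr,
             cr_cpe = countAccuracy(t[["count_cpe"]], nTrue)$cr,
             cr_w = countAccuracy(t[["count_watershed"]], nTrue)$cr)
}

#' Write a JSON counting report
#'
#' Per-contour results (corner/segment counts, cp/cpe estimates, fallback
#' flags, fitted ellipse parameters) plus image totals, as JSON.
#' Coordinates are 1-based (row, col).
#'
#' @param result a \linkS4class{GrainCountResult}.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
writeCountReport <- function(result, path) {
  per <- result@perContour
  contours <- lapply(seq_len(nrow(per)), function(i) {
    fits <- result@ellipses[[i]]
    list(contour_id = i,
         n_corners = per$n_corners[i], n_segments = per$n_segments[i],
         count_cp = per$count_cp[i], count_cpe = per$count_cpe[i],
         fallback_used = per$fallback_used[i],
         ellipses = lapply(Filter(Negate(is.null), fits), function(f)
           list(center = f@center, axes = f@semiAxes, angle = f@angle)),
         segment_assignment = result@assignments[[i]])
  })
  jsonlite::write_json(list(totals = as.list(result@totals),
                            contours = contours),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Render a per-grain overlay PNG
#'
#' Colors every contour pixel by its assigned grain and marks detected
#' corner regions, over the (downsampled) input image if available.
#'
#' @param result a \linkS4class{GrainCountResult}.
#' @param image RGB array to draw on (e.g. the \code{downsampled}
#'   attribute of the mask); \code{NULL} draws on the mask itself.
#' @param path output PNG path.
#' @return the path, invisibly.
#' @export
renderOverlay <- function(result, image = NULL, path) {
  mask <- result@mask
  h <- nrow(mask); w <- ncol(mask)
  if (is.null(image)) {
    image <- array(0, c(h, w, 3L))
    for (ch in 1:3) image[, , ch] <- (mask != 0L) * 220
  }
  img <- image / 255
  pal <- grDevices::col2rgb(grDevices::rainbow(12)) / 255
  for (i in seq_along(result@contours)) {
    p <- result@contours[[i]]@points
    asg <- result@assignments[[i]]
    colix <- (asg * 5L + i) %% 12L + 1L
    for (ch in 1:3)
      img[cbind(p[, 1L], p[, 2L], ch)] <- pal[ch, colix]
  }
  EBImage::writeImage(
    EBImage::Image(aperm(img, c(2L, 1L, 3L)), colormode = "Color"), path)
  invisible(path)
}
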