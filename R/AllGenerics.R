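#' Accessors for grainsplit classes
#'
#' Small accessor generics: \code{grainCount} returns the number of grains
#' implied by an object (subset count of a partition, cpe total of a result,
#' true count of a synthetic scene); \code{contourPoints} the (row, col)
#' coordinate matrix of a contour; \code{cornerIndices} the detected corner
#' positions; \code{crfValues} the corner-response profile values;
#' \code{residual} and \code{isValidEllipse} the fit diagnostics;
#' \code{sceneImage} and \code{sceneLabels} the rendered synthetic image and
#' its ground-truth label matrix; \code{trueCount} the ground-truth grain
#' count.
#'
#' @param x an object of the appropriate grainsplit class.
#' @return See the individual description; scalars, vectors or matrices.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("grainCount", function(x) standardGeneric("grainCount"))

#' @rdname accessors
#' @export
setGeneric("contourPoints", function(x) standardGeneric("contourPoints"))

#' @rdname accessors
#' @export
setGeneric("cornerIndices", function(x) standardGeneric("cornerIndices"))

#' @rdname accessors
#' @export
setGeneric("crfValues", function(x) standardGeneric("crfValues"))

#' @rdname accessors
#' @export
setGeneric("residual", function(x) standardGeneric("residual"))

#' @rdname accessors
#' @export
setGeneric("isValidEllipse", function(x) standardGeneric("isValidEllipse"))

#' @rdname accessors
#' @export
setGeneric("sceneImage", function(x) standardGeneric("sceneImage"))

#' @rdname accessors
#' @export
setGeneric("sceneLabels", function(x) standardGeneric("sceneLabels"))

#' @rdname accessors
#' @export
setGeneric("trueCount", function(x) standardGeneric("trueCount"))

#' @rdname accessors
#' @export
setMethod("grainCount", "GrainPartition", function(x) x@grainCount)

#' @rdname accessors
#' @export
setMethod("grainCount", "GrainCountResult",
          function(x) as.integer(x@totals[["count_cpe"]]))

#' @rdname accessors
#' @export
setMethod("grainCount", "GrainScene", function(x) x@trueCount)

#' @rdname accessors
#' @export
setMethod("contourPoints", "GrainContour", function(x) x@points)

#' @rdname accessors
#' @export
setMethod("cornerIndices", "CornerSet", function(x) x@indices)

#' @rdname accessors
#' @export
setMethod("crfValues", "CRFProfile", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("crfValues", "CornerSet", function(x) x@profile@values)

#' @rdname accessors
#' @export
setMethod("residual", "EllipseFit", function(x) x@residual)

#' @rdname accessors
#' @export
setMethod("isValidEllipse", "EllipseFit", function(x) x@isValidEllipse)

#' @rdname accessors
#' @export
setMethod("sceneImage", "GrainScene", function(x) x@image)

#' @rdname accessors
#' @export
setMethod("sceneLabels", "GrainScene", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("trueCount", "GrainScene", function(x) x@trueCount)

setMethod("show", "GrainContour", function(object) {
  cat("GrainContour:", nrow(object@points), "boundary points, region area",
      object@area, "px (label", object@label, ")\n")
})

setMethod("show", "CornerSet", function(object) {
  cat("CornerSet:", length(object@indices), "corner(s) at CRF >",
      object@threshold, "(R =", object@profile@radius, ")\n")
  if (length(object@indices))
    cat("  indices:", paste(object@indices, collapse = ", "), "\n")
})

setMethod("show", "EllipseFit", function(object) {
  if (object@isValidEllipse) {
    cat(sprintf(
      "EllipseFit: center (%.2f, %.2f), semi-axes (%.2f, %.2f), angle %.1f deg\n",
      object@center[1L], object@center[2L], object@semiAxes[1L],
      object@semiAxes[2L], object@angle * 180 / pi))
    cat(sprintf("  %d points, algebraic residual %.3g\n",
                object@nPoints, object@residual))
  } else {
    cat("EllipseFit: degenerate (not a real ellipse),", object@nPoints,
        "points\n")
  }
})

setMethod("show", "GrainPartition", function(object) {
  cat("GrainPartition:", object@grainCount, "grain(s), total error",
      format(object@totalError, digits = 4), "\n")
  for (i in seq_along(object@subsets))
    cat("  grain", i, "<- segments",
        paste(object@subsets[[i]], collapse = ", "), "\n")
})

setMethod("show", "GrainScene", function(object) {
  d <- dim(object@image)
  cat("GrainScene:", object@trueCount, "grains,", d[2L], "x", d[1L],
      "px, seed", object@seed, "\n")
  cat(" ", nrow(object@adjacency), "touching pair(s),",
      sum(object@grains$chipped), "chipped grain(s)\n")
})

setMethod("show", "GrainCountResult", function(object) {
  t <- object@totals
  cat("GrainCountResult:", t[["n_contours"]], "contour(s)\n")
  cat("  counts: cp =", t[["count_cp"]], " cpe =", t[["count_cpe"]],
      " watershed =", t[["count_watershed"]], "\n")
  nf <- sum(object@perContour$fallback_used)
  if (nf) cat(" ", nf, "contour(s) fell back to the cp estimate\n")
})
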