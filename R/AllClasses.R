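#' @import methods
NULL

#' GrainContour: closed boundary of one connected grain region
#'
#' Ordered, closed sequence of boundary pixel coordinates for one connected
#' foreground component of a binary mask. Consecutive points (and the
#' last/first pair) are 8-connected neighbors; coordinates are 1-based
#' \code{(row, col)} with the image origin at the top-left.
#'
#' @slot points integer matrix, one row per boundary pixel, columns
#'   \code{row} and \code{col}.
#' @slot label integer, the connected-component label of the region this
#'   contour bounds (index into the label image it came from).
#' @slot area numeric, area of the bounded region in pixels.
#'
#' @export
setClass("GrainContour",
  representation(points = "matrix", label = "integer", area = "numeric"),
  validity = function(object) {
    p <- object@points
    if (!is.numeric(p) || ncol(p) != 2L) return("points must be an n x 2 matrix")
    if (nrow(p) < 1L) return("contour must contain at least one point")
    n <- nrow(p)
    nxt <- c(2:n, 1L)[seq_len(n)]
    if (n > 1L) {
      d <- pmax(abs(p[, 1L] - p[nxt, 1L]), abs(p[, 2L] - p[nxt, 2L]))
      if (any(d > 1L)) return("consecutive contour points must be 8-connected")
      if (any(d == 0L)) return("duplicate consecutive contour points")
    }
    TRUE
  })

#' CRFProfile: corner response values along a contour
#'
#' Per-point values of the corner response function (CRF): the fraction of
#' the radius-R raster disk centered at each contour pixel that is occupied
#' by foreground pixels of the bounded region. Values lie in [0, 1];
#' approximately 0.5 on straight boundary stretches and above 0.6 at concave
#' notches where two grains touch.
#'
#' @slot values numeric vector, one CRF value per contour point.
#' @slot radius numeric, disk radius R in pixels.
#'
#' @export
setClass("CRFProfile",
  representation(values = "numeric", radius = "numeric"),
  validity = function(object) {
    if (length(object@radius) != 1L || object@radius < 1)
      return("radius must be a single value >= 1")
    v <- object@values
    if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
      return("CRF values must be finite and within [0, 1]")
    TRUE
  })

#' CornerSet: detected corner points on a contour
#'
#' One representative contour index per maximal run of consecutive points
#' whose CRF exceeds the threshold (runs wrap around the contour end).
#'
#' @slot indices integer vector, strictly increasing indices into the
#'   contour's point list.
#' @slot threshold numeric, the CRF cutoff used (default 0.6).
#' @slot profile the \linkS4class{CRFProfile} the corners were detected on.
#'
#' @export
setClass("CornerSet",
  representation(indices = "integer", threshold = "numeric",
                 profile = "CRFProfile"),
  validity = function(object) {
    idx <- object@indices
    if (length(idx) && any(diff(idx) <= 0L))
      return("corner indices must be strictly increasing")
    if (length(idx) && length(object@profile@values) &&
        (any(idx < 1L) || any(idx > length(object@profile@values))))
      return("corner indices out of contour range")
    TRUE
  })

#' EllipseFit: least-squares conic fit to a pixel set
#'
#' Result of fitting the conic
#' \eqn{a_{11}x^2 + 2a_{12}xy + a_{22}y^2 + 2b_1x + 2b_2y + 1 = 0}
#' to a set of pixel coordinates by SVD least squares. The conic is an
#' ellipse iff \eqn{a_{11}a_{22} - a_{12}^2 > 0} and both axis lengths are
#' positive.
#'
#' @slot coefficients named numeric of length 5: \code{a11, a12, a22, b1, b2}
#'   (in original, un-conditioned image coordinates).
#' @slot center numeric length 2, ellipse center \code{(x, y)} in pixels
#'   (\code{x} = column direction, \code{y} = row direction); \code{NA} if
#'   degenerate.
#' @slot semiAxes numeric length 2, \code{(major, minor)} semi-axis lengths
#'   in pixels.
#' @slot angle numeric, orientation of the major axis in radians in
#'   \eqn{[0, \pi)}.
#' @slot residual numeric, squared norm of the algebraic residual
#'   \eqn{\lVert D\alpha + 1\rVert^2} in conditioned (centered/scaled)
#'   coordinates.
#' @slot nPoints integer, number of distinct points fitted.
#' @slot isValidEllipse logical, whether the conic is a real ellipse.
#'
#' @export
setClass("EllipseFit",
  representation(coefficients = "numeric", center = "numeric",
                 semiAxes = "numeric", angle = "numeric",
                 residual = "numeric", nPoints = "integer",
                 isValidEllipse = "logical"),
  validity = function(object) {
    if (length(object@coefficients) != 5L)
      return("coefficients must have length 5")
    if (object@residual < 0) return("residual must be non-negative")
    if (isTRUE(object@isValidEllipse)) {
      ax <- object@semiAxes
      if (any(!is.finite(ax)) || any(ax <= 0) || ax[2L] > ax[1L])
        return("valid ellipse requires 0 < minor <= major")
    }
    TRUE
  })

#' GrainPartition: optimal grouping of contour segments into grains
#'
#' A partition of a contour's inter-corner segments into disjoint subsets,
#' each subset representing the boundary arcs of one grain, together with
#' the per-subset ellipse fits and the total partitioning error that was
#' minimized. The grain count is the number of subsets.
#'
#' @slot subsets list of integer vectors; disjoint, jointly exhaustive
#'   segment indices.
#' @slot fits list of \linkS4class{EllipseFit}, one per subset (fit to the
#'   pooled pixels of the subset's segments).
#' @slot totalError numeric, value of the minimized partition error.
#' @slot grainCount integer, \code{length(subsets)}.
#'
#' @export
setClass("GrainPartition",
  representation(subsets = "list", fits = "list", totalError = "numeric",
                 grainCount = "integer"),
  validity = function(object) {
    k <- length(object@subsets)
    if (object@grainCount != k) return("grainCount must equal number of subsets")
    if (length(object@fits) != k) return("one fit per subset required")
    all_idx <- sort(unlist(object@subsets))
    if (length(all_idx) && !identical(all_idx, seq_len(max(all_idx))))
      return("subsets must partition the segment indices 1..k")
    TRUE
  })

#' GrainScene: synthetic grain scene with ground truth
#'
#' A rendered synthetic photograph of elliptical grains on a white
#' background, together with complete ground truth: per-grain ellipse
#' parameters, a per-grain label image, the true count, and the adjacency
#' (touching) pairs. Scenes are bit-reproducible from their seed.
#'
#' @slot image numeric array \code{height x width x 3}, RGB in [0, 255].
#' @slot grains data.frame with one row per grain: center (\code{cx},
#'   \code{cy}, in pixel units, x = column), semi-axes (\code{a}, \code{b}),
#'   orientation \code{theta} (radians), base color (\code{r}, \code{g},
#'   \code{bcol}), and \code{chipped} flag.
#' @slot labels integer matrix \code{height x width}; 0 = background,
#'   i = pixel of grain i.
#' @slot trueCount integer, number of grains.
#' @slot adjacency integer matrix with two columns; each row a touching
#'   pair of grain indices.
#' @slot seed integer, the RNG seed the scene was generated from.
#'
#' @export
setClass("GrainScene",
  representation(image = "array", grains = "data.frame", labels = "matrix",
                 trueCount = "integer", adjacency = "matrix",
                 seed = "integer"),
  validity = function(object) {
    if (length(dim(object@image)) != 3L || dim(object@image)[3L] != 3L)
      return("image must be height x width x 3")
    if (!identical(dim(object@image)[1:2], dim(object@labels)))
      return("labels must match image dimensions")
    if (object@trueCount != nrow(object@grains))
      return("trueCount must equal number of grains")
    TRUE
  })

#' GrainCountResult: per-image grain counting report
#'
#' Full result of running the counting pipeline on one image: per-contour
#' corner counts, cp and cpe estimates, fitted ellipses, and image totals.
#'
#' @slot perContour data.frame with one row per analyzed contour:
#'   \code{contour_id}, \code{area}, \code{n_corners}, \code{n_segments},
#'   \code{count_cp}, \code{count_cpe}, \code{fallback_used}.
#' @slot ellipses list (one element per contour) of lists of
#'   \linkS4class{EllipseFit} for the winning partition.
#' @slot assignments list (one element per contour) of integer vectors
#'   assigning every contour point to a grain subset.
#' @slot contours list of \linkS4class{GrainContour}.
#' @slot totals named numeric: \code{n_contours}, \code{count_cp},
#'   \code{count_cpe}, \code{count_watershed}.
#' @slot mask the binary mask (integer matrix) the counts were computed on.
#'
#' @export
setClass("GrainCountResult",
  representation(perContour = "data.frame", ellipses = "list",
                 assignments = "list", contours = "list",
                 totals = "numeric", mask = "matrix"))
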