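#' Extract closed grain-region contours from a binary mask
#'
#' Labels the connected foreground components of the mask, discards those
#' below \code{minArea}, and traces one closed outer boundary contour per
#' surviving component (holes are ignored). Contours are ordered sequences
#' of 8-connected boundary pixels with a consistent traversal orientation
#' (counterclockwise in image coordinates, rows increasing downward).
#'
#' @param mask integer/logical matrix, nonzero = foreground.
#' @param minArea minimum component area in pixels (default 30).
#' @return list of \linkS4class{GrainContour}; empty list for an empty mask.
#' @export
extractContours <- function(mask, minArea = 30) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  m <- matrix(as.integer(mask != 0L), nrow(mask), ncol(mask))
  lab <- .label_components(m)
  nlab <- max(lab)
  if (nlab == 0L) return(list())
  areas <- tabulate(lab[lab > 0L], nbins = nlab)
  keep <- which(areas >= minArea)
  if (!length(keep)) return(list())
  # relabel so contour j corresponds to label j in the filtered label image
  relab <- integer(nlab); relab[keep] <- seq_along(keep)
  lab2 <- matrix(ifelse(lab > 0L, relab[pmax(lab, 1L)], 0L),
                 nrow(lab), ncol(lab))
  oc <- EBImage::ocontour(EBImage::Image(t(lab2)))
  out <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    p <- oc[[j]]
    # EBImage returns 0-based (x, y); we feed it the transposed mask, so
    # x is the original column and y the original row
    pts <- cbind(row = p[, 2L] + 1L, col = p[, 1L] + 1L)
    pts <- .clean_contour(pts)
    pts <- .orient_ccw(pts)
    out[[j]] <- new("GrainContour", points = pts, label = j,
                    area = as.numeric(areas[keep[j]]))
  }
  attr(out, "labels") <- lab2
  out
}

## drop duplicate consecutive points and a duplicated closing point
.clean_contour <- function(pts) {
  n <- nrow(pts)
  if (n > 1L) {
    dup <- c(FALSE, pts[-1L, 1L] == pts[-n, 1L] & pts[-1L, 2L] == pts[-n, 2L])
    pts <- pts[!dup, , drop = FALSE]
    n <- nrow(pts)
    if (n > 1L && all(pts[1L, ] == pts[n, ])) pts <- pts[-n, , drop = FALSE]
  }
  pts
}

## normalize traversal so the shoelace signed area (x = col, y = row) is >= 0
.orient_ccw <- function(pts) {
  n <- nrow(pts)
  if (n < 3L) return(pts)
  x <- pts[, 2L]; y <- pts[, 1L]
  nxt <- c(2:n, 1L)
  s <- sum(x * y[nxt] - x[nxt] * y)
  if (s < 0) pts[rev(seq_len(n)), , drop = FALSE] else pts
}

## integer offsets of the raster disk of radius R (Euclidean, pixel centers)
.disk_offsets <- function(R) {
  r <- as.integer(R)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g <- g[g$dr^2 + g$dc^2 <= R^2, , drop = FALSE]
  as.matrix(g)
}

.region_membership <- function(mask, label) {
  if (max(mask) <= 1L) mask > 0L else mask == label
}

#' Corner response function along a contour
#'
#' For every contour pixel \code{p}, CRF(p) = np / A, where A is the number
#' of raster pixels whose centers lie within Euclidean distance R of
#' \code{p}, and np the number of those pixels that are foreground pixels
#' of the region this contour bounds. Near the image border the disk is
#' clipped and only in-bounds pixels are counted. CRF is about 0.5 on a
#' straight boundary, below 0.5 on convex corners, and rises above 0.6 in
#' the concave notch where two touching grains meet.
#'
#' @param contour a \linkS4class{GrainContour}.
#' @param mask binary mask (0/1) or the component label matrix from
#'   \code{\link{extractContours}} (attribute \code{labels}); with a label
#'   matrix only pixels of this contour's own region are counted.
#' @param radius disk radius R in pixels (default 7).
#' @return a \linkS4class{CRFProfile}.
#' @export
crfProfile <- function(contour, mask, radius = 7L) {
  if (radius < 1) stop("radius must be >= 1")
  p <- contour@points
  fg <- .region_membership(mask, contour@label)
  off <- .disk_offsets(radius)
  h <- nrow(mask); w <- ncol(mask); n <- nrow(p)
  np <- numeric(n); A <- numeric(n)
  for (k in seq_len(nrow(off))) {
    r <- p[, 1L] + off[k, 1L]
    c <- p[, 2L] + off[k, 2L]
    ok <- r >= 1L & r <= h & c >= 1L & c <= w
    A <- A + ok
    idx <- (c[ok] - 1L) * h + r[ok]
    np[ok] <- np[ok] + fg[idx]
  }
  new("CRFProfile", values = unname(np / A), radius = as.numeric(radius))
}

#' Corner response at a single contour point
#'
#' Convenience scalar form of \code{\link{crfProfile}}.
#'
#' @inheritParams crfProfile
#' @param index index of the contour point to evaluate.
#' @return CRF value in [0, 1].
#' @export
cornerResponse <- function(contour, mask, index, radius = 7L) {
  if (index < 1L || index > nrow(contour@points))
    stop("index outside the contour")
  p <- contour@points[index, , drop = FALSE]
  sub <- new("GrainContour", points = p, label = contour@label,
             area = contour@area)
  unname(crfProfile(sub, mask, radius)@values)
}

#' Detect concave corner points on a contour
#'
#' Computes the CRF profile, takes the maximal runs of consecutive contour
#' points with CRF above the threshold (runs wrap around the contour end),
#' and emits one representative per run: the point of maximum CRF within
#' the run, ties broken by the lowest contour index.
#'
#' @inheritParams crfProfile
#' @param threshold CRF cutoff in (0, 1); default 0.6.
#' @return a \linkS4class{CornerSet} (possibly with zero corners).
#' @export
detectCorners <- function(contour, mask, radius = 7L, threshold = 0.6) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  prof <- crfProfile(contour, mask, radius)
  v <- prof@values
  above <- v > threshold
  n <- length(v)
  idx <- integer(0)
  if (any(above)) {
    if (all(above)) {
      runs <- list(seq_len(n))
    } else {
      # rotate so position 1 is below threshold, then take rle runs
      start <- which(!above)[1L]
      rot <- c(start:n, seq_len(start - 1L))
      ab <- above[rot]
      r <- rle(ab)
      ends <- cumsum(r$lengths)
      begins <- ends - r$lengths + 1L
      runs <- lapply(which(r$values), function(i) rot[begins[i]:ends[i]])
    }
    idx <- vapply(runs, function(run) run[which.max(v[run])], integer(1))
    idx <- sort(idx)
  }
  new("CornerSet", indices = as.integer(idx), threshold = threshold,
      profile = prof)
}

#' Split a contour into inter-corner segments
#'
#' With k detected corners the contour splits into exactly k segments, each
#' the open arc between two cyclically consecutive corner representatives
#' (the corner points themselves belong to no segment). With zero corners
#' the whole contour is a single segment.
#'
#' @param contour a \linkS4class{GrainContour}.
#' @param corners a \linkS4class{CornerSet}.
#' @return list of integer vectors of contour point indices (a segment may
#'   be empty when two corners are adjacent); attribute \code{bounds} holds
#'   the (start corner, end corner) pair of each segment.
#' @export
splitSegments <- function(contour, corners) {
  n <- nrow(contour@points)
  ci <- corners@indices
  k <- length(ci)
  if (k == 0L) {
    segs <- list(seq_len(n))
    attr(segs, "bounds") <- matrix(NA_integer_, 1L, 2L)
    return(segs)
  }
  segs <- vector("list", k)
  bounds <- matrix(0L, k, 2L)
  for (i in seq_len(k)) {
    a <- ci[i]
    b <- if (i < k) ci[i + 1L] else ci[1L]
    bounds[i, ] <- c(a, b)
    if (i < k) {
      segs[[i]] <- if (b - a > 1L) seq.int(a + 1L, b - 1L) else integer(0)
    } else {
      # wraparound arc from the last corner past the end to the first
      segs[[i]] <- c(if (a < n) seq.int(a + 1L, n) else integer(0),
                     if (b > 1L) seq.int(1L, b - 1L) else integer(0))
    }
  }
  attr(segs, "bounds") <- bounds
  segs
}

#' Corner-point grain count estimate (cp)
#'
#' Estimates the number of grains in a compound contour from the corner
#' count alone: \code{Ngrains = Ncorners / 2 - Rclosed + 1}, floored at 1.
#' Each grain-grain contact contributes a pair of concave corners, so an
#' odd corner count (possible with raster noise) is rounded up to the next
#' even number with a warning.
#'
#' @param nCorners number of detected corner points (>= 0).
#' @param rClosed number of degenerate closed boundary segments (see
#'   vignette; 0 in typical scenes).
#' @return integer grain count >= 1.
#' @export
estimateCountCp <- function(nCorners, rClosed = 0L) {
  if (nCorners < 0L || rClosed < 0L) stop("counts must be non-negative")
  if (nCorners %% 2L == 1L) {
    warning("odd corner count ", nCorners, "; rounding up to ", nCorners + 1L)
    nCorners <- nCorners + 1L
  }
  max(1L, as.integer(nCorners / 2L - rClosed + 1L))
}

## degenerate closed-segment count: a segment whose two bounding corners are
## the same corner (only possible with exactly one detected corner)
.r_closed <- function(corners) {
  as.integer(length(corners@indices) == 1L)
}
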