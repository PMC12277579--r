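## Partitioning of inter-corner contour segments into grains.
##
## A candidate grouping of segments is scored by the total partitioning
## error: per-subset algebraic fit residual (normalized by pixel count)
## plus a center-dispersion penalty. Physically impossible groupings are
## rejected (infinite error): a subset is invalid when its pooled pixels
## are too few to determine a conic, when the fitted conic is not a real
## ellipse, when the fitted ellipse is smaller than a plausible grain, or
## when the ellipse center does not lie inside the grain region; a
## partition is additionally invalid when the ellipses of two of its
## subsets substantially interpenetrate (grains are solid: they can touch,
## but cannot co-occupy area -- this is what merges arcs split by a
## spurious corner, whose separate fits land on nearly the same ellipse,
## and what rejects phantom ellipses fitted to short contact-zone arcs).

#' Enumerate all set partitions of k elements
#'
#' Restricted-growth-string enumeration in a fixed deterministic order;
#' the number of partitions is the Bell number of k.
#'
#' @param k number of elements (>= 1).
#' @return list of integer assignment vectors of length k; blocks are
#'   numbered by first appearance.
#' @export
setPartitions <- function(k) {
  stopifnot(k >= 1L)
  parts <- list(1L)
  if (k == 1L) return(parts)
  for (i in 2:k) {
    nxt <- vector("list", 0L)
    for (p in parts) {
      m <- max(p)
      nxt <- c(nxt, lapply(seq_len(m + 1L), function(b) c(p, b)))
    }
    parts <- nxt
  }
  parts
}

## Evaluate one subset (pooled union of segments). Returns list with
## error (residual/n + lambda * dispersion/B), center, minor axis, fit,
## valid flag. segPixels: list of per-segment (x, y) matrices.
.eval_subset <- function(segIdx, segPixels, lambda, minGrainArea, inRegion) {
  pool <- do.call(rbind, segPixels[segIdx])
  if (is.null(pool) || nrow(unique(pool)) < 5L)
    return(list(valid = FALSE))
  fit <- fitConicLSQ(pool)
  if (!fit@isValidEllipse) return(list(valid = FALSE))
  ax <- fit@semiAxes
  if (pi * ax[1L] * ax[2L] < minGrainArea) return(list(valid = FALSE))
  if (!is.null(inRegion) && !inRegion(fit@center)) return(list(valid = FALSE))
  n <- fit@nPoints
  # center dispersion over per-segment fits (short/degenerate arcs add 0)
  ds <- numeric(0)
  minors <- ax[2L]
  if (length(segIdx) > 1L) {
    for (s in segIdx) {
      ps <- segPixels[[s]]
      if (is.null(ps) || nrow(unique(ps)) < 5L) next
      fs <- fitConicLSQ(ps)
      if (!fs@isValidEllipse) next
      ds <- c(ds, sqrt(sum((fs@center - fit@center)^2)))
      minors <- c(minors, fs@semiAxes[2L])
    }
  }
  B <- min(minors)
  disp <- if (length(ds)) mean(ds) else 0
  list(valid = TRUE, error = fit@residual / n + lambda * disp / B,
       center = fit@center, minor = ax[2L], fit = fit)
}

#' Total partitioning error of a segment grouping
#'
#' Scores a partition of contour segments into grain subsets: the sum over
#' subsets of the pooled ellipse-fit residual (normalized by the subset's
#' pixel count) plus \code{lambda} times the subset's center dispersion --
#' the mean distance between the pooled ellipse center and the centers of
#' ellipses fitted to each constituent segment alone -- normalized by B,
#' the smallest semi-minor axis among the subset's fits. Returns \code{Inf}
#' for physically invalid partitions (see \code{\link{bestPartition}}).
#'
#' @param subsets list of integer vectors partitioning the segment indices.
#' @param segPixels list of per-segment pixel coordinate matrices (x, y).
#' @param lambda penalty weight (default 1).
#' @param minGrainArea smallest plausible grain area in pixels (default 30).
#' @param inRegion optional function taking an (x, y) center and returning
#'   whether it lies inside the contour's foreground region.
#' @return list with \code{total} (numeric, may be \code{Inf}) and
#'   \code{fits} (per-subset \linkS4class{EllipseFit}, or \code{NULL} for
#'   invalid subsets).
#' @export
partitionError <- function(subsets, segPixels, lambda = 1,
                           minGrainArea = 30, inRegion = NULL) {
  evals <- lapply(subsets, .eval_subset, segPixels = segPixels,
                  lambda = lambda, minGrainArea = minGrainArea,
                  inRegion = inRegion)
  fits <- lapply(evals, function(e) if (isTRUE(e$valid)) e$fit else NULL)
  if (any(!vapply(evals, function(e) isTRUE(e$valid), logical(1))))
    return(list(total = Inf, fits = fits))
  if (!.subsets_disjoint(evals)) return(list(total = Inf, fits = fits))
  list(total = sum(vapply(evals, `[[`, numeric(1), "error")), fits = fits)
}

## max tolerated interpenetration: fraction of the smaller ellipse's area
## inside the larger. Touching grains overlap by a sliver (a few percent);
## phantom or duplicated ellipses overlap by most of their area.
.overlap_limit <- 0.4

.subsets_disjoint <- function(evals, pairCache = NULL) {
  k <- length(evals)
  if (k < 2L) return(TRUE)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    ov <- NULL
    if (!is.null(pairCache)) {
      pkey <- paste(sort(c(evals[[i]]$key, evals[[j]]$key)), collapse = "|")
      ov <- pairCache[[pkey]]
    }
    if (is.null(ov)) {
      ov <- .ellipse_overlap_frac(evals[[i]]$fit, evals[[j]]$fit)
      if (!is.null(pairCache)) pairCache[[pkey]] <- ov
    }
    if (ov > .overlap_limit) return(FALSE)
  }
  TRUE
}

#' Optimal grouping of contour segments into grains
#'
#' Enumerates every set partition of the k segments (Bell-number
#' enumeration in a fixed order), scores each with
#' \code{\link{partitionError}}, and returns the minimizer; ties are broken
#' by fewer subsets, then enumeration order. The winning subset count is
#' the grain count.
#'
#' @param segPixels list of per-segment pixel coordinate matrices (x, y).
#' @param maxSegments largest k for which the exact search runs (default
#'   10; Bell(10) = 115975 candidate partitions). Larger k is an error so
#'   callers can fall back to the corner-count estimate.
#' @inheritParams partitionError
#' @return a \linkS4class{GrainPartition}.
#' @export
bestPartition <- function(segPixels, maxSegments = 10L, lambda = 1,
                          minGrainArea = 30, inRegion = NULL) {
  k <- length(segPixels)
  if (k < 1L) stop("no segments to partition")
  if (k > maxSegments)
    stop("contour too complex: ", k, " segments exceeds maxSegments = ",
         maxSegments)
  cache <- new.env(parent = emptyenv())
  subset_eval <- function(idx) {
    key <- paste(idx, collapse = ",")
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    e <- .eval_subset(idx, segPixels, lambda, minGrainArea, inRegion)
    e$key <- key
    cache[[key]] <- e
    e
  }
  pairCache <- new.env(parent = emptyenv())
  best <- NULL; bestErr <- Inf; bestK <- Inf
  for (assign in setPartitions(k)) {
    blocks <- split(seq_len(k), assign)
    evals <- lapply(blocks, subset_eval)
    if (any(!vapply(evals, function(e) isTRUE(e$valid), logical(1)))) next
    if (!.subsets_disjoint(evals, pairCache)) next
    err <- sum(vapply(evals, `[[`, numeric(1), "error"))
    nb <- length(blocks)
    if (err < bestErr || (err == bestErr && nb < bestK)) {
      bestErr <- err; bestK <- nb
      best <- list(blocks = blocks, evals = evals)
    }
  }
  if (is.null(best))
    stop("no valid partition: every grouping violates the ellipse ",
         "constraints (region too small or degenerate)")
  new("GrainPartition",
      subsets = unname(lapply(best$blocks, as.integer)),
      fits = unname(lapply(best$evals, `[[`, "fit")),
      totalError = bestErr, grainCount = length(best$blocks))
}

#' Count the grains bounded by one contour (cpe algorithm)
#'
#' The full per-contour counting procedure: detect concave corners, split
#' the contour into inter-corner segments, and search for the segment
#' partition best approximated by ellipses. A contour with no corners is a
#' single grain and short-circuits the search. A contour with more than
#' \code{maxSegments} segments falls back to the corner-count estimate
#' (flagged in the result).
#'
#' @param contour a \linkS4class{GrainContour}.
#' @param mask binary mask or label matrix (see \code{\link{crfProfile}}).
#' @param config a \code{\link{grainConfig}}.
#' @return list with elements \code{count_cpe}, \code{count_cp},
#'   \code{n_corners}, \code{n_segments}, \code{fallback} (logical),
#'   \code{partition} (\linkS4class{GrainPartition} or \code{NULL}),
#'   \code{corners} (\linkS4class{CornerSet}), and \code{assignment}
#'   (integer subset id per contour point; 0 for unassignable points).
#' @export
countGrainsCpe <- function(contour, mask, config = grainConfig()) {
  corners <- detectCorners(contour, mask, radius = config$crfRadius,
                           threshold = config$crfThreshold)
  nC <- length(corners@indices)
  rcl <- .r_closed(corners)
  cp <- suppressWarnings(estimateCountCp(nC, rcl))
  n <- nrow(contour@points)
  pts_xy <- cbind(x = contour@points[, 2L], y = contour@points[, 1L])
  base <- list(count_cp = cp, n_corners = nC, corners = corners)

  if (nC == 0L) {
    fit <- tryCatch(fitConicLSQ(pts_xy), error = function(e) NULL)
    part <- if (!is.null(fit))
      new("GrainPartition", subsets = list(1L), fits = list(fit),
          totalError = fit@residual / fit@nPoints, grainCount = 1L)
    return(c(base, list(count_cpe = 1L, n_segments = 1L, fallback = FALSE,
                        partition = part, assignment = rep(1L, n))))
  }

  segs <- splitSegments(contour, corners)
  keep <- which(lengths(segs) > 0L)
  segIdxList <- segs[keep]
  k <- length(segIdxList)
  segPixels <- lapply(segIdxList, function(ix) pts_xy[ix, , drop = FALSE])
  fg <- .region_membership(mask, contour@label)
  inRegion <- function(ctr) {
    r <- as.integer(round(ctr[2L])); c <- as.integer(round(ctr[1L]))
    r >= 1L && r <= nrow(fg) && c >= 1L && c <= ncol(fg) && fg[r, c]
  }

  if (k == 0L || k > config$maxSegments) {
    return(c(base, list(count_cpe = cp, n_segments = k, fallback = TRUE,
                        partition = NULL, assignment = rep(0L, n))))
  }
  part <- tryCatch(
    bestPartition(segPixels, maxSegments = config$maxSegments,
                  lambda = config$lambda,
                  minGrainArea = config$minGrainArea, inRegion = inRegion),
    error = function(e) NULL)
  if (is.null(part)) {
    return(c(base, list(count_cpe = cp, n_segments = k, fallback = TRUE,
                        partition = NULL, assignment = rep(0L, n))))
  }

  assignment <- integer(n)
  for (s in seq_along(part@subsets))
    for (seg in part@subsets[[s]])
      assignment[segIdxList[[seg]]] <- s
  # corner pixels: join the adjacent subset whose ellipse passes closer
  for (ci in corners@indices) {
    nb <- c(assignment[if (ci == 1L) n else ci - 1L],
            assignment[if (ci == n) 1L else ci + 1L])
    nb <- unique(nb[nb > 0L])
    if (length(nb) == 1L) assignment[ci] <- nb
    else if (length(nb) > 1L) {
      res <- vapply(nb, function(s)
        conicResidualAt(part@fits[[s]], pts_xy[ci, , drop = FALSE]),
        numeric(1))
      assignment[ci] <- nb[which.min(res)]
    }
  }
  c(base, list(count_cpe = part@grainCount, n_segments = k,
               fallback = FALSE, partition = part, assignment = assignment))
}
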