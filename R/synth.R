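## Synthetic grain scenes: elliptical "grains" in tan/brown tones on white
## paper, placed loosely with a controllable fraction of touching contacts
## (clusters of 2-4) and optional chips (circular bites out of the
## boundary) that provoke spurious corner points. Scenes carry complete
## ground truth and are bit-reproducible from their seed.

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## radial support of an ellipse (a, b, theta) in global direction psi
.ellipse_radius <- function(a, b, theta, psi) {
  w <- psi - theta
  a * b / sqrt((b * cos(w))^2 + (a * sin(w))^2)
}

#' Generate a synthetic grain scene with ground truth
#'
#' Renders \code{nGrains} elliptical grains (semi-minor axis sampled from
#' \code{minorRange}, aspect ratio from \code{ratioRange}, random
#' orientation) on a white background. A \code{touchFraction} share of the
#' grains is placed tangent to an already-placed grain (overlapping about
#' 3 px along the line of centers, so the contact survives the pipeline's
#' 2x downsampling), forming clusters of up to 4. With probability
#' \code{chipProbability} a grain gets a chip: a circular bite of radius
#' 10-25\% of its semi-minor axis taken out of the boundary, the failure
#' mode that produces spurious corner points. Colors are grain-like
#' tan/brown with mild per-pixel noise.
#'
#' @param nGrains number of grains (>= 1; default 20).
#' @param touchFraction fraction of grains placed touching a previous one,
#'   in [0, 1] (default 0).
#' @param chipProbability per-grain probability of a chip (default 0).
#' @param imageSize c(width, height) in pixels (default 1984 x 1488, the
#'   pipeline's working resolution before its own 2x downsampling).
#' @param seed RNG seed; the scene is a deterministic function of the
#'   arguments and the seed.
#' @param minorRange,ratioRange sampling ranges for the grain semi-minor
#'   axis (pixels) and the major/minor aspect ratio.
#' @return a \linkS4class{GrainScene}.
#' @examples
#' sc <- generateScene(5, imageSize = c(600, 450), seed = 1)
#' trueCount(sc)
#' @export
generateScene <- function(nGrains = 20L, touchFraction = 0,
                          chipProbability = 0,
                          imageSize = c(1984L, 1488L), seed = 1L,
                          minorRange = c(28, 40),
                          ratioRange = c(1.6, 2.4)) {
  stopifnot(nGrains >= 1L, touchFraction >= 0, touchFraction <= 1)
  w <- as.integer(imageSize[1L]); h <- as.integer(imageSize[2L])
  .with_seed(seed, {
    b <- runif(nGrains, minorRange[1L], minorRange[2L])
    a <- b * runif(nGrains, ratioRange[1L], ratioRange[2L])
    th <- runif(nGrains, 0, pi)
    touch <- c(FALSE, runif(nGrains - 1L) < touchFraction)[seq_len(nGrains)]
    cx <- numeric(nGrains); cy <- numeric(nGrains)
    cluster <- seq_len(nGrains)  # union-find-ish cluster ids
    planned <- vector("list", 0L)  # planned touch pairs

    ok_margin <- function(i, x, y)
      x >= a[i] + 2 && x <= w - a[i] - 1 && y >= a[i] + 2 && y <= h - a[i] - 1
    clear_of <- function(i, x, y, others, gap) {
      for (k in others) {
        dx <- cx[k] - x; dy <- cy[k] - y
        d <- sqrt(dx^2 + dy^2)
        psi <- atan2(dy, dx)
        need <- .ellipse_radius(a[i], b[i], th[i], psi) +
                .ellipse_radius(a[k], b[k], th[k], psi + pi) + gap
        if (d < need) return(FALSE)
      }
      TRUE
    }

    for (i in seq_len(nGrains)) {
      placed <- FALSE
      for (try in seq_len(600L)) {
        if (touch[i] && i > 1L) {
          csize <- table(cluster[seq_len(i - 1L)])
          cand <- which(csize[as.character(cluster[seq_len(i - 1L)])] < 4L)
          if (!length(cand)) { touch[i] <- FALSE; next }
          j <- cand[sample.int(length(cand), 1L)]
          psi <- runif(1L, 0, 2 * pi)
          d <- .ellipse_radius(a[j], b[j], th[j], psi) +
               .ellipse_radius(a[i], b[i], th[i], psi + pi) - 3
          x <- cx[j] + d * cos(psi); y <- cy[j] + d * sin(psi)
          if (ok_margin(i, x, y) &&
              clear_of(i, x, y, setdiff(seq_len(i - 1L), j), 6)) {
            cx[i] <- x; cy[i] <- y
            cluster[i] <- cluster[j]
            planned[[length(planned) + 1L]] <- c(j, i)
            placed <- TRUE; break
          }
        } else {
          x <- runif(1L, a[i] + 2, w - a[i] - 1)
          y <- runif(1L, a[i] + 2, h - a[i] - 1)
          if (clear_of(i, x, y, seq_len(i - 1L), 8)) {
            cx[i] <- x; cy[i] <- y
            placed <- TRUE; break
          }
        }
      }
      if (!placed)
        stop("could not place grain ", i, " within the overlap limits; ",
             "reduce nGrains or enlarge imageSize")
    }

    # rasterize per-grain labels (first-placed grain keeps contested pixels)
    labels <- matrix(0L, h, w)
    for (i in seq_len(nGrains)) {
      r0 <- max(1L, floor(cy[i] - a[i])); r1 <- min(h, ceiling(cy[i] + a[i]))
      c0 <- max(1L, floor(cx[i] - a[i])); c1 <- min(w, ceiling(cx[i] + a[i]))
      rows <- r0:r1; cols <- c0:c1
      dx <- outer(rep(1, length(rows)), cols - cx[i])
      dy <- outer(rows - cy[i], rep(1, length(cols)))
      u <- dx * cos(th[i]) + dy * sin(th[i])
      v <- -dx * sin(th[i]) + dy * cos(th[i])
      inside <- (u / a[i])^2 + (v / b[i])^2 <= 1
      sub <- labels[rows, cols]
      sub[inside & sub == 0L] <- i
      labels[rows, cols] <- sub
    }

    # chips: circular bites out of the boundary
    chipped <- logical(nGrains)
    for (i in seq_len(nGrains)) {
      if (runif(1L) >= chipProbability) next
      t0 <- runif(1L, 0, 2 * pi)
      px <- cx[i] + a[i] * cos(t0) * cos(th[i]) - b[i] * sin(t0) * sin(th[i])
      py <- cy[i] + a[i] * cos(t0) * sin(th[i]) + b[i] * sin(t0) * cos(th[i])
      cr <- runif(1L, 0.10, 0.25) * b[i]
      r0 <- max(1L, floor(py - cr)); r1 <- min(h, ceiling(py + cr))
      c0 <- max(1L, floor(px - cr)); c1 <- min(w, ceiling(px + cr))
      rows <- r0:r1; cols <- c0:c1
      dd <- outer((rows - py)^2, rep(1, length(cols))) +
            outer(rep(1, length(rows)), (cols - px)^2)
      sub <- labels[rows, cols]
      sub[dd <= cr^2 & sub == i] <- 0L
      labels[rows, cols] <- sub
      chipped[i] <- TRUE
    }

    # grain colors: tan/brown via HSV
    hh <- runif(nGrains, 25, 40) / 360
    ss <- runif(nGrains, 0.45, 0.65)
    vv <- runif(nGrains, 0.50, 0.75)
    base <- grDevices::col2rgb(grDevices::hsv(hh, ss, vv))  # 3 x n

    img <- array(0, dim = c(h, w, 3L))
    fgidx <- which(labels > 0L)
    lv <- labels[fgidx]
    for (ch in 1:3) {
      plane <- matrix(253, h, w) + matrix(stats::rnorm(h * w, 0, 2), h, w)
      plane[fgidx] <- base[ch, lv] + stats::rnorm(length(fgidx), 0, 5)
      img[, , ch] <- pmin(255, pmax(0, round(plane)))
    }

    adjacency <- .label_adjacency(labels)
    grains <- data.frame(cx = cx, cy = cy, a = a, b = b, theta = th,
                         r = base[1L, ], g = base[2L, ], bcol = base[3L, ],
                         chipped = chipped)
    new("GrainScene", image = img, grains = grains, labels = labels,
        trueCount = as.integer(nGrains), adjacency = adjacency,
        seed = as.integer(seed))
  })
}

## touching pairs of distinct positive labels (8-neighborhood) in a label
## image
.label_adjacency <- function(labels) {
  h <- nrow(labels); w <- ncol(labels)
  cmp <- function(a, b) {
    sel <- a > 0L & b > 0L & a != b
    if (any(sel)) cbind(pmin(a[sel], b[sel]), pmax(a[sel], b[sel])) else NULL
  }
  pairs <- rbind(cmp(labels[, -w], labels[, -1L]),      # right neighbor
                 cmp(labels[-h, ], labels[-1L, ]),      # down
                 cmp(labels[-h, -w], labels[-1L, -1L]), # down-right
                 cmp(labels[-h, -1L], labels[-1L, -w])) # down-left
  if (is.null(pairs)) matrix(integer(0), 0L, 2L)
  else matrix(as.integer(unique(pairs)), ncol = 2L)
}
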