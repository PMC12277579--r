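# Independent brute-force oracles. These deliberately share no code with
# the package internals: plain double loops and textbook formulas.

# corner response by exhaustive pixel enumeration over the whole image
crf_oracle <- function(mask, label, row, col, R) {
  h <- nrow(mask); w <- ncol(mask)
  np <- 0L; A <- 0L
  fg_is_label <- max(mask) > 1L
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      if ((r - row)^2 + (c - col)^2 <= R^2) {
        A <- A + 1L
        fg <- if (fg_is_label) mask[r, c] == label else mask[r, c] > 0L
        if (fg) np <- np + 1L
      }
    }
  }
  np / A
}

# Otsu threshold by exhaustive between-class-variance scan over integer
# thresholds 0..255 (foreground/background split at value > t)
otsu_oracle <- function(gray) {
  v <- as.integer(round(as.vector(gray)))
  hist <- tabulate(v + 1L, nbins = 256L)
  n <- sum(hist)
  best_t <- 0L; best_var <- -1
  for (t in 0:255) {
    n0 <- sum(hist[seq_len(t + 1L)])
    n1 <- n - n0
    if (n0 == 0L || n1 == 0L) next
    mu0 <- sum((0:t) * hist[seq_len(t + 1L)]) / n0
    mu1 <- sum(((t + 1L):255) * hist[(t + 2L):256L]) / n1
    bc <- (n0 / n) * (n1 / n) * (mu0 - mu1)^2
    if (bc > best_var) { best_var <- bc; best_t <- t }
  }
  best_t
}

# --- independent partition evaluator ---------------------------------------

# conic fit by normal equations (lm.fit), own conditioning and geometry
oracle_fit <- function(pts) {
  pts <- unique(pts)
  if (nrow(pts) < 5L) return(NULL)
  x <- pts[, 1L]; y <- pts[, 2L]
  mx <- mean(x); my <- mean(y)
  sc <- max(max(x) - min(x), max(y) - min(y)) / 2
  if (sc <= 0) return(NULL)
  u <- (x - mx) / sc; v <- (y - my) / sc
  D <- cbind(u^2, 2 * u * v, v^2, 2 * u, 2 * v)
  fit <- stats::lm.fit(D, rep(-1, nrow(D)))
  al <- fit$coefficients
  al[is.na(al)] <- 0
  resid <- sum((D %*% al + 1)^2)
  # back to image coordinates
  A11 <- al[1L] / sc^2; A12 <- al[2L] / sc^2; A22 <- al[3L] / sc^2
  B1 <- al[4L] / sc - (al[1L] * mx + al[2L] * my) / sc^2
  B2 <- al[5L] / sc - (al[2L] * mx + al[3L] * my) / sc^2
  C <- (al[1L] * mx^2 + 2 * al[2L] * mx * my + al[3L] * my^2) / sc^2 -
       2 * (al[4L] * mx + al[5L] * my) / sc + 1
  det2 <- A11 * A22 - A12^2
  if (!is.finite(det2) || det2 <= 0) return(list(valid = FALSE))
  cx <- (A12 * B2 - A22 * B1) / det2
  cy <- (A12 * B1 - A11 * B2) / det2
  fc <- B1 * cx + B2 * cy + C
  tr <- A11 + A22
  disc <- sqrt(max((A11 - A22)^2 / 4 + A12^2, 0))
  l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
  if (-fc / l1 <= 0 || -fc / l2 <= 0) return(list(valid = FALSE))
  semi <- sort(c(sqrt(-fc / l1), sqrt(-fc / l2)), decreasing = TRUE)
  # major axis direction: eigenvector of the smaller eigenvalue l2
  ang <- if (abs(A12) > 1e-12) atan2(l2 - A11, A12) %% pi
         else if (A11 <= A22) 0 else pi / 2
  list(valid = TRUE, center = c(cx, cy), semi = semi, angle = ang,
       resid = resid, n = nrow(pts),
       conic = c(A11, A12, A22, B1, B2, C))
}

oracle_inside <- function(f, px, py) {
  co <- f$conic
  val <- co[1L] * px^2 + 2 * co[2L] * px * py + co[3L] * py^2 +
         2 * co[4L] * px + 2 * co[5L] * py + co[6L]
  ctr <- co[1L] * f$center[1L]^2 + 2 * co[2L] * prod(f$center) +
         co[3L] * f$center[2L]^2 + 2 * co[4L] * f$center[1L] +
         2 * co[5L] * f$center[2L] + co[6L]
  if (ctr < 0) val < 0 else val > 0
}

# overlap fraction via a cartesian bounding-box raster of the smaller
# ellipse (different scheme from the package's polar sampling)
oracle_overlap <- function(f1, f2) {
  if (prod(f2$semi) < prod(f1$semi)) { tmp <- f1; f1 <- f2; f2 <- tmp }
  a <- f1$semi[1L]
  xs <- seq(f1$center[1L] - a, f1$center[1L] + a, length.out = 41L)
  ys <- seq(f1$center[2L] - a, f1$center[2L] + a, length.out = 41L)
  g <- expand.grid(x = xs, y = ys)
  in1 <- oracle_inside(f1, g$x, g$y)
  if (!any(in1)) return(0)
  mean(oracle_inside(f2, g$x[in1], g$y[in1]))
}

# recursive set-partition enumeration (grow blocks depth-first)
oracle_partitions <- function(k) {
  out <- list()
  recurse <- function(i, blocks) {
    if (i > k) { out[[length(out) + 1L]] <<- blocks; return(invisible()) }
    for (b in seq_along(blocks)) {
      nb <- blocks; nb[[b]] <- c(nb[[b]], i)
      recurse(i + 1L, nb)
    }
    recurse(i + 1L, c(blocks, list(i)))
  }
  recurse(2L, list(1L))
  out
}

oracle_subset_error <- function(idx, segPixels, lambda, minGrainArea, fg) {
  f <- oracle_fit(do.call(rbind, segPixels[idx]))
  if (is.null(f) || !isTRUE(f$valid)) return(NULL)
  if (pi * prod(f$semi) < minGrainArea) return(NULL)
  r <- round(f$center[2L]); c <- round(f$center[1L])
  if (r < 1 || r > nrow(fg) || c < 1 || c > ncol(fg) || !fg[r, c])
    return(NULL)
  ds <- numeric(0); minors <- f$semi[2L]
  if (length(idx) > 1L) {
    for (s in idx) {
      fs <- oracle_fit(segPixels[[s]])
      if (is.null(fs) || !isTRUE(fs$valid)) next
      ds <- c(ds, sqrt(sum((fs$center - f$center)^2)))
      minors <- c(minors, fs$semi[2L])
    }
  }
  err <- f$resid / f$n +
         lambda * (if (length(ds)) mean(ds) else 0) / min(minors)
  list(err = err, fit = f)
}

# full re-evaluation: returns the winning blocks (canonicalized) and error
oracle_best_partition <- function(segPixels, fg, lambda = 1,
                                  minGrainArea = 30, overlap_limit = 0.4) {
  k <- length(segPixels)
  best <- NULL; bestErr <- Inf; bestK <- Inf
  for (blocks in oracle_partitions(k)) {
    evals <- lapply(blocks, oracle_subset_error, segPixels = segPixels,
                    lambda = lambda, minGrainArea = minGrainArea, fg = fg)
    if (any(vapply(evals, is.null, logical(1)))) next
    bad <- FALSE
    if (length(blocks) > 1L) {
      for (i in seq_len(length(blocks) - 1L)) {
        for (j in (i + 1L):length(blocks)) {
          if (oracle_overlap(evals[[i]]$fit, evals[[j]]$fit) >
              overlap_limit) { bad <- TRUE; break }
        }
        if (bad) break
      }
    }
    if (bad) next
    err <- sum(vapply(evals, `[[`, numeric(1), "err"))
    if (err < bestErr || (err == bestErr && length(blocks) < bestK)) {
      bestErr <- err; bestK <- length(blocks); best <- blocks
    }
  }
  list(blocks = best, err = bestErr)
}

canon_blocks <- function(blocks) {
  s <- lapply(blocks, function(b) sort(as.integer(b)))
  s[order(vapply(s, `[`, integer(1), 1L))]
}
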