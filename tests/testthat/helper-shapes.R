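# Raster shape builders used throughout the tests (built in code, no
# stored fixtures).

raster_disk <- function(h, w, cy, cx, r) {
  m <- matrix(0L, h, w)
  g <- expand.grid(r = seq_len(h), c = seq_len(w))
  sel <- (g$r - cy)^2 + (g$c - cx)^2 <= r^2
  m[cbind(g$r[sel], g$c[sel])] <- 1L
  m
}

raster_ellipse <- function(h, w, cy, cx, a, b, theta) {
  m <- matrix(0L, h, w)
  g <- expand.grid(r = seq_len(h), c = seq_len(w))
  dx <- g$c - cx; dy <- g$r - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  sel <- (u / a)^2 + (v / b)^2 <= 1
  m[cbind(g$r[sel], g$c[sel])] <- 1L
  m
}

# remove a circular bite of radius cr centered at boundary point (by, bx)
raster_chip <- function(mask, by, bx, cr) {
  g <- expand.grid(r = seq_len(nrow(mask)), c = seq_len(ncol(mask)))
  sel <- (g$r - by)^2 + (g$c - bx)^2 <= cr^2
  mask[cbind(g$r[sel], g$c[sel])] <- 0L
  mask
}

# point on an ellipse boundary at parameter t
ellipse_point <- function(cy, cx, a, b, theta, t) {
  c(y = cy + a * cos(t) * sin(theta) + b * sin(t) * cos(theta),
    x = cx + a * cos(t) * cos(theta) - b * sin(t) * sin(theta))
}

# half-plane foreground: left `cols` columns are foreground
raster_halfplane <- function(h, w, cols) {
  m <- matrix(0L, h, w)
  m[, seq_len(cols)] <- 1L
  m
}

# filled wedge with apex at (cy, cx), interior angle `deg` degrees,
# bisector pointing along +x (into increasing columns)
raster_wedge <- function(h, w, cy, cx, deg) {
  g <- expand.grid(r = seq_len(h), c = seq_len(w))
  ang <- atan2(g$r - cy, g$c - cx)
  half <- deg / 2 * pi / 180
  sel <- abs(ang) <= half | (g$r == cy & g$c == cx)
  m <- matrix(0L, h, w)
  m[cbind(g$r[sel], g$c[sel])] <- 1L
  m
}
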