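#' Least-squares conic (ellipse) fit to a pixel set
#'
#' Fits the conic \eqn{a_{11}x^2 + 2a_{12}xy + a_{22}y^2 + 2b_1x + 2b_2y
#' + 1 = 0} to a set of points by linear least squares: every point
#' contributes one row \eqn{(x^2, 2xy, y^2, 2x, 2y)} of the design matrix
#' D with right-hand side \eqn{-1}, and the coefficient vector is the SVD
#' pseudoinverse solution minimizing \eqn{\lVert D\alpha + 1\rVert^2}.
#' Coordinates are centered and scaled to the point set's bounding box
#' before solving (the raw quadratic system is badly conditioned at image
#' scale) and the conic is mapped back afterwards. The algebraic residual
#' is reported in the conditioned coordinates, normalized so that points
#' lying exactly on an ellipse give residuals at machine precision
#' regardless of where the ellipse sits in the image.
#'
#' @param points numeric matrix with columns \code{(x, y)} (x = column
#'   direction, y = row direction, in pixels).
#' @return an \linkS4class{EllipseFit}. Collinear or otherwise degenerate
#'   point sets yield \code{isValidEllipse = FALSE} (no error); fewer than
#'   5 distinct points is an error.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 40)
#' pts <- cbind(100 + 30 * cos(th), 80 + 15 * sin(th))
#' fitConicLSQ(pts)
#' @export
fitConicLSQ <- function(points) {
  if (!is.matrix(points) || ncol(points) != 2L)
    stop("points must be an n x 2 matrix of (x, y)")
  pts <- unique(points)
  n <- nrow(pts)
  if (n < 5L) stop("underdetermined: need >= 5 distinct points")
  x <- pts[, 1L]; y <- pts[, 2L]
  cx <- mean(x); cy <- mean(y)
  s <- max(max(x) - min(x), max(y) - min(y)) / 2
  if (s <= 0) stop("underdetermined: need >= 5 distinct points")
  u <- (x - cx) / s; v <- (y - cy) / s
  D <- cbind(u^2, 2 * u * v, v^2, 2 * u, 2 * v)
  sv <- svd(D)
  d <- sv$d
  tol <- max(d) * max(dim(D)) * .Machine$double.eps
  dinv <- ifelse(d > tol, 1 / d, 0)
  alpha <- -as.vector(sv$v %*% (dinv * crossprod(sv$u, rep(1, n))))
  resid <- sum((D %*% alpha + 1)^2)
  geo <- .conic_geometry(alpha, cx, cy, s)
  new("EllipseFit", coefficients = geo$coefficients, center = geo$center,
      semiAxes = geo$semiAxes, angle = geo$angle, residual = resid,
      nPoints = as.integer(n), isValidEllipse = geo$valid)
}

## map conditioned conic coefficients back to image coordinates and derive
## center, semi-axes and orientation
.conic_geometry <- function(alpha, cx, cy, s) {
  a11 <- alpha[1L]; a12 <- alpha[2L]; a22 <- alpha[3L]
  b1 <- alpha[4L]; b2 <- alpha[5L]
  # un-normalize: u = (x - cx)/s, v = (y - cy)/s
  A11 <- a11 / s^2; A12 <- a12 / s^2; A22 <- a22 / s^2
  B1 <- b1 / s - (a11 * cx + a12 * cy) / s^2
  B2 <- b2 / s - (a12 * cx + a22 * cy) / s^2
  C <- (a11 * cx^2 + 2 * a12 * cx * cy + a22 * cy^2) / s^2 -
       2 * (b1 * cx + b2 * cy) / s + 1
  coefs <- c(a11 = A11, a12 = A12, a22 = A22, b1 = B1, b2 = B2)
  if (abs(C) > 1e-300) coefs <- coefs / C  # restore the "+ 1" normal form
  Amat <- matrix(c(A11, A12, A12, A22), 2L, 2L)
  detA <- A11 * A22 - A12^2
  bad <- list(coefficients = coefs, center = c(NA_real_, NA_real_),
              semiAxes = c(NA_real_, NA_real_), angle = NA_real_,
              valid = FALSE)
  if (!is.finite(detA) || detA <= .Machine$double.eps * max(abs(Amat))^2)
    return(bad)
  ctr <- tryCatch(solve(Amat, -c(B1, B2)), error = function(e) NULL)
  if (is.null(ctr) || any(!is.finite(ctr))) return(bad)
  fc <- B1 * ctr[1L] + B2 * ctr[2L] + C  # value of the form at the center
  ev <- eigen(Amat, symmetric = TRUE)
  ax2 <- -fc / ev$values
  if (any(!is.finite(ax2)) || any(ax2 <= 0)) return(bad)
  semi <- sqrt(ax2)            # eigen returns decreasing values ->
  ord <- order(semi, decreasing = TRUE)  # smaller eigenvalue = major axis
  vec <- ev$vectors[, ord[1L]]
  ang <- atan2(vec[2L], vec[1L]) %% pi
  list(coefficients = coefs, center = as.numeric(ctr),
       semiAxes = as.numeric(semi[ord]), angle = ang, valid = TRUE)
}

## fraction of the smaller ellipse's area lying inside the larger one,
## approximated on a deterministic interior sample grid. Used to reject
## partitions whose grain ellipses interpenetrate: two solid grains can
## touch but cannot substantially co-occupy the same area.
.ellipse_overlap_frac <- function(f1, f2) {
  a1 <- prod(f1@semiAxes); a2 <- prod(f2@semiAxes)
  if (a2 < a1) { tmp <- f1; f1 <- f2; f2 <- tmp }
  # area-uniform polar sample of the smaller ellipse's interior
  u <- seq(0.05, 0.95, length.out = 10L)
  t <- seq(0, 2 * pi, length.out = 17L)[-1L]
  g <- expand.grid(r = sqrt(u), t = t)
  ca <- cos(f1@angle); sa <- sin(f1@angle)
  ex <- f1@semiAxes[1L] * g$r * cos(g$t); ey <- f1@semiAxes[2L] * g$r * sin(g$t)
  px <- f1@center[1L] + ex * ca - ey * sa
  py <- f1@center[2L] + ex * sa + ey * ca
  co <- f2@coefficients
  val <- co[["a11"]] * px^2 + 2 * co[["a12"]] * px * py +
         co[["a22"]] * py^2 + 2 * co[["b1"]] * px + 2 * co[["b2"]] * py + 1
  # the interior of a real ellipse in "+1" normal form is where the form
  # is negative (its value at the center is negative)
  ctrv <- co[["a11"]] * f2@center[1L]^2 +
          2 * co[["a12"]] * f2@center[1L] * f2@center[2L] +
          co[["a22"]] * f2@center[2L]^2 + 2 * co[["b1"]] * f2@center[1L] +
          2 * co[["b2"]] * f2@center[2L] + 1
  inside <- if (ctrv < 0) val < 0 else val > 0
  mean(inside)
}

#' Evaluate the algebraic conic residual at points
#'
#' Absolute value of \eqn{a_{11}x^2 + 2a_{12}xy + a_{22}y^2 + 2b_1x +
#' 2b_2y + 1} at the given points, using a fit's image-coordinate
#' coefficients. Used to assign corner pixels to the adjacent grain whose
#' ellipse passes closer.
#'
#' @param fit an \linkS4class{EllipseFit}.
#' @param points numeric matrix with columns (x, y).
#' @return numeric vector of absolute algebraic residuals.
#' @export
conicResidualAt <- function(fit, points) {
  co <- fit@coefficients
  x <- points[, 1L]; y <- points[, 2L]
  abs(co[["a11"]] * x^2 + 2 * co[["a12"]] * x * y + co[["a22"]] * y^2 +
      2 * co[["b1"]] * x + 2 * co[["b2"]] * y + 1)
}
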