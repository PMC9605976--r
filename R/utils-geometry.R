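#' @useDynLib eggchamber, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx coef dist lm lm.fit loess median optimize p.adjust pf
#'   plogis pnorm predict prcomp qt quantile rlnorm rnorm runif sd setNames
#'   uniroot var aov cor
#' @importFrom utils head read.csv tail write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

## ---- ellipse geometry -------------------------------------------------
## All planar geometry in the package is built on axis-aligned ellipses:
## the anterior pole sits at x = -a, the posterior pole at x = +a.

#' Discretize an ellipse contour
#'
#' @param a,b semi-axes (anterior-posterior and dorso-ventral), um.
#' @param n number of vertices.
#' @return matrix with columns x, y; closed curve traversed
#'   counter-clockwise starting at the posterior pole.
#' @keywords internal
ellipse_contour <- function(a, b, n = 720L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(x = a * cos(th), y = b * sin(th))
}

## shoelace area of a closed polygon (matrix with columns x, y)
polygon_area <- function(p) {
  x <- p[, 1L]; y <- p[, 2L]
  abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
}

## perimeter of an ellipse (numeric quadrature, well below 1e-8 rel. error)
ellipse_perimeter <- function(a, b, n = 4096L) {
  th <- seq(0, pi / 2, length.out = n)
  f <- sqrt((a * sin(th))^2 + (b * cos(th))^2)
  4 * sum((f[-1L] + f[-n]) / 2) * diff(th[1:2])
}

## area of the ellipse segment x >= x0
ellipse_segment_area <- function(a, b, x0) {
  t0 <- acos(pmin(1, pmax(-1, x0 / a)))
  a * b * (t0 - sin(t0) * cos(t0))
}

## x-position of the chord cutting a posterior segment of given area fraction
ellipse_segment_chord <- function(a, b, frac) {
  if (frac <= 0) return(a)
  if (frac >= 1) return(-a)
  target <- frac * pi * a * b
  uniroot(function(x0) ellipse_segment_area(a, b, x0) - target,
          c(-a + 1e-9 * a, a - 1e-9 * a), tol = 1e-12 * a)$root
}

## arc-length fraction of the ellipse boundary with x >= x0
ellipse_arc_fraction <- function(a, b, x0, n = 4096L) {
  ## integrate ds over parameter t where x(t) >= x0
  th <- seq(0, pi, length.out = n)  # upper half suffices by symmetry
  x <- a * cos(th)
  ds <- sqrt((a * sin(th))^2 + (b * cos(th))^2)
  w <- (x[-1L] + x[-n]) / 2 >= x0
  sum(((ds[-1L] + ds[-n]) / 2)[w]) / sum((ds[-1L] + ds[-n]) / 2)
}

## unit tangent of the ellipse at parameter theta
ellipse_tangent <- function(a, b, theta) {
  v <- c(-a * sin(theta), b * cos(theta))
  v / sqrt(sum(v^2))
}

## arc length from the anterior pole (theta = pi) to parameter theta,
## measured along the upper half; theta in [0, pi]
ellipse_arc_from_anterior <- function(a, b, theta, n = 2048L) {
  vapply(theta, function(t1) {
    th <- seq(pi, t1, length.out = n)
    f <- sqrt((a * sin(th))^2 + (b * cos(th))^2)
    abs(sum((f[-1L] + f[-n]) / 2 * diff(th)))
  }, numeric(1))
}
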