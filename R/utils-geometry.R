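#' Distance from points to a closed polygon outline
#'
#' Minimal Euclidean distance from each query point to the outline of a
#' closed polygon (the edge set, including the closing edge). Points may lie
#' inside or outside the polygon; the distance is always non-negative.
#'
#' @param pts numeric matrix with two columns (x, y), one row per point.
#' @param poly numeric matrix with two columns (x, y) of polygon vertices in
#'   order; the polygon is closed implicitly (last vertex connects to first).
#' @return numeric vector of distances, one per row of `pts`.
#' @export
dist_to_polygon <- function(pts, poly) {
  pts <- as_xy_matrix(pts)
  poly <- as_xy_matrix(poly)
  if (nrow(poly) < 3L) stop("polygon needs at least 3 vertices")
  x1 <- poly[, 1L]; y1 <- poly[, 2L]
  x2 <- c(poly[-1L, 1L], poly[1L, 1L])
  y2 <- c(poly[-1L, 2L], poly[1L, 2L])
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  len2[len2 == 0] <- .Machine$double.eps
  vapply(seq_len(nrow(pts)), function(i) {
    px <- pts[i, 1L]; py <- pts[i, 2L]
    tt <- ((px - x1) * dx + (py - y1) * dy) / len2
    tt <- pmin(1, pmax(0, tt))
    qx <- x1 + tt * dx - px
    qy <- y1 + tt * dy - py
    sqrt(min(qx * qx + qy * qy))
  }, numeric(1L))
}

as_xy_matrix <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (ncol(m) != 2L) stop("expected a 2-column (x, y) matrix")
  m
}

#' Smoothed random-radius star polygon
#'
#' Cell outlines are modelled as star-shaped domains around a center: the
#' radius is sampled at a small number of control angles, perturbed, and
#' interpolated with a periodic spline. This gives irregular but smooth,
#' non-self-intersecting outlines resembling adherent cells.
#'
#' @param cx,cy center coordinates.
#' @param radius mean radius (same units as the coordinates).
#' @param n_ctrl number of radial control points (8-12 is typical).
#' @param irregularity relative s.d. of the radial perturbation.
#' @param n_vertices number of polygon vertices returned.
#' @return a matrix of vertices (columns x, y) with attributes `center`,
#'   `theta` and `r` giving the dense radial representation r(theta).
#' @export
star_polygon <- function(cx, cy, radius, n_ctrl = 10L, irregularity = 0.1,
                         n_vertices = 120L) {
  stopifnot(radius > 0, n_ctrl >= 3L, n_vertices >= 12L)
  th_ctrl <- seq(0, 2 * pi, length.out = n_ctrl + 1L)
  r_ctrl <- radius * pmax(0.4, 1 + stats::rnorm(n_ctrl, 0, irregularity))
  r_ctrl <- c(r_ctrl, r_ctrl[1L])
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  r <- stats::spline(th_ctrl, r_ctrl, method = "periodic", xout = th)$y
  r <- pmin(pmax(r, 0.3 * radius), 1.8 * radius)
  out <- cbind(x = cx + r * cos(th), y = cy + r * sin(th))
  attr(out, "center") <- c(cx, cy)
  attr(out, "theta") <- th
  attr(out, "r") <- r
  out
}

# Radius of a star polygon's dense radial representation at arbitrary angles,
# by periodic linear interpolation between the stored dense samples.
star_radius_at <- function(poly, theta) {
  th <- attr(poly, "theta"); r <- attr(poly, "r")
  if (is.null(th)) stop("polygon lacks a radial representation")
  theta <- theta %% (2 * pi)
  step <- th[2L] - th[1L]
  i0 <- floor(theta / step)
  frac <- theta / step - i0
  n <- length(r)
  i0 <- (i0 %% n) + 1L
  i1 <- (i0 %% n) + 1L
  r[i0] * (1 - frac) + r[i1] * frac
}

# TRUE when points lie inside the star polygon (radial test against the dense
# radial representation, with a small safety margin so that accepted points
# are strictly inside the chord polygon as well).
inside_star <- function(poly, pts, margin = 0.995) {
  pts <- as_xy_matrix(pts)
  ctr <- attr(poly, "center")
  dx <- pts[, 1L] - ctr[1L]
  dy <- pts[, 2L] - ctr[2L]
  rho <- sqrt(dx * dx + dy * dy)
  th <- atan2(dy, dx)
  rho <= margin * star_radius_at(poly, th)
}

# Evaluate code with a temporary RNG seed, restoring global RNG state after.
local_rng <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
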