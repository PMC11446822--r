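#' Hexagonal lattice coordinates
#'
#' The lattice uses integer axial coordinates (p, q) in which all three
#' cardinal axes point upwards: a step along v is (p+1, q+1), along p is
#' (p+1, q) and along q is (p, q+1).  The Cartesian embedding with lattice
#' constant `a` is
#' \deqn{x = (p - q)\,\frac{\sqrt{3}}{2}\,a, \qquad y = (p + q)\,\frac{a}{2}}
#' so the six nearest neighbours of (p, q) are (p±1, q), (p, q±1) and
#' (p±1, q±1), all at distance `a`.  Hexagons are flat-topped with side
#' `s = a / sqrt(3)`.
#'
#' @param p,q integer axial coordinates (vectorized).
#' @param a lattice constant (centre-to-centre column spacing).
#' @return `hex_to_cart()`: a two-column matrix of `x`, `y` coordinates.
#' @examples
#' hex_to_cart(1, 0)          # p step: upper right, +60 deg from vertical
#' hex_dist(0, 0, 1, -1)      # next-nearest neighbour: 2 steps
#' @export
hex_to_cart <- function(p, q, a = 1) {
  cbind(x = (p - q) * sqrt(3) / 2 * a, y = (p + q) * a / 2)
}

#' @rdname hex_to_cart
#' @param p2,q2 coordinates of the second point.
#' @return `hex_dist()`: integer lattice (hop) distance.
#' @export
hex_dist <- function(p, q, p2, q2) {
  dp <- p2 - p
  dq <- q2 - q
  ifelse(sign(dp) * sign(dq) >= 0, pmax(abs(dp), abs(dq)), abs(dp) + abs(dq))
}

# Offsets of the six nearest neighbours, one row each.
hex_neighbour_offsets <- function() {
  cbind(p = c(1, -1, 0, 0, 1, -1), q = c(0, 0, 1, -1, 1, -1))
}

#' All lattice points within a hexagonal ball
#'
#' @param radius non-negative integer hop radius.
#' @return data.frame with columns `p`, `q` of all points at lattice distance
#'   `<= radius` from the origin, in deterministic (p, q) order.
#' @export
hex_ball <- function(radius) {
  stopifnot(radius >= 0)
  g <- expand.grid(p = -radius:radius, q = -radius:radius)
  g <- g[hex_dist(0, 0, g$p, g$q) <= radius, , drop = FALSE]
  g <- g[order(g$p, g$q), ]
  rownames(g) <- NULL
  g
}

#' Axial step vector of a cardinal axis
#'
#' @param axis one of `"v"`, `"p"`, `"q"`.
#' @return integer vector `c(p, q)` of one step along the axis.
#' @export
hex_axis_step <- function(axis = c("v", "p", "q")) {
  axis <- match.arg(axis)
  switch(axis, v = c(1L, 1L), p = c(1L, 0L), q = c(0L, 1L))
}

#' Orientation of a cardinal axis, degrees clockwise from vertical
#'
#' v points up (0), p upper-right (+60), q upper-left (-60).
#' @inheritParams hex_axis_step
#' @export
hex_axis_angle <- function(axis = c("v", "p", "q")) {
  axis <- match.arg(axis)
  switch(axis, v = 0, p = 60, q = -60)
}

#' Uniform samples over a flat-top regular hexagon
#'
#' Rejection sampling from the bounding box of a flat-topped hexagon of side
#' `s` centred at the origin (vertices at (±s, 0) and (±s/2, ±s√3/2)).
#' Used to validate the uniform-hexagon term of the ellipse covariance.
#'
#' @param n number of samples.
#' @param s hexagon side length.
#' @return matrix with columns `x`, `y` and `n` rows.
#' @export
sample_hexagon <- function(n, s = 1) {
  stopifnot(n >= 1, s > 0)
  out <- matrix(numeric(0), ncol = 2)
  while (nrow(out) < n) {
    m <- ceiling((n - nrow(out)) / 0.7) # hexagon fills ~75% of its box
    x <- stats::runif(m, -s, s)
    y <- stats::runif(m, -s * sqrt(3) / 2, s * sqrt(3) / 2)
    keep <- abs(y) <= sqrt(3) * (s - abs(x))
    out <- rbind(out, cbind(x[keep], y[keep]))
  }
  out <- out[seq_len(n), , drop = FALSE]
  colnames(out) <- c("x", "y")
  out
}

# Wrap an axial angle (degrees) into (-90, 90].
wrap_axial <- function(theta) {
  t <- (theta + 90) %% 180 - 90
  ifelse(t == -90, 90, t)
}

#' Axial orientation difference
#'
#' Smallest absolute difference between two axial orientations (mod 180
#' degrees); the natural error measure for ellipse orientations.
#'
#' @param theta1,theta2 orientations in degrees (vectorized).
#' @return absolute axial difference in `[0, 90]`.
#' @export
axial_diff_deg <- function(theta1, theta2) {
  d <- (theta1 - theta2 + 90) %% 180 - 90
  abs(d)
}
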