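#' Ellipse approximation to a hexel image
#'
#' Normalizes the map into a probability distribution
#' `p_i = h_i / sum_j h_j` over hexel centres at Cartesian coordinates
#' `(x_i, y_i)`, computes the centroid and the covariance matrix
#' \deqn{C = \sum_i p_i \begin{pmatrix}(x_i-\bar x)^2 & (x_i-\bar x)(y_i-\bar y)\\
#'  (x_i-\bar x)(y_i-\bar y) & (y_i-\bar y)^2\end{pmatrix} + \frac{5 s^2}{12} I}
#' and reports length `2*sigma_max`, width `2*sigma_min` (square roots of
#' the larger/smaller eigenvalue), and the orientation of the principal
#' eigenvector as an axial angle in degrees, clockwise-positive relative to
#' vertical, in (-90, 90].  The `5 s^2 / 12` term is the correction applied
#' when each point mass is smeared over its hexagonal column, so that a
#' single non-zero hexel has length = width = `s * sqrt(5/3)` rather than 0.
#'
#' @param m a non-empty [hexel_map] with positive total weight.
#' @param s hexagon side; the lattice constant is `a = s * sqrt(3)`
#'   (default `a = 1`).
#' @return list of class `hex_ellipse`: `cx`, `cy` (centroid, Cartesian),
#'   `length`, `width`, `orientation` (degrees), `aspect`, `degenerate`
#'   (TRUE when the covariance is isotropic and orientation is reported
#'   as 0).
#' @export
ellipse_fit <- function(m, s = 1 / sqrt(3)) {
  if (nrow(m) == 0 || sum(m$value) <= 0)
    stop("ellipse_fit needs a map with positive total weight", call. = FALSE)
  a <- s * sqrt(3)
  xy <- hex_to_cart(m$p, m$q, a = a)
  pr <- m$value / sum(m$value)
  cx <- sum(pr * xy[, 1])
  cy <- sum(pr * xy[, 2])
  dx <- xy[, 1] - cx
  dy <- xy[, 2] - cy
  C <- matrix(c(sum(pr * dx^2), sum(pr * dx * dy),
                sum(pr * dx * dy), sum(pr * dy^2)), 2, 2)
  C <- C + 5 * s^2 / 12 * diag(2)
  e <- eigen(C, symmetric = TRUE)
  lmax <- e$values[1]
  lmin <- e$values[2]
  degenerate <- (lmax - lmin) <= 1e-12 * lmax
  if (degenerate) {
    orientation <- 0
  } else {
    v <- e$vectors[, 1]
    orientation <- wrap_axial(atan2(v[1], v[2]) * 180 / pi)
  }
  structure(list(cx = cx, cy = cy,
                 length = 2 * sqrt(lmax), width = 2 * sqrt(lmin),
                 orientation = orientation,
                 aspect = if (degenerate) 1 else sqrt(lmax / lmin),
                 degenerate = degenerate),
            class = "hex_ellipse")
}

#' @export
print.hex_ellipse <- function(x, ...) {
  cat(sprintf(
    "<ellipse> centre (%.3f, %.3f), length %.3f, width %.3f, %.1f deg, aspect %.3f\n",
    x$cx, x$cy, x$length, x$width, x$orientation, x$aspect))
  invisible(x)
}

#' Gaussian width conventions
#'
#' The stored length/width are `2*sigma` of the matched 1D Gaussian, i.e.
#' the full width at `exp(-1/2) ~ 0.6` of the maximum.  The full width at
#' half maximum alternative is `2*sqrt(2*log(2))*sigma ~ 2.4*sigma`.
#'
#' @param sigma Gaussian standard deviation(s).
#' @param convention `"two_sigma"` or `"fwhm"`.
#' @return the width under the chosen convention.
#' @export
gaussian_width <- function(sigma, convention = c("two_sigma", "fwhm")) {
  convention <- match.arg(convention)
  switch(convention,
         two_sigma = 2 * sigma,
         fwhm = 2 * sqrt(2 * log(2)) * sigma)
}

#' 1D projection onto a cardinal lattice axis
#'
#' Groups hexels with equal `p + q` (axis v), `2p - q` (axis p) or `2q - p`
#' (axis q), then smooths the grouped sums by convolving with
#' `[0.5, 1, 0.5]` at stride 2, sampling on even keys so the key-0 bin
#' always exists.  The resulting bin coordinate is `key / 2`, in units of
#' one lattice constant.  The binned values conserve the total map weight.
#'
#' @param m a non-empty [hexel_map].
#' @param axis `"v"`, `"p"` or `"q"`.
#' @return data.frame of class `projection1d` with columns `coordinate`,
#'   `value`; attributes `axis` and `unit` (`"lattice_constant"`).
#' @export
project_cardinal <- function(m, axis = c("v", "p", "q")) {
  axis <- match.arg(axis)
  if (nrow(m) == 0) stop("cannot project an empty map", call. = FALSE)
  key <- switch(axis, v = m$p + m$q, p = 2 * m$p - m$q, q = 2 * m$q - m$p)
  lo <- min(key) - 1
  hi <- max(key) + 1
  ks <- lo:hi
  g <- stats::setNames(rep(0, length(ks)), ks)
  sums <- tapply(m$value, key, sum)
  g[names(sums)] <- sums
  even <- ks[ks %% 2 == 0]
  gv <- function(k) ifelse(k >= lo & k <= hi, g[as.character(k)], 0)
  val <- 0.5 * gv(even - 1) + gv(even) + 0.5 * gv(even + 1)
  structure(data.frame(coordinate = even / 2, value = as.numeric(val)),
            axis = axis, unit = "lattice_constant",
            class = c("projection1d", "data.frame"))
}

#' 1D projection onto an orthogonal lattice axis
#'
#' Groups hexels with equal `q - p` (axis h), `q` (axis p-perp) or `p`
#' (axis q-perp); no smoothing.  The bin coordinate is the key, in units of
#' lattice constant times `sqrt(3)/2`.
#'
#' @param m a non-empty [hexel_map].
#' @param axis `"h"`, `"p_perp"` or `"q_perp"`.
#' @return a `projection1d` (see [project_cardinal()]) with unit
#'   `"lattice_constant_sqrt3_over_2"`.
#' @export
project_orthogonal <- function(m, axis = c("h", "p_perp", "q_perp")) {
  axis <- match.arg(axis)
  if (nrow(m) == 0) stop("cannot project an empty map", call. = FALSE)
  key <- switch(axis, h = m$q - m$p, p_perp = m$q, q_perp = m$p)
  sums <- tapply(m$value, key, sum)
  ks <- as.integer(names(sums))
  ord <- order(ks)
  structure(data.frame(coordinate = ks[ord], value = as.numeric(sums)[ord]),
            axis = axis, unit = "lattice_constant_sqrt3_over_2",
            class = c("projection1d", "data.frame"))
}

#' Support half-width of a projection
#'
#' Largest absolute bin coordinate with non-zero value; a scalar measure of
#' how far the field extends along the projection axis.
#'
#' @param pr a `projection1d`.
#' @export
projection_extent <- function(pr) {
  nz <- pr$coordinate[pr$value > 0]
  if (length(nz) == 0) 0 else max(abs(nz))
}

#' Mean and spread of aligned 1D projections
#'
#' Per-bin mean and population standard deviation across cells; bins absent
#' from one projection count as 0 there.  All projections must share the
#' same axis.
#'
#' @param projections list of `projection1d` objects on a common axis.
#' @return a `projection1d` with columns `coordinate`, `value` (mean), `sd`,
#'   and attribute `n`.
#' @export
projection_stats <- function(projections) {
  stopifnot(length(projections) >= 1)
  axes <- vapply(projections, function(p) attr(p, "axis"), character(1))
  if (length(unique(axes)) != 1)
    stop("projections are on different axes", call. = FALSE)
  coords <- sort(unique(unlist(lapply(projections, `[[`, "coordinate"))))
  acc <- vapply(projections, function(pr) {
    v <- pr$value[match(coords, pr$coordinate)]
    v[is.na(v)] <- 0
    v
  }, numeric(length(coords)))
  acc <- matrix(acc, nrow = length(coords))
  mu <- rowMeans(acc)
  sdv <- sqrt(pmax(rowMeans(acc^2) - mu^2, 0))
  structure(data.frame(coordinate = coords, value = mu, sd = sdv),
            axis = axes[1], unit = attr(projections[[1]], "unit"),
            n = length(projections),
            class = c("projection1d", "data.frame"))
}

#' Export a projection to CSV
#' @param pr a `projection1d`.
#' @param path file path.
#' @export
write_projection_csv <- function(pr, path) {
  d <- as.data.frame(pr)
  d$axis <- attr(pr, "axis")
  n <- attr(pr, "n")
  d$n <- if (is.null(n)) 1L else n
  utils::write.csv(d, path, row.names = FALSE)
  invisible(pr)
}

# Axial (mod 180 deg) median via angle doubling: the sample orientation
# minimizing the summed axial distance to all others.
axial_median <- function(theta) {
  if (length(theta) == 1) return(wrap_axial(theta))
  cost <- vapply(theta, function(t) sum(axial_diff_deg(t, theta)), numeric(1))
  wrap_axial(theta[which.min(cost)])
}

#' Population summary of fitted ellipses
#'
#' Box-plot statistics (median, quartiles, whiskers at 1.5 times the
#' interquartile range, outliers beyond the whiskers) for the aspect ratio,
#' and circular (axial, mod 180 degrees) statistics for the orientation via
#' the doubled-angle construction.
#'
#' @param ellipses list of [ellipse_fit()] results.
#' @return list with elements `n`, `orientation` (median, and axial spread
#'   `mad`) and `aspect` (median, q1, q3, whisker_lo, whisker_hi, outliers).
#' @export
population_summary <- function(ellipses) {
  stopifnot(length(ellipses) >= 1)
  ori <- vapply(ellipses, `[[`, numeric(1), "orientation")
  asp <- vapply(ellipses, `[[`, numeric(1), "aspect")
  med_ori <- axial_median(ori)
  qs <- stats::quantile(asp, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- qs[3] - qs[1]
  lo <- qs[1] - 1.5 * iqr
  hi <- qs[3] + 1.5 * iqr
  list(n = length(ellipses),
       orientation = list(median = med_ori,
                          mad = stats::median(axial_diff_deg(ori, med_ori))),
       aspect = list(median = qs[2], q1 = qs[1], q3 = qs[3],
                     whisker_lo = min(asp[asp >= lo]),
                     whisker_hi = max(asp[asp <= hi]),
                     outliers = sort(asp[asp < lo | asp > hi])))
}

#' Export ellipses to CSV
#'
#' Columns: id, cx, cy, length, width, orientation_deg, aspect.
#' @param ellipses named list of [ellipse_fit()] results.
#' @param path file path.
#' @export
write_ellipses_csv <- function(ellipses, path) {
  d <- data.frame(
    id = if (is.null(names(ellipses))) seq_along(ellipses) else names(ellipses),
    cx = vapply(ellipses, `[[`, numeric(1), "cx"),
    cy = vapply(ellipses, `[[`, numeric(1), "cy"),
    length = vapply(ellipses, `[[`, numeric(1), "length"),
    width = vapply(ellipses, `[[`, numeric(1), "width"),
    orientation_deg = vapply(ellipses, `[[`, numeric(1), "orientation"),
    aspect = vapply(ellipses, `[[`, numeric(1), "aspect"))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(ellipses)
}
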