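test_that("single-hexel ellipse has the closed-form size", {
  for (s in c(1, 1 / sqrt(3), 2.5)) {
    e <- ellipse_fit(hexel_map(2, -1, 7), s = s)
    expect_equal(e$length, s * sqrt(5 / 3), tolerance = 1e-12)
    expect_equal(e$width, s * sqrt(5 / 3), tolerance = 1e-12)
    expect_equal(e$aspect, 1)
    expect_true(e$degenerate)
    expect_equal(e$orientation, 0)
  }
  expect_error(ellipse_fit(hexel_map()), "positive total weight")
})

test_that("two equal hexels one lattice constant apart along v", {
  # sigma_max^2 = a^2/4 + 5a^2/36, sigma_min^2 = 5a^2/36 (a = 1)
  e <- ellipse_fit(hexel_map(c(0, 1), c(0, 1), c(3, 3)), s = 1 / sqrt(3))
  expect_equal(e$length, 2 * sqrt(7 / 18), tolerance = 1e-12)
  expect_equal(e$width, 2 * sqrt(5 / 36), tolerance = 1e-12)
  expect_equal(e$orientation, 0)
  expect_equal(e$aspect, sqrt(14 / 5), tolerance = 1e-12)
})

test_that("k collinear hexels match the closed form and a brute-force covariance", {
  for (k in c(2, 3, 5)) {
    for (axis in c("v", "p", "q")) {
      step <- hex_axis_step(axis)
      j <- (0:(k - 1)) - floor((k - 1) / 2)
      m <- hexel_map(j * step[1], j * step[2], rep(2, k))
      e <- ellipse_fit(m)
      expect_equal(e$aspect, bar_aspect_theory(k), tolerance = 1e-12)
      expect_equal(e$orientation, hex_axis_angle(axis))
      # independent brute-force covariance eigenvalues (a = 1, s = 1/sqrt(3))
      xy <- hex_to_cart(m$p, m$q)
      pr <- m$value / sum(m$value)
      mu <- colSums(pr * xy)
      d <- sweep(xy, 2, mu)
      C <- t(d) %*% (pr * d) + 5 * (1 / sqrt(3))^2 / 12 * diag(2)
      ev <- sort(eigen(C)$values, decreasing = TRUE)
      expect_equal(e$length, 2 * sqrt(ev[1]), tolerance = 1e-12)
      expect_equal(e$width, 2 * sqrt(ev[2]), tolerance = 1e-12)
    }
  }
})

test_that("ellipse is equivariant under 60-degree lattice rotation", {
  set.seed(4)
  m <- hexel_map(sample(-3:3, 6, TRUE), sample(-3:3, 6, TRUE), runif(6, 1, 5))
  e0 <- ellipse_fit(m)
  # rotate by -60 deg: unit steps map p(1,0)->v(1,1), v(1,1)->q(0,1),
  # q(0,1)->(-1,0); linear map (p,q) -> (p - q, p)
  mr <- hexel_map(m$p - m$q, m$p, m$value)
  er <- ellipse_fit(mr)
  expect_equal(er$length, e0$length, tolerance = 1e-9)
  expect_equal(er$width, e0$width, tolerance = 1e-9)
  expect_equal(er$aspect, e0$aspect, tolerance = 1e-9)
  expect_equal(axial_diff_deg(er$orientation, e0$orientation - 60), 0,
               tolerance = 1e-9)
})

test_that("ellipse is translation-invariant up to the centroid", {
  set.seed(5)
  m <- hexel_map(sample(-3:3, 5, TRUE), sample(-3:3, 5, TRUE), runif(5, 1, 4))
  e0 <- ellipse_fit(m)
  e1 <- ellipse_fit(shift_map(m, 3, -2))
  d <- hex_to_cart(3, -2)
  expect_equal(e1$cx, e0$cx + d[1], tolerance = 1e-12)
  expect_equal(e1$cy, e0$cy + d[2], tolerance = 1e-12)
  expect_equal(e1$length, e0$length, tolerance = 1e-12)
  expect_equal(e1$width, e0$width, tolerance = 1e-12)
  expect_equal(e1$orientation, e0$orientation, tolerance = 1e-12)
})

test_that("gaussian width conventions relate as 2 sigma and ~2.4 sigma", {
  sigma <- 1.7
  w2 <- gaussian_width(sigma, "two_sigma")
  # at half the 2-sigma width from the peak, a Gaussian is at exp(-1/2)
  g <- function(x) exp(-x^2 / (2 * sigma^2))
  expect_equal(g(w2 / 2), exp(-0.5), tolerance = 1e-12)
  wf <- gaussian_width(sigma, "fwhm")
  expect_equal(g(wf / 2), 0.5, tolerance = 1e-12)
  expect_equal(wf / sigma, 2 * sqrt(2 * log(2)), tolerance = 1e-12)
})

test_that("cardinal projections group, smooth and conserve mass", {
  # single hexel: one bin at 0 with the full weight
  pr <- project_cardinal(hexel_map(0, 0, 3), "v")
  expect_equal(pr$value[pr$coordinate == 0], 3)
  expect_equal(sum(pr$value), 3)

  # hexels (0,0) and (1,1) along v: keys 0 and 2 -> bins at 0 and 1
  pr2 <- project_cardinal(hexel_map(c(0, 1), c(0, 1), c(2, 2)), "v")
  expect_equal(pr2$value[pr2$coordinate == 0], 2)
  expect_equal(pr2$value[pr2$coordinate == 1], 2)

  # odd keys split between adjacent even bins; totals conserved
  set.seed(6)
  m <- hexel_map(sample(-4:4, 8, TRUE), sample(-4:4, 8, TRUE), runif(8, 0.5, 3))
  for (axis in c("v", "p", "q")) {
    pr <- project_cardinal(m, axis)
    expect_equal(sum(pr$value), map_total(m), tolerance = 1e-12)
  }
})

test_that("orthogonal projections group without smoothing", {
  pr <- project_orthogonal(hexel_map(2, 3, 5), "h")
  expect_equal(pr$coordinate, 1)
  expect_equal(pr$value, 5)
  # a bar along v is a single transverse bin at 0
  bar <- hexel_map(-2:2, -2:2, rep(1, 5))
  prh <- project_orthogonal(bar, "h")
  expect_equal(prh$coordinate, 0)
  expect_equal(prh$value, 5)
  set.seed(7)
  m <- hexel_map(sample(-4:4, 6, TRUE), sample(-4:4, 6, TRUE), runif(6, 1, 2))
  for (axis in c("h", "p_perp", "q_perp"))
    expect_equal(sum(project_orthogonal(m, axis)$value), map_total(m))
})

test_that("a cardinal bar projects long longitudinally, one bin transversely", {
  k <- 5
  bar <- hexel_map(0:(k - 1), 0:(k - 1), rep(1, k))
  long <- project_cardinal(bar, "v")
  expect_equal(sum(long$value > 0), k)
  trans <- project_orthogonal(bar, "h")
  expect_equal(sum(trans$value > 0), 1)
})

test_that("projection stats average aligned cells with population sd", {
  p1 <- project_cardinal(hexel_map(0, 0, 2), "v")
  p2 <- project_cardinal(hexel_map(0, 0, 4), "v")
  st <- projection_stats(list(p1, p2))
  expect_equal(st$value[st$coordinate == 0], 3)
  expect_equal(st$sd[st$coordinate == 0], 1)
  # identical projections -> sd 0
  st2 <- projection_stats(list(p1, p1, p1))
  expect_true(all(st2$sd == 0))
  # missing bins count as zero
  p3 <- project_cardinal(hexel_map(1, 1, 2), "v") # bin at 1
  st3 <- projection_stats(list(p1, p3))
  expect_equal(st3$value[st3$coordinate == 1], 1)
  expect_error(projection_stats(list(p1, project_cardinal(hexel_map(0, 0, 1),
                                                          "p"))),
               "different axes")
})

test_that("population summary flags outliers and wraps axial orientations", {
  mk <- function(orientation, aspect)
    structure(list(orientation = orientation, aspect = aspect),
              class = "hex_ellipse")
  same <- lapply(1:4, function(i) mk(10, 2))
  s <- population_summary(same)
  expect_equal(s$aspect$median, 2)
  expect_equal(s$aspect$q3 - s$aspect$q1, 0)
  expect_length(s$aspect$outliers, 0)

  s2 <- population_summary(lapply(c(1, 2, 3, 4, 100), function(a) mk(0, a)))
  expect_equal(s2$aspect$outliers, 100)
  expect_equal(s2$aspect$whisker_hi, 4)

  # orientations clustered at +-89 deg have an axial median near the
  # 90-degree boundary, not near 0
  s3 <- population_summary(lapply(c(89, -89, 88, -88, 89), function(o)
    mk(o, 2)))
  expect_true(axial_diff_deg(s3$orientation$median, 90) <= 2)
})

test_that("hexagon sampler has the uniform-hexagon second moments", {
  set.seed(12)
  xy <- sample_hexagon(2e5, s = 1)
  # per-axis variance of a unit-side regular hexagon is 5/24; the total
  # (2D) variance is 5/12, the constant used by the ellipse correction
  se <- stats::sd(xy[, 2]^2) / sqrt(nrow(xy))
  expect_lt(abs(var(xy[, 1]) - 5 / 24), 3 * se)
  expect_lt(abs(var(xy[, 2]) - 5 / 24), 3 * se)
  expect_lt(abs(mean(xy[, 1]^2 + xy[, 2]^2) - 5 / 12), 3 * sqrt(2) * se)
  # scaling: variance scales with s^2
  xy2 <- sample_hexagon(2e5, s = 2)
  expect_lt(abs(var(xy2[, 1]) - 4 * 5 / 24), 12 * se)
})
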