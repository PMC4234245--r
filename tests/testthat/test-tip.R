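# analytic expanding target wave (concentric circular isolines)
target_movie <- function(n = 60, nt = 40, speed = 1, width = 6) {
  ctr <- (n + 1) / 2
  xm <- matrix(seq_len(n), n, n)
  ym <- matrix(seq_len(n), n, n, byrow = TRUE)
  r <- sqrt((xm - ctr)^2 + (ym - ctr)^2)
  fr <- array(0, c(n, n, nt))
  for (k in seq_len(nt)) {
    z <- (speed * k - r) / width
    fr[, , k] <- pmin(pmax(z, 0), 1)
  }
  voltage_movie(fr, 1, grid_spec(n, n, 1, 1, small_ok = TRUE), "target")
}

test_that("planar and target waves yield (essentially) empty trajectories", {
  tp <- track_tip(planar_movie(nx = 50, ny = 50, nt = 40, v0 = 0, v1 = 1),
                  v_iso = 0.5)
  expect_lte(nrow(tp$points), 2)
  tt <- track_tip(target_movie(), v_iso = 0.5)
  expect_lte(nrow(tt$points), 2)
})

test_that("the FHN rigid-spiral trajectory is a circle", {
  tip <- track_tip(fhn_movie())
  fc <- fit_circle(tip)
  expect_lt(max(abs(fc$residuals)), 0.1 * fc$radius)
  # nearby iso-levels localize the same core
  tip2 <- track_tip(fhn_movie(), v_iso = 0.4)
  c1 <- colMeans(tip$points[, c("x", "y")])
  c2 <- colMeans(tip2$points[, c("x", "y")])
  expect_lt(sqrt(sum((c1 - c2)^2)), 0.05 * (2 * fc$radius))
})

test_that("wavefront mask selects the depolarizing half-max band", {
  # moving 10-node linear upstroke; band = half-max +/- 10% of range
  mv <- planar_movie(nx = 40, ny = 8, nt = 20, v0 = 0, v1 = 1, width = 10,
                     speed = 1)
  m <- wavefront_mask(mv, 10)
  expect_true(all(m[, 1] == m[, 5]))           # y-invariant
  sel <- which(m[, 4])
  v <- mv$frames[, 4, 10]
  expect_true(all(v[sel] >= 0.4 & v[sel] <= 0.6))
  # nodes within the band: ~2 of the 10 ramp nodes
  expect_gte(length(sel), 1)
  expect_lte(length(sel), 3)
  # resting tissue -> flat movie error / all-false for one flat frame
  flat <- voltage_movie(array(0, c(10, 10, 4)), 1,
                        grid_spec(10, 10, 1, 1, small_ok = TRUE))
  expect_error(wavefront_mask(flat, 2), "flat")
  # repolarizing back (dv/dt < 0) is excluded
  fr <- mv$frames[, , 20:1]                   # time-reversed: wave recedes
  mvr <- voltage_movie(fr, 1, mv$grid)
  mr <- wavefront_mask(mvr, 10)
  vr <- mvr$frames[, 4, 10]
  in_band <- vr >= 0.4 & vr <= 0.6
  expect_true(any(in_band))
  expect_false(any(mr[in_band, 4]))
})

test_that("propagation direction follows the -grad(v) convention", {
  mvx <- planar_movie(nx = 40, ny = 40, nt = 30, v0 = 0, v1 = 1, width = 8)
  dx_ <- propagation_direction(mvx, 15)
  expect_gt(nrow(dx_), 0)
  expect_true(all(abs(dx_$psi) < 0.05))
  expect_lt(circ_spread(dx_$psi), 0.01)
  mvy <- planar_movie(nx = 40, ny = 40, nt = 30, v0 = 0, v1 = 1, width = 8,
                      axis = "y")
  dy_ <- propagation_direction(mvy, 15)
  expect_true(all(abs(dy_$psi - pi / 2) < 0.05))
  # circular wave: psi equals the polar angle about the source
  mt <- target_movie(n = 61, nt = 40, width = 8)
  dt_ <- propagation_direction(mt, 25)
  ang <- atan2(dt_$y - 31, dt_$x - 31)
  dpsi <- atan2(sin(dt_$psi - ang), cos(dt_$psi - ang))
  expect_lt(max(abs(dpsi)), 0.1)
})

test_that("meridian scatter is uniform for a planar wave", {
  mv <- planar_movie(nx = 50, ny = 30, nt = 40, v0 = 0, v1 = 1, width = 8)
  sc <- meridian_direction_scatter(mv, "horizontal", offset = 15,
                                   window = c(0, 1))
  expect_gt(nrow(sc), 10)
  expect_lt(diff(range(sc$psi)), 0.05)
  pr <- meridian_spread_profile(sc, 50, min_n = 2)
  expect_true(all(pr[!is.na(pr)] < 0.01))
})

test_that("trajectory geometry helpers are exact on known shapes", {
  ang <- seq(0, 2 * pi, length.out = 101)[-101]
  circ <- data.frame(t = seq_along(ang), x = 5 + 3 * cos(ang),
                     y = -2 + 3 * sin(ang))
  fc <- fit_circle(circ)
  expect_equal(unname(fc$center), c(5, -2), tolerance = 1e-9)
  expect_equal(fc$radius, 3, tolerance = 1e-9)
  expect_equal(meander_area(circ), pi * 9, tolerance = 0.01 * pi * 9)
  tri <- data.frame(t = 1:3, x = c(0, 4, 0), y = c(0, 0, 3))
  expect_equal(meander_area(tri), 6)
  expect_equal(hull_distance(tri, 1, 1), 0)
  expect_equal(hull_distance(tri, -3, 0), 3)
  expect_equal(tip_distance(tri, 5, 0), 1)
  empty <- structure(list(points = data.frame(t = numeric(0),
                                              x = numeric(0),
                                              y = numeric(0))),
                     class = "tip_trajectory")
  expect_equal(tip_distance(empty, 0, 0), Inf)
  expect_equal(meander_area(empty), 0)
})
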