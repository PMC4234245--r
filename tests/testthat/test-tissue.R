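test_that("grid_spec validates its invariants", {
  expect_error(grid_spec(30, 30, 0.5, 1), "nx, ny >= 50")
  g <- grid_spec(30, 30, 0.5, 1, small_ok = TRUE)
  expect_s3_class(g, "grid_spec")
  expect_error(grid_spec(60, 60, 0, 1))
  m <- cell_model("fhn")
  st <- resting_tissue(grid_spec(60, 60, 0.5, 1), m)
  # CFL bound: dx^2/(4D) = 0.0625
  expect_error(simulate_tissue(st, m, grid_spec(60, 60, 0.5, 1),
                               duration = 1, dt = 0.1), "stability bound")
})

test_that("spiral-initiation phase field follows frac(k phi/2pi + r/lambda)", {
  g <- grid_spec(50, 50, 0.5, 1)
  th <- initial_phase_field(g, center = c(25, 25), k = 1, wavelength = Inf)
  expect_true(all(th >= 0 & th < 1))
  # node at polar angle pi: theta = 0.5
  expect_equal(th[1, 25], 0.5)
  # k = 2, phi = -pi/2 -> frac(2 * -0.25) = 0.5
  th2 <- initial_phase_field(g, center = c(25, 25), k = 2, wavelength = Inf)
  expect_equal(th2[25, 1], 0.5)
  # winding number: unwrapped phase around a loop enclosing the center
  ang <- seq(0, 2 * pi, length.out = 33)[-33]
  xs <- round(25 + 8 * cos(ang)); ys <- round(25 + 8 * sin(ang))
  vals <- th[cbind(xs, ys)]
  d <- diff(c(vals, vals[1]))
  d <- d - round(d)                      # unwrap modulo 1
  expect_equal(sum(d), 1, tolerance = 1e-9)
  # radial term advances phase with r
  th3 <- initial_phase_field(g, center = c(25, 25), k = 1, wavelength = 10)
  expect_false(isTRUE(all.equal(th3, th)))
  expect_error(initial_phase_field(g, center = c(100, 25)), "inside")
})

test_that("init_spiral paints library states; resting field stays resting", {
  m <- cell_model("fhn")
  g <- grid_spec(60, 60, 0.5, 1)
  lib <- build_cycle_library(m, pacing_cl = 200)
  st <- init_spiral(g, lib, theta_field = matrix(0, 60, 60))
  expect_equal(max(abs(sweep(st, 2, as.numeric(m$resting_state)))), 0,
               tolerance = 1e-3)
  # fixed point preserved by the integrator
  mv <- simulate_tissue(resting_tissue(g, m), m, g, duration = 50,
                        dt_sample = 5)
  expect_lt(max(abs(mv$frames - m$resting_state[["v"]])), 1e-6)
  # model/state mismatch
  expect_error(simulate_tissue(st, cell_model("lr91"), g, duration = 1),
               "mismatch")
})

test_that("conduction velocity scales as sqrt(D)", {
  m <- cell_model("fhn")
  lib <- build_cycle_library(m, pacing_cl = 200)
  cv <- function(D, dt) {
    g <- grid_spec(200, 5, 0.5, D, small_ok = TRUE)
    st <- planar_wave_state(g, lib, extent = 60, span = 0.3)
    mv <- simulate_tissue(st, m, g, duration = 200, dt = dt, dt_sample = 1)
    nf <- dim(mv$frames)[3]
    crossing <- function(i) {
      tr <- mv$frames[i, 3, ]
      k <- which(tr[-1] > 0.5 & tr[-nf] <= 0.5)[1]
      mv$t[k + 1]
    }
    (180 - 100) * 0.5 / (crossing(180) - crossing(100))
  }
  ratio <- cv(2, 0.025) / cv(1, 0.025)
  expect_equal(ratio, sqrt(2), tolerance = 0.05)
})

test_that("halving dt changes the LR91 solution by < 1 mV", {
  m <- cell_model("lr91", params = list(gsi = 0.043))
  g <- grid_spec(60, 5, 0.025, 3e-4, small_ok = TRUE)
  lib <- build_cycle_library(m, pacing_cl = 400)
  st <- planar_wave_state(g, lib, extent = 30, span = 0.3)
  run <- function(dt) simulate_tissue(st, m, g, duration = 60, dt = dt,
                                      dt_sample = 60)
  v1 <- run(0.02)$frames
  v2 <- run(0.01)$frames
  expect_lt(max(abs(v1[, , dim(v1)[3]] - v2[, , dim(v2)[3]])), 1)
})

test_that("no-flux boundaries preserve mirror symmetry", {
  m <- cell_model("fhn")
  g <- grid_spec(60, 61, 0.5, 1)
  st <- resting_tissue(g, m)
  v <- matrix(st[, 1], 60, 61)
  v[25:35, 29:33] <- 1            # symmetric about row j = 31
  st[, 1] <- as.vector(v)
  mv <- simulate_tissue(st, m, g, duration = 60, dt_sample = 10)
  for (k in seq_len(dim(mv$frames)[3])) {
    fr <- mv$frames[, , k]
    expect_lt(max(abs(fr - fr[, 61:1])), 1e-6)
  }
})

test_that("the FHN spiral rotates rigidly with a stable period", {
  mv <- fhn_movie()
  tip <- track_tip(mv)
  expect_gt(nrow(tip$points), 0.9 * dim(mv$frames)[3])
  fc <- fit_circle(tip)
  expect_lt(max(abs(fc$residuals)), 0.1 * fc$radius)
  # period per rotation constant to 2%
  a <- atan2(tip$points$y - fc$center[2], tip$points$x - fc$center[1])
  ua <- cumsum(c(a[1], atan2(sin(diff(a)), cos(diff(a)))))
  rot <- abs(ua - ua[1]) / (2 * pi)
  tms <- vapply(seq_len(floor(max(rot))),
                function(r) tip$points$t[which(rot >= r)[1]], numeric(1))
  periods <- diff(tms)
  expect_lt(diff(range(periods)) / mean(periods), 0.02)
  # rigid rotation: centroid drift per rotation < 2% of core radius
  ctrs <- t(vapply(seq_len(length(tms) - 1), function(r) {
    sel <- tip$points$t >= tms[r] & tip$points$t < tms[r + 1]
    colMeans(as.matrix(tip$points[sel, c("x", "y")]))
  }, numeric(2)))
  drift <- max(sqrt(diff(ctrs[, 1])^2 + diff(ctrs[, 2])^2))
  expect_lt(drift, 0.02 * fc$radius * 2)
})

test_that("mirrored phase field reverses the spiral chirality", {
  m <- cell_model("fhn")
  g <- grid_spec(90, 90, 0.5, 1)
  lib <- build_cycle_library(m, pacing_cl = 200)
  spin <- function(k) {
    mv <- simulate_rotor(m, g, duration = 250, settle = 120, dt_sample = 1,
                         k = k, library = lib)
    tip <- track_tip(mv)
    ctr <- colMeans(tip$points[, c("x", "y")])
    a <- atan2(tip$points$y - ctr[2], tip$points$x - ctr[1])
    sum(atan2(sin(diff(a)), cos(diff(a))))
  }
  s1 <- spin(1); s2 <- spin(-1)
  expect_gt(abs(s1), pi)          # at least half a rotation observed
  expect_lt(s1 * s2, 0)           # opposite angular order
})

test_that("movie_window crops frames and times consistently", {
  mv <- planar_movie(nt = 50)
  w <- movie_window(mv, c(0.2, 1))
  expect_equal(dim(w$frames)[3], 40)
  expect_equal(w$t[1], mv$t[11])
})
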