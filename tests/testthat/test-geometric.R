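test_that("the analytic spiral is rigidly rotating and Archimedean", {
  sp <- geo_spiral_spec()
  period <- 2 * pi / sp$omega
  set.seed(61)
  pts <- matrix(runif(40, -30, 30), ncol = 2)
  # rigid rotation: exact temporal periodicity at every fixed point
  v1 <- spiral_voltage(sp, pts[, 1], pts[, 2], 13.7)
  v2 <- spiral_voltage(sp, pts[, 1], pts[, 2], 13.7 + period)
  expect_equal(v1, v2, tolerance = 1e-12)
  # rotating the point by theta equals shifting time by -theta/omega
  th <- 0.9
  rot <- cbind(cos(th) * pts[, 1] - sin(th) * pts[, 2],
               sin(th) * pts[, 1] + cos(th) * pts[, 2])
  va <- spiral_voltage(sp, rot[, 1], rot[, 2], 5)
  vb <- spiral_voltage(sp, pts[, 1], pts[, 2], 5 + th / sp$omega)
  expect_equal(va, vb, tolerance = 1e-12)
  # consecutive front crossings along a radial ray are one pitch apart
  r <- seq(2, 40, by = 0.01)
  v <- spiral_voltage(sp, r, rep(0, length(r)), 0)
  up <- which(v[-1] > 0.5 & v[-length(v)] <= 0.5)
  expect_equal(diff(r[up]), rep(sp$a, length(up) - 1), tolerance = 0.02)
  # constant-gradient front: max |grad v| = v_amp / front_width
  eps <- 1e-4
  g <- max(abs(spiral_voltage(sp, r + eps, rep(0, length(r)), 0) - v) / eps)
  expect_equal(g, sp$v_amp / sp$front_width, tolerance = 0.01)
})

test_that("geo_spiral_spec and geo_movie validate their inputs", {
  expect_error(geo_spiral_spec(front_width = 5, a = 4))
  expect_error(geo_movie(geo_spiral_spec(front_width = 0.2), mesh = 0.25),
               "finer")
})

# small-extent configuration used by the remaining checks (cheap)
mini_geo <- function() cached("mini_geo", function() {
  sp <- geo_spiral_spec(arm_extent = 14)
  mv <- geo_movie(sp, mesh = 0.25,
                  t_grid = seq(0, 200, length.out = 101)[-101])
  list(sp = sp, mv = mv)
})

test_that("geometric unipolar electrograms decay with elevation and are
           periodic", {
  mg <- mini_geo()
  u1 <- geo_unipolar(mg$sp, -0.5, 0, h = 0.5, movie = mg$mv)
  u2 <- geo_unipolar(mg$sp, -0.5, 0, h = 1, movie = mg$mv)
  expect_gt(max(abs(u1$samples)), max(abs(u2$samples)))
  # 2 pi / omega periodicity (t_grid covers exactly two rotations)
  half <- length(u1$samples) / 2
  expect_lt(max(abs(u1$samples[1:half] - u1$samples[half + 1:half])),
            1e-6 * max(abs(u1$samples)))
})

test_that("a far electrode is dominated by the rotation fundamental", {
  mg <- mini_geo()
  u <- geo_unipolar(mg$sp, 11, 0, h = 0.5, movie = mg$mv)
  x <- u$samples - mean(u$samples)
  pw <- Mod(fft(x))^2
  n <- length(x)
  # two rotations in the window: fundamental at bin 3, harmonic at bin 5
  keep <- 2:(n / 2)
  frac <- sum(pw[c(3, 5)]) / sum(pw[keep])
  expect_gte(frac, 0.8)
})

test_that("bipolar amplitude vanishes linearly as spacing goes to zero", {
  mg <- mini_geo()
  uf <- unipolar_field(mg$mv, h = 2, source_mode = "voltage")
  site <- nearest_site(uf, round((6 + 14) / 0.25), round(14 / 0.25))
  p2p <- function(s) {
    bf <- bipolar_field(uf, s, "horizontal")
    diff(range(bf$data[site[1], site[2], ]))
  }
  expect_equal(p2p(2) / p2p(1), 2, tolerance = 0.1)
})

test_that("zero crossings are counted as strict sign changes", {
  expect_equal(zero_crossings(c(1, -1, 1, -1)), 3)
  expect_equal(zero_crossings(c(1, 0, -1)), 1)
  expect_equal(zero_crossings(c(2, 3, 1)), 0)
})
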