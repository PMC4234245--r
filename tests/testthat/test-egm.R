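test_that("FFT unipolar field equals the brute-force double sum", {
  set.seed(7)
  for (mode in c("laplacian", "voltage")) {
    for (n in c(5, 20)) {
      fr <- array(rnorm(n * n * 2), c(n, n, 2))
      g <- grid_spec(n, n, 0.3, 1, small_ok = TRUE)
      mv <- voltage_movie(fr, dt_sample = 1, g)
      uf <- unipolar_field(mv, h = 1, source_mode = mode)
      for (k in 1:2) {
        expect_lt(max(abs(uf$data[, , k] -
                          brute_unipolar(fr[, , k], 0.3, 1, mode))), 1e-10)
      }
    }
  }
})

test_that("uniform voltage has zero current-source electrogram", {
  fr <- array(0.37, c(12, 12, 3))
  mv <- voltage_movie(fr, 1, grid_spec(12, 12, 1, 1, small_ok = TRUE))
  uf <- unipolar_field(mv, h = 1, source_mode = "laplacian")
  expect_lt(max(abs(uf$data)), 1e-10)
})

test_that("a point source obeys 1/r geometry with the elevation offset", {
  fr <- array(0, c(21, 21, 1))
  fr[11, 11, 1] <- 1
  mv <- voltage_movie(fr, 1, grid_spec(21, 21, 1, 1, small_ok = TRUE))
  uf <- unipolar_field(mv, h = 1, source_mode = "voltage")
  # directly above: r = h; laterally offset by 2h: r = h sqrt(5)
  expect_equal(uf$data[11, 11, 1] / uf$data[13, 11, 1], sqrt(5),
               tolerance = 1e-10)
})

test_that("the forward model is linear in the voltage field", {
  set.seed(11)
  g <- grid_spec(15, 15, 0.5, 1, small_ok = TRUE)
  v1 <- array(rnorm(15 * 15 * 2), c(15, 15, 2))
  v2 <- array(rnorm(15 * 15 * 2), c(15, 15, 2))
  for (mode in c("laplacian", "voltage")) {
    u1 <- unipolar_field(voltage_movie(v1, 1, g), h = 1, source_mode = mode)
    u2 <- unipolar_field(voltage_movie(v2, 1, g), h = 1, source_mode = mode)
    u12 <- unipolar_field(voltage_movie(2 * v1 - 3 * v2, 1, g), h = 1,
                          source_mode = mode)
    expect_lt(max(abs(u12$data - (2 * u1$data - 3 * u2$data))), 1e-9)
  }
})

test_that("electrode elevation is required and spacing must fit", {
  mv <- planar_movie(nx = 20, ny = 20, nt = 5)
  expect_error(unipolar_field(mv, h = 0), "singularity")
  uf <- unipolar_field(mv, h = 1)
  expect_error(bipolar_field(uf, 20, "horizontal"), "exceeds")
  expect_error(bipolar_field(uf, -1), ">= 0")
})

test_that("bipolar field is the spaced difference with midpoint sites", {
  mv <- planar_movie(nx = 24, ny = 20, nt = 6)
  uf <- unipolar_field(mv, h = 1)
  # s = 0: identically zero
  b0 <- bipolar_field(uf, 0, "horizontal")
  expect_true(all(b0$data == 0))
  expect_equal(dim(b0$data), dim(uf$data))
  # direct difference + cropping + midpoint registration
  b3 <- bipolar_field(uf, 3, "horizontal")
  expect_equal(dim(b3$data)[1], 21)
  expect_equal(b3$data[5, 7, ], uf$data[5, 7, ] - uf$data[8, 7, ])
  expect_equal(b3$sites_x[5], 5 + 1.5)
  bv <- bipolar_field(uf, 2, "vertical")
  expect_equal(bv$data[4, 6, ], uf$data[4, 6, ] - uf$data[4, 8, ])
  expect_equal(bv$sites_y[6], 7)
  # identical unipolar traces at both poles -> zero bipolar
  ufc <- uf
  ufc$data <- array(rep(uf$data[1, , ], each = dim(uf$data)[1]),
                    dim(uf$data))            # x-uniform unipolar field
  bc <- bipolar_field(ufc, 2, "horizontal")
  expect_true(all(bc$data == 0))
})

test_that("rotating the movie 90 degrees and swapping orientation transposes", {
  set.seed(3)
  fr <- array(rnorm(18 * 18 * 3), c(18, 18, 3))
  g <- grid_spec(18, 18, 0.4, 1, small_ok = TRUE)
  u1 <- unipolar_field(voltage_movie(fr, 1, g), h = 1)
  b1 <- bipolar_field(u1, 2, "horizontal")
  frt <- aperm(fr, c(2, 1, 3))
  u2 <- unipolar_field(voltage_movie(frt, 1, g), h = 1)
  b2 <- bipolar_field(u2, 2, "vertical")
  expect_lt(max(abs(b2$data - aperm(b1$data, c(2, 1, 3)))), 1e-10)
})

test_that("egm_trace carries its configuration", {
  mv <- planar_movie(nx = 20, ny = 20, nt = 5)
  uf <- unipolar_field(mv, h = 2, source_mode = "voltage")
  bf <- bipolar_field(uf, 4, "vertical")
  tr <- egm_trace(bf, 3, 5)
  expect_s3_class(tr, "egm_trace")
  expect_equal(length(tr$samples), 5)
  expect_equal(tr$config$spacing_s, 4L)
  expect_equal(tr$config$height_h, 2)
  expect_equal(tr$config$position[["y"]], bf$sites_y[5])
  expect_equal(nearest_site(bf, 3.2, bf$sites_y[5]), c(3, 5))
})
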