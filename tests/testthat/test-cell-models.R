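test_that("resting states are fixed points of every model", {
  for (nm in c("fhn", "lr91", "crn")) {
    m <- cell_model(nm, quiet = TRUE)
    expect_lt(max(abs(model_rhs(m, m$resting_state))), 1e-3)
  }
})

test_that("FHN right-hand side matches the cubic form", {
  m <- cell_model("fhn")
  expect_equal(unname(model_rhs(m, c(0, 0))), c(0, 0))
  # v = 1 is a root of v (v - a)(1 - v)
  expect_equal(model_rhs(m, c(1, 0))[["v"]], 0)
  # suprathreshold growth at v = 0.5: 0.5 * 0.4 * 0.5 = 0.1
  expect_equal(model_rhs(m, c(0.5, 0))[["v"]], 0.1)
  expect_error(model_rhs(m, c(NaN, 0)), "non-finite")
})

test_that("LR91 Gsi controls the slow-inward current and the APD", {
  expect_error(cell_model("lr91", params = list(gsi = -0.01)),
               "non-negative")
  # Gsi = 0: dV/dt is independent of the d and f gates
  m0 <- cell_model("lr91", params = list(gsi = 0))
  s1 <- m0$resting_state; s2 <- s1
  s1[c("d", "f")] <- c(0.2, 0.9); s2[c("d", "f")] <- c(0.9, 0.1)
  expect_equal(model_rhs(m0, s1)[["V"]], model_rhs(m0, s2)[["V"]],
               tolerance = 1e-12)
  # dCai still sees Isi = 0
  expect_equal(model_rhs(m0, s1)[["Cai"]],
               0.07 * (1e-4 - s1[["Cai"]]), tolerance = 1e-10)

  # single-cell APD90 is non-decreasing in Gsi over the shipped sweep
  apds <- vapply(c(0, 0.02, 0.03, 0.043), function(g) {
    m <- cell_model("lr91", params = list(gsi = g))
    r <- pace_cell(m, cl = 400, n_beats = 4, record_dt = 0.5)
    keep <- r$time > 1200
    apd90(r$time[keep], r$states[1, keep])
  }, numeric(1))
  expect_true(all(diff(apds) > 0))
  expect_gt(apds[4], apds[1])   # Gsi = 0.043 prolongs vs Gsi = 0
})

test_that("CRN scale factors of one reproduce the published model", {
  expect_message(cell_model("crn"), "unmodified")
  m1 <- cell_model("crn", quiet = TRUE)
  m2 <- cell_model("crn", params = list(s_cal = 1, s_to = 1, s_kur = 1))
  set.seed(42)
  for (i in 1:25) {
    st <- m1$resting_state
    st[1] <- runif(1, -80, 20)
    st[2:13] <- pmin(pmax(st[2:13] + runif(12, -0.05, 0.05), 0), 1)
    st[14] <- runif(1, 5e-5, 1e-3)
    expect_equal(model_rhs(m1, st), model_rhs(m2, st), tolerance = 1e-12)
  }
})

test_that("gate variables stay in [0, 1] during paced APs", {
  for (nm in c("lr91", "crn")) {
    m <- cell_model(nm, quiet = TRUE)
    r <- pace_cell(m, cl = 400, n_beats = 1, record_dt = 0.5)
    gates <- switch(nm, lr91 = 2:7, crn = c(2:13, 19:21))
    expect_true(all(r$states[gates, ] >= 0 & r$states[gates, ] <= 1))
    expect_true(all(r$states[1, ] > -100 & r$states[1, ] < 70))
  }
})

test_that("cycle libraries are phase-indexed action-potential cycles", {
  m <- cell_model("fhn")
  lib <- build_cycle_library(m, pacing_cl = 200)
  expect_s3_class(lib, "cycle_library")
  expect_gte(length(lib$theta), 100)
  expect_true(!is.unsorted(lib$theta))
  # theta = 0 is the resting state
  expect_equal(unname(lib$states[1, ]), c(0, 0), tolerance = 1e-3)
  # theta = 1 carries (close to) the maximal upstroke velocity
  dvdts <- apply(lib$states, 1, function(s) model_rhs(m, s)[["v"]])
  expect_gte(dvdts[length(dvdts)], 0.95 * max(dvdts))

  mlr <- cell_model("lr91")
  liblr <- build_cycle_library(mlr, pacing_cl = 500)
  vr <- range(liblr$states[, 1])
  expect_lt(vr[1], -80)
  expect_gt(vr[2], 10)

  # interpolation: endpoints and midpoints behave
  expect_equal(library_interp(lib, c(0, 1)),
               lib$states[c(1, nrow(lib$states)), ], ignore_attr = TRUE)
  expect_error(library_interp(lib, 1.2), "\\[0, 1\\]")
})

test_that("pacing that never settles raises a diagnostic error", {
  m <- cell_model("fhn")
  expect_error(build_cycle_library(m, pacing_cl = 200, budget_beats = 1),
               "no periodic steady state")
})
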