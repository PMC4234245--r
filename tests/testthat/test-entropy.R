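test_that("amplitude histograms follow the bin-fraction rule", {
  x <- c(-1, -0.5, 0.001, 0.5, 1)
  p <- amplitude_histogram(x, histogram_spec(bin_fraction = 0.25))
  expect_equal(attr(p, "n_bins"), 8L)
  expect_equal(sum(p > 0), 5)
  expect_equal(unname(p[p > 0]), rep(0.2, 5))
  # hand-binning oracle on random traces
  set.seed(21)
  for (i in 1:20) {
    y <- rnorm(300)
    bf <- sample(c(0.01, 0.02, 0.1, 0.25), 1)
    p1 <- amplitude_histogram(y, histogram_spec(bin_fraction = bf))
    expect_equal(as.numeric(p1), brute_histogram(y, bf), tolerance = 1e-12)
    expect_equal(sum(p1), 1, tolerance = 1e-12)
  }
  # default rule: 1% bins over [-max, max] -> 200 bins
  expect_equal(attr(amplitude_histogram(rnorm(50)), "n_bins"), 200L)
})

test_that("degenerate traces are handled as specified", {
  # constant nonzero trace: exactly one occupied bin
  p <- amplitude_histogram(rep(0.7, 100), histogram_spec())
  expect_equal(sum(p > 0), 1)
  expect_equal(shannon_entropy(p), 0)
  # all-zero trace: p = [1] with a notice
  expect_message(p0 <- amplitude_histogram(rep(0, 10)), "all-zero")
  expect_equal(as.numeric(p0), 1)
  expect_equal(shannon_entropy(p0), 0)
  expect_error(amplitude_histogram(numeric(0)), "empty")
  expect_error(amplitude_histogram(c(1, NA)), "non-finite")
})

test_that("Shannon entropy has its closed-form values and bounds", {
  expect_equal(shannon_entropy(rep(0.25, 4)), 2)
  expect_equal(shannon_entropy(1), 0)
  expect_equal(shannon_entropy(c(0.5, 0.25, 0.25)), 1.5)
  expect_error(shannon_entropy(c(-0.1, 1.1)), "negative")
  set.seed(9)
  for (i in 1:50) {
    n <- sample(2:300, 1)
    p <- runif(n); p <- p / sum(p)
    H <- shannon_entropy(p)
    expect_gte(H, 0)
    expect_lte(H, log2(n) + 1e-12)
  }
})

test_that("per-trace entropy is invariant to amplitude rescaling", {
  set.seed(13)
  x <- rnorm(500)
  sp <- histogram_spec(reference = "per_trace")
  h1 <- shannon_entropy(amplitude_histogram(x, sp))
  h2 <- shannon_entropy(amplitude_histogram(137.5 * x, sp))
  expect_equal(h1, h2, tolerance = 1e-12)
})

test_that("entropy maps: constant fields, symmetry and margins", {
  mk_field <- function(data) {
    structure(list(data = data, fs = 1000, t = seq_len(dim(data)[3]) - 1,
                   dt_sample = 1, sites_x = seq_len(dim(data)[1]),
                   sites_y = seq_len(dim(data)[2]), kind = "bipolar",
                   h = 1, source_mode = "laplacian", spacing = 1L,
                   orientation = "horizontal",
                   grid = grid_spec(dim(data)[1], dim(data)[2], 1, 1,
                                    small_ok = TRUE), model_tag = "toy"),
              class = "egm_field")
  }
  # all-identical traces -> constant map
  tr <- sin(seq(0, 20, length.out = 200))
  f1 <- mk_field(array(rep(tr, each = 36), c(6, 6, 200)))
  m1 <- shen_map(f1, window = c(0, 1))
  expect_equal(diff(range(m1$values)), 0)
  # transposing the field transposes the map exactly
  set.seed(31)
  dat <- array(rnorm(8 * 5 * 150), c(8, 5, 150))
  m2 <- shen_map(mk_field(dat), window = c(0, 1))
  m3 <- shen_map(mk_field(aperm(dat, c(2, 1, 3))), window = c(0, 1))
  expect_equal(m3$values, t(m2$values))
  # bounds: 0 <= H <= log2(200)
  expect_true(all(m2$values >= 0 & m2$values <= log2(200)))
  # edge margin restricts the statistics but not the values
  m4 <- shen_map(mk_field(dat), window = c(0, 1), edge_margin = 1)
  expect_equal(m4$values, m2$values)
  expect_equal(m4$stats[["max"]], max(m2$values[2:7, 2:4]))
  am <- argmax_site(m4)
  expect_true(am[1] >= 2 && am[1] <= 7)
})

test_that("render_map clips to the median-max range and overlays the tip", {
  set.seed(41)
  dat <- array(rnorm(10 * 10 * 100), c(10, 10, 100))
  f <- structure(list(data = dat, fs = 1000, t = 0:99, dt_sample = 1,
                      sites_x = 1:10, sites_y = 1:10, kind = "bipolar",
                      h = 1, source_mode = "laplacian", spacing = 1L,
                      orientation = "horizontal",
                      grid = grid_spec(10, 10, 1, 1, small_ok = TRUE),
                      model_tag = "toy"), class = "egm_field")
  m <- shen_map(f, window = c(0, 1))
  tip <- structure(list(points = data.frame(t = 1:3, x = c(4, 5, 6),
                                            y = c(4, 4.5, 5))),
                   class = "tip_trajectory")
  png_file <- tempfile(fileext = ".png")
  out <- render_map(m, tip = tip, file = png_file)
  expect_true(file.exists(png_file))
  expect_equal(out$zlim[1], median(m$values))
  expect_equal(out$zlim[2], max(m$values))
  expect_equal(out$tip_xy$x, tip$points$x)
  # degenerate map: full-range fallback with a notice, no crash
  mc <- m
  mc$values[] <- 3
  mc$stats <- c(min = 3, median = 3, max = 3)
  f2 <- tempfile(fileext = ".png")
  expect_message(render_map(mc, file = f2), "degenerate")
})

test_that("median-band sites and their tip distances are computed", {
  set.seed(51)
  vals <- matrix(runif(100), 10, 10)
  m <- structure(list(values = vals, sites_x = 1:10, sites_y = 1:10,
                      spacing = 1L, orientation = "horizontal",
                      edge_margin = 0L,
                      stats = c(min = min(vals), median = median(vals),
                                max = max(vals))), class = "shen_map")
  tip <- structure(list(points = data.frame(t = 1, x = 5, y = 5)),
                   class = "tip_trajectory")
  d <- median_site_distances(m, tip, tol = 0.1)
  expect_true(length(d) >= 1)
  expect_true(all(is.finite(d)))
})
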