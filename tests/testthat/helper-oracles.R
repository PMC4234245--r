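# Independent oracles: deliberately simple, slow implementations used to
# cross-check the production code paths.

# brute-force O(N^2) unipolar field for one frame
brute_unipolar <- function(v, dx, h, source_mode = "laplacian") {
  nx <- nrow(v); ny <- ncol(v)
  S <- if (source_mode == "laplacian") -discrete_laplacian(v, dx) else v
  u <- matrix(0, nx, ny)
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    acc <- 0
    for (k in seq_len(nx)) for (l in seq_len(ny)) {
      r <- dx * sqrt((i - k)^2 + (j - l)^2 + h^2)
      acc <- acc + S[k, l] / r
    }
    u[i, j] <- acc
  }
  u
}

# hand-binned histogram (explicit loop over samples)
brute_histogram <- function(x, bin_fraction) {
  M <- max(abs(x))
  bw <- bin_fraction * M
  nb <- ceiling(2 / bin_fraction)
  counts <- numeric(nb)
  for (s in x) {
    b <- floor((s + M) / bw) + 1
    b <- min(max(b, 1), nb)
    counts[b] <- counts[b] + 1
  }
  counts / length(x)
}

# steady-state amplitude of a filtered sine.  Causal: measured late in the
# trace (after the startup transient); zero-phase: measured mid-trace (both
# ends carry the forward/backward edge transients).
sine_gain <- function(spec, f, fs = 1000, n_cycles = 60) {
  n <- max(4096, round(n_cycles * fs / f))
  t <- (0:(n - 1)) / fs
  y <- apply_filter(sin(2 * pi * f * t), spec, fs = fs)
  start <- if (spec$apply_mode == "causal") round(0.7 * n) else round(0.4 * n)
  spc <- fs / f                          # samples per cycle
  len <- floor(0.25 * n / spc) * spc     # whole number of cycles
  idx <- seq(start, start + len - 1)
  sqrt(2 * mean(y[idx]^2))               # RMS amplitude of the sine
}
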