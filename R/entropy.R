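#' Amplitude-histogram specification
#'
#' The histogram bin width is a fixed fraction (default 1%) of the
#' maximum EGM amplitude. With the default symmetric range
#' \[-max|w|, +max|w|\] this yields `2 / bin_fraction` = 200 bins.
#' `reference = "per_trace"` scales each trace by its own maximum, which
#' makes the entropy a pure morphology measure (invariant to amplitude);
#' `"global"` uses one maximum for a whole field.
#'
#' @param bin_fraction bin width as a fraction of the maximum amplitude
#'   (0 < bin_fraction <= 1; default 0.01).
#' @param reference `"per_trace"` or `"global"`.
#' @param range_mode `"symmetric_about_zero"` or `"min_to_max"`.
#' @return object of class `histogram_spec`.
#' @export
histogram_spec <- function(bin_fraction = 0.01,
                           reference = c("per_trace", "global"),
                           range_mode = c("symmetric_about_zero",
                                          "min_to_max")) {
  stopifnot(bin_fraction > 0, bin_fraction <= 1)
  structure(list(bin_fraction = bin_fraction,
                 reference = match.arg(reference),
                 range_mode = match.arg(range_mode)),
            class = "histogram_spec")
}

#' Amplitude histogram of an EGM trace
#'
#' Bins the sample amplitudes with bin width `bin_fraction * max|w|`
#' (or `bin_fraction` times the supplied global reference) and returns
#' relative frequencies: counts in each bin divided by the total count.
#'
#' An all-zero trace has no amplitude scale; it is assigned the single
#' occupied bin `p = 1` (entropy 0) with a notice.
#'
#' @param x an `egm_trace` or numeric vector.
#' @param spec a [histogram_spec()].
#' @param ref_max reference maximum amplitude for
#'   `reference = "global"`.
#' @return probability vector `p` (sums to 1) with attributes `breaks`
#'   and `n_bins`.
#' @export
amplitude_histogram <- function(x, spec = histogram_spec(), ref_max = NULL) {
  if (inherits(x, "egm_trace")) x <- x$samples
  if (!length(x)) stop("empty trace")
  if (anyNA(x) || any(!is.finite(x))) stop("non-finite samples in trace")
  M <- if (spec$reference == "global" && !is.null(ref_max)) ref_max
       else max(abs(x))
  if (M == 0) {
    message("all-zero trace: single occupied bin, entropy 0")
    p <- 1
    attr(p, "breaks") <- c(0, 0)
    attr(p, "n_bins") <- 1L
    return(p)
  }
  bw <- spec$bin_fraction * M
  if (spec$range_mode == "symmetric_about_zero") {
    lo <- -M
    nb <- as.integer(ceiling(2 / spec$bin_fraction - 1e-9))
  } else {
    lo <- min(x)
    nb <- max(1L, as.integer(ceiling((max(x) - lo) / bw - 1e-9)))
  }
  idx <- pmin(pmax(floor((x - lo) / bw) + 1, 1L), nb)
  counts <- tabulate(idx, nbins = nb)
  p <- counts / sum(counts)
  attr(p, "breaks") <- lo + bw * (0:nb)
  attr(p, "n_bins") <- nb
  p
}

#' Shannon entropy of a probability vector
#'
#' \deqn{H = -\sum_{i: p_i > 0} p_i \log_2 p_i} in bits; empty bins
#' contribute zero (the standard 0 log 0 = 0 convention).
#'
#' @param p probability vector (non-negative, summing to 1).
#' @return entropy in bits, in \[0, log2(length(p))\].
#' @export
shannon_entropy <- function(p) {
  p <- as.numeric(p)
  if (any(p < -1e-12)) stop("negative probabilities")
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Shannon entropy map of a bipolar EGM field
#'
#' Computes the per-site amplitude histogram and its Shannon entropy for
#' every bipole site, over an analysis window that excludes the initial
#' settling fraction of the recording.
#'
#' @param field a bipolar (or unipolar) `egm_field`.
#' @param spec a [histogram_spec()].
#' @param window fraction window of samples analysed (default final 80%).
#' @param edge_margin number of sites next to the sheet boundary to
#'   exclude from the map statistics (max/min/median and
#'   [argmax_site()]). The no-flux boundary and the truncated 1/r sum
#'   distort electrograms recorded at the very edge; the pipeline uses
#'   a 5-site margin. All site values are still computed and returned.
#' @return object of class `shen_map`: `values` (matrix of entropies in
#'   bits), `sites_x`, `sites_y`, `spacing`, `orientation`,
#'   `histogram_spec`, `window`, `edge_margin` and summary `stats`.
#' @export
shen_map <- function(field, spec = histogram_spec(), window = c(0.2, 1),
                     edge_margin = 0) {
  stopifnot(inherits(field, "egm_field"))
  d <- dim(field$data)
  idx <- seq(max(1L, floor(window[1] * d[3]) + 1L), floor(window[2] * d[3]))
  ref_max <- if (spec$reference == "global")
    max(abs(field$data[, , idx])) else NULL
  vals <- matrix(NA_real_, d[1], d[2])
  for (j in seq_len(d[2])) {
    for (i in seq_len(d[1])) {
      p <- suppressMessages(
        amplitude_histogram(field$data[i, j, idx], spec, ref_max = ref_max))
      vals[i, j] <- shannon_entropy(p)
    }
  }
  m <- min(edge_margin, (min(d[1], d[2]) - 1) %/% 3)
  vin <- vals[(1 + m):(d[1] - m), (1 + m):(d[2] - m)]
  structure(list(values = vals, sites_x = field$sites_x,
                 sites_y = field$sites_y, spacing = field$spacing,
                 orientation = field$orientation, histogram_spec = spec,
                 window = window, edge_margin = m,
                 stats = c(min = min(vin), median = median(vin),
                           max = max(vin))),
            class = "shen_map")
}

#' @export
print.shen_map <- function(x, ...) {
  cat("<shen_map>", nrow(x$values), "x", ncol(x$values), "sites",
      if (!is.na(x$spacing)) paste0("(s = ", x$spacing, ", ",
                                    x$orientation, ")"), "\n")
  cat("  ShEn bits: min", signif(x$stats["min"], 4),
      " median", signif(x$stats["median"], 4),
      " max", signif(x$stats["max"], 4), "\n")
  invisible(x)
}

#' Coordinates of the map maximum
#'
#' Respects the map's `edge_margin`: the arg-max is taken over interior
#' sites only.
#' @param map a `shen_map`.
#' @return `c(x, y)` node coordinates of the arg-max site.
#' @export
argmax_site <- function(map) {
  m <- if (is.null(map$edge_margin)) 0L else map$edge_margin
  d <- dim(map$values)
  vin <- map$values[(1 + m):(d[1] - m), (1 + m):(d[2] - m), drop = FALSE]
  ij <- arrayInd(which.max(vin), dim(vin)) + m
  c(x = map$sites_x[ij[1]], y = map$sites_y[ij[2]])
}

#' Sites whose entropy is near the map median, with distances to a
#' trajectory
#'
#' Utility for the "median-entropy sites lie farther from the pivot
#' than the arg-max" property.
#' @param map a `shen_map`.
#' @param tip a `tip_trajectory`.
#' @param tol half-width of the band around the median (bits).
#' @return numeric vector of distances (nodes) from each median-band
#'   site to the nearest trajectory point.
#' @export
median_site_distances <- function(map, tip, tol = 0.05) {
  m <- if (is.null(map$edge_margin)) 0L else map$edge_margin
  d <- dim(map$values)
  vin <- map$values[(1 + m):(d[1] - m), (1 + m):(d[2] - m), drop = FALSE]
  med <- median(vin)
  idx <- which(abs(vin - med) <= tol, arr.ind = TRUE)
  if (!nrow(idx)) idx <- arrayInd(which.min(abs(vin - med)), dim(vin))
  if (nrow(idx) > 400)                     # deterministic thinning
    idx <- idx[seq(1, nrow(idx), length.out = 400), , drop = FALSE]
  vapply(seq_len(nrow(idx)), function(r) {
    tip_distance(tip, map$sites_x[idx[r, 1] + m], map$sites_y[idx[r, 2] + m])
  }, numeric(1))
}

#' Render a Shannon entropy map
#'
#' Draws the map with the color scale clipped to the
#' \[median, maximum\] dynamic range (maximizing color resolution around
#' the pivot), optionally overlaying the spiral tip trajectory. A
#' degenerate (constant) map falls back to the full range with a notice.
#'
#' @param map a `shen_map`.
#' @param tip optional `tip_trajectory` to overlay.
#' @param file optional PNG path; when `NULL` draws on the active
#'   device.
#' @param main plot title.
#' @return invisibly, a list with the color range `zlim`, the overlay
#'   coordinates `tip_xy` and `file`.
#' @export
render_map <- function(map, tip = NULL, file = NULL, main = NULL) {
  stopifnot(inherits(map, "shen_map"))
  stopifnot(all(is.finite(map$values)))
  zlim <- c(median(map$values), max(map$values))
  if (diff(zlim) == 0) {
    message("degenerate (constant) map: falling back to full range")
    zlim <- zlim + c(-0.5, 0.5)
  }
  if (!is.null(file)) {
    png(file, width = 720, height = 640)
    on.exit(dev.off())
  }
  z <- pmax(map$values, zlim[1])
  image(map$sites_x, map$sites_y, z, zlim = zlim, useRaster = TRUE,
        col = hcl.colors(64, "Spectral", rev = TRUE),
        xlab = "x (nodes)", ylab = "y (nodes)",
        main = if (is.null(main)) "Shannon entropy (bits)" else main,
        asp = 1)
  tip_xy <- NULL
  if (!is.null(tip) && nrow(tip$points)) {
    tip_xy <- tip$points[, c("x", "y")]
    lines(tip_xy$x, tip_xy$y, col = "blue", lwd = 2)
  }
  invisible(list(zlim = zlim, tip_xy = tip_xy, file = file))
}
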