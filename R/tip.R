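#' Track the spiral-wave tip
#'
#' The tip is localized per frame as the intersection of the isoline
#' `v = v_iso` with the isoline `dv/dt = 0` (time derivative from
#' centered differences across neighbouring frames). Both isolines are
#' extracted by marching squares with linear interpolation and all
#' segment-segment intersections are computed at sub-grid resolution; a
#' continuity filter keeps, per frame, the intersection nearest the
#' previous tip (nearest the grid center for the first frame). Frames
#' without an intersection contribute no point, so a planar or target
#' wave yields an empty trajectory.
#'
#' The default iso-level is the half-maximal voltage of phase 0
#' (-30 mV for the physiological models, the mid-cubic 0.5 for FHN).
#' An iso-level of 0 mV is only reliable when the local spike peak
#' stays above 0 everywhere: rate-adapted reentrant action potentials
#' often peak near or below 0 mV, and the spike crest (dv/dt = 0)
#' then interleaves with the v = 0 isoline all along the wavefront,
#' spraying spurious intersections. Any level can be supplied via
#' `v_iso`.
#'
#' @param movie a `voltage_movie`.
#' @param v_iso tip iso-voltage; default 0.5 for FHN, -30 mV otherwise.
#' @param crop_radius search window half-width (nodes) around the
#'   previous tip; speeds up long movies. `Inf` disables cropping.
#' @param amp_frac phase-singularity discriminator: an intersection only
#'   qualifies as a tip if the voltage range within a 4-node
#'   neighbourhood exceeds this fraction of the whole-movie voltage
#'   range. The pivot has all phases in close proximity, whereas
#'   spurious isoline crossings on weak far-field wave crests do not.
#' @return object of class `tip_trajectory` with `points`, a data frame
#'   of `(t, x, y)` sub-grid positions (units of nodes).
#' @export
track_tip <- function(movie, v_iso = NULL, crop_radius = 25,
                      amp_frac = 0.3) {
  stopifnot(inherits(movie, "voltage_movie"))
  fr <- movie$frames
  nx <- dim(fr)[1]; ny <- dim(fr)[2]; nt <- dim(fr)[3]
  if (nt < 3) stop("need >= 3 frames for centered dv/dt")
  if (is.null(v_iso)) v_iso <- if (movie$model_tag == "fhn") 0.5 else -30
  dts <- movie$dt_sample
  amp_min <- amp_frac * diff(range(fr))
  prev <- c((nx + 1) / 2, (ny + 1) / 2)
  have_prev <- FALSE
  ts <- xs <- ys <- numeric(0)
  for (k in 2:(nt - 1)) {
    dvdt <- (fr[, , k + 1] - fr[, , k - 1]) / (2 * dts)
    pt <- NULL
    if (have_prev && is.finite(crop_radius)) {
      ix <- max(1, floor(prev[1] - crop_radius)):min(nx, ceiling(prev[1] + crop_radius))
      iy <- max(1, floor(prev[2] - crop_radius)):min(ny, ceiling(prev[2] + crop_radius))
      pt <- frame_tip(fr[ix, iy, k], dvdt[ix, iy], ix, iy, v_iso, prev,
                      amp_min)
    }
    if (is.null(pt))
      pt <- frame_tip(fr[, , k], dvdt, seq_len(nx), seq_len(ny), v_iso,
                      prev, amp_min)
    if (!is.null(pt)) {
      ts <- c(ts, movie$t[k]); xs <- c(xs, pt[1]); ys <- c(ys, pt[2])
      prev <- pt
      have_prev <- TRUE
    }
  }
  structure(list(points = data.frame(t = ts, x = xs, y = ys),
                 v_iso = v_iso, grid = movie$grid),
            class = "tip_trajectory")
}

# tip candidate within one (sub)frame: nearest qualifying isoline
# intersection of v = v_iso and dv/dt = 0
frame_tip <- function(v, dvdt, ix, iy, v_iso, ref, amp_min = 0) {
  if (length(ix) < 2 || length(iy) < 2) return(NULL)
  rv <- range(v); rd <- range(dvdt)
  if (v_iso <= rv[1] || v_iso >= rv[2] || rd[1] >= 0 || rd[2] <= 0)
    return(NULL)
  ca <- contourLines(ix, iy, v, levels = v_iso)
  cb <- contourLines(ix, iy, dvdt, levels = 0)
  if (!length(ca) || !length(cb)) return(NULL)
  pts <- segment_intersections(contour_segments(ca), contour_segments(cb))
  if (is.null(pts) || !nrow(pts)) return(NULL)
  if (amp_min > 0) {
    nx <- length(ix); ny <- length(iy)
    ok <- vapply(seq_len(nrow(pts)), function(r) {
      i <- round(pts[r, 1]) - ix[1] + 1
      j <- round(pts[r, 2]) - iy[1] + 1
      ii <- max(1, i - 4):min(nx, i + 4)
      jj <- max(1, j - 4):min(ny, j + 4)
      diff(range(v[ii, jj])) >= amp_min
    }, logical(1))
    pts <- pts[ok, , drop = FALSE]
    if (!nrow(pts)) return(NULL)
  }
  d2 <- (pts[, 1] - ref[1])^2 + (pts[, 2] - ref[2])^2
  pts[which.min(d2), ]
}

contour_segments <- function(cl) {
  do.call(rbind, lapply(cl, function(c1) {
    n <- length(c1$x)
    if (n < 2) return(NULL)
    cbind(c1$x[-n], c1$y[-n], c1$x[-1], c1$y[-1])
  }))
}

# all intersection points between two segment sets (n x 4 matrices)
segment_intersections <- function(A, B) {
  if (is.null(A) || is.null(B)) return(NULL)
  na <- nrow(A); nb <- nrow(B)
  # bounding-box prefilter
  ax0 <- pmin(A[, 1], A[, 3]); ax1 <- pmax(A[, 1], A[, 3])
  ay0 <- pmin(A[, 2], A[, 4]); ay1 <- pmax(A[, 2], A[, 4])
  bx0 <- pmin(B[, 1], B[, 3]); bx1 <- pmax(B[, 1], B[, 3])
  by0 <- pmin(B[, 2], B[, 4]); by1 <- pmax(B[, 2], B[, 4])
  cand <- which(outer(ax0, bx1, "<=") & outer(ax1, bx0, ">=") &
                outer(ay0, by1, "<=") & outer(ay1, by0, ">="),
                arr.ind = TRUE)
  if (!nrow(cand)) return(NULL)
  ia <- cand[, 1]; ib <- cand[, 2]
  rx <- A[ia, 3] - A[ia, 1]; ry <- A[ia, 4] - A[ia, 2]
  sx <- B[ib, 3] - B[ib, 1]; sy <- B[ib, 4] - B[ib, 2]
  qx <- B[ib, 1] - A[ia, 1]; qy <- B[ib, 2] - A[ia, 2]
  den <- rx * sy - ry * sx
  ok <- abs(den) > 1e-12
  t <- (qx * sy - qy * sx) / den
  u <- (qx * ry - qy * rx) / den
  ok <- ok & t >= 0 & t <= 1 & u >= 0 & u <= 1
  if (!any(ok)) return(NULL)
  cbind(A[ia[ok], 1] + t[ok] * rx[ok], A[ia[ok], 2] + t[ok] * ry[ok])
}

#' @export
print.tip_trajectory <- function(x, ...) {
  cat("<tip_trajectory>", nrow(x$points), "points")
  if (nrow(x$points)) {
    cat(", t:", paste(signif(range(x$points$t), 4), collapse = " .. "))
    cat(", centroid: (", paste(signif(colMeans(x$points[, c("x", "y")]), 4),
                               collapse = ", "), ")")
  }
  cat("\n")
  invisible(x)
}

#' Least-squares circle fit (Kasa) of a tip trajectory
#' @param tip a `tip_trajectory` (or a data frame with `x`, `y`).
#' @return list with `center`, `radius` and `residuals` (radial).
#' @export
fit_circle <- function(tip) {
  pts <- if (inherits(tip, "tip_trajectory")) tip$points else tip
  x <- pts$x; y <- pts$y
  Amat <- cbind(x, y, 1)
  sol <- unname(qr.solve(Amat, x^2 + y^2))
  cx <- sol[1] / 2; cy <- sol[2] / 2
  r <- sqrt(sol[3] + cx^2 + cy^2)
  rr <- sqrt((x - cx)^2 + (y - cy)^2)
  list(center = c(x = cx, y = cy), radius = r, residuals = rr - r)
}

#' Convex-hull area of a tip trajectory (meander area)
#' @param tip a `tip_trajectory`.
#' @return hull area in node^2 units (0 for < 3 points).
#' @export
meander_area <- function(tip) {
  pts <- if (inherits(tip, "tip_trajectory")) tip$points else tip
  if (nrow(pts) < 3) return(0)
  h <- chull(pts$x, pts$y)
  x <- pts$x[h]; y <- pts$y[h]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Distance from a point to the dilated convex hull of a trajectory
#'
#' Zero when the point lies inside the hull; otherwise the Euclidean
#' distance to the hull boundary.
#' @param tip a `tip_trajectory`.
#' @param x,y query point, node units.
#' @return distance in node units.
#' @export
hull_distance <- function(tip, x, y) {
  pts <- if (inherits(tip, "tip_trajectory")) tip$points else tip
  if (nrow(pts) == 0) return(Inf)
  if (nrow(pts) < 3)
    return(min(sqrt((pts$x - x)^2 + (pts$y - y)^2)))
  h <- chull(pts$x, pts$y)
  hx <- pts$x[h]; hy <- pts$y[h]
  n <- length(hx)
  x2 <- c(hx[-1], hx[1]); y2 <- c(hy[-1], hy[1])
  cross <- (x2 - hx) * (y - hy) - (y2 - hy) * (x - hx)
  if (all(cross >= 0) || all(cross <= 0)) return(0)
  # distance to each hull edge
  dx <- x2 - hx; dy <- y2 - hy
  tt <- pmin(pmax(((x - hx) * dx + (y - hy) * dy) / (dx^2 + dy^2), 0), 1)
  min(sqrt((hx + tt * dx - x)^2 + (hy + tt * dy - y)^2))
}

#' Minimum distance from a point to the trajectory points
#' @param tip a `tip_trajectory`.
#' @param x,y query point.
#' @return distance in node units (Inf for an empty trajectory).
#' @export
tip_distance <- function(tip, x, y) {
  pts <- if (inherits(tip, "tip_trajectory")) tip$points else tip
  if (!nrow(pts)) return(Inf)
  min(sqrt((pts$x - x)^2 + (pts$y - y)^2))
}

#' Wavefront mask of a movie frame
#'
#' The wavefront is the region whose voltage lies within +/- 10% of the
#' half-maximal level, `(v_max + v_min)/2 +/- band_frac (v_max - v_min)`,
#' while depolarizing (`dv/dt > 0`). The voltage extrema are taken over
#' the whole movie by default (per-frame extrema fluctuate with
#' repolarization and destabilize the half-max level).
#'
#' @param movie a `voltage_movie`.
#' @param k frame index (dv/dt uses centered differences where
#'   possible).
#' @param band_frac half-width of the voltage band as a fraction of the
#'   voltage range (default 0.1).
#' @param extrema `"global"` (whole movie) or `"frame"`.
#' @param vrange optionally the precomputed global voltage range (avoids
#'   rescanning the movie when masking many frames).
#' @return logical `nx` x `ny` mask.
#' @export
wavefront_mask <- function(movie, k, band_frac = 0.1,
                           extrema = c("global", "frame"), vrange = NULL) {
  extrema <- match.arg(extrema)
  fr <- movie$frames
  nt <- dim(fr)[3]
  stopifnot(k >= 1, k <= nt)
  vr <- if (!is.null(vrange)) vrange
        else if (extrema == "global") range(fr) else range(fr[, , k])
  if (vr[1] == vr[2]) stop("flat movie: wavefront level undefined")
  mid <- mean(vr)
  band <- band_frac * diff(vr)
  dvdt <- frame_dvdt(movie, k)
  v <- fr[, , k]
  v >= mid - band & v <= mid + band & dvdt > 0
}

frame_dvdt <- function(movie, k) {
  fr <- movie$frames
  nt <- dim(fr)[3]
  dts <- movie$dt_sample
  if (k == 1) (fr[, , 2] - fr[, , 1]) / dts
  else if (k == nt) (fr[, , nt] - fr[, , nt - 1]) / dts
  else (fr[, , k + 1] - fr[, , k - 1]) / (2 * dts)
}

#' Wavefront propagation direction
#'
#' The direction of propagation at depolarizing wavefront nodes,
#' \deqn{\psi = \mathrm{atan2}(-\partial v/\partial y,
#'                             -\partial v/\partial x),}
#' i.e. the down-gradient direction: the front advances into resting
#' tissue. Gradients use central differences. Nodes with zero gradient
#' are dropped (their count is recorded in attribute `n_dropped`).
#'
#' @param movie a `voltage_movie`.
#' @param k frame index.
#' @param mask logical node mask; defaults to [wavefront_mask()].
#' @param ... passed to [wavefront_mask()].
#' @return data frame of direction samples `(x, y, t, psi)`, psi in
#'   radians wrapped to (-pi, pi\].
#' @export
propagation_direction <- function(movie, k, mask = NULL, ...) {
  fr <- movie$frames
  nx <- dim(fr)[1]; ny <- dim(fr)[2]
  if (is.null(mask)) mask <- wavefront_mask(movie, k, ...)
  v <- fr[, , k]
  im <- c(1L, seq_len(nx - 1)); ip <- c(seq_len(nx)[-1], nx)
  jm <- c(1L, seq_len(ny - 1)); jp <- c(seq_len(ny)[-1], ny)
  denx <- matrix(ip - im, nx, ny)
  deny <- matrix(jp - jm, nx, ny, byrow = TRUE)
  gx <- (v[ip, ] - v[im, ]) / denx
  gy <- (v[, jp] - v[, jm]) / deny
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx))
    return(structure(data.frame(x = numeric(0), y = numeric(0),
                                t = numeric(0), psi = numeric(0)),
                     n_dropped = 0L))
  g1 <- gx[idx]; g2 <- gy[idx]
  nz <- g1 != 0 | g2 != 0
  out <- data.frame(x = idx[nz, 1], y = idx[nz, 2],
                    t = movie$t[k], psi = atan2(-g2[nz], -g1[nz]))
  attr(out, "n_dropped") <- sum(!nz)
  out
}

#' Wavefront directions along a meridian line
#'
#' Collects, for every frame in the window, the propagation-direction
#' samples where the wavefront mask crosses a full-width line of the
#' sheet, keyed by position along the line. This is the raw material of
#' the direction scatter plots that expose the directional diversity at
#' the rotor pivot.
#'
#' @param movie a `voltage_movie`.
#' @param orientation `"horizontal"` (line of constant y) or
#'   `"vertical"`.
#' @param offset the fixed coordinate of the line (node index).
#' @param window fraction window of frames analysed.
#' @param band_frac,extrema passed to [wavefront_mask()].
#' @return data frame `(pos, psi, t)`: position along the line, wave
#'   angle (radians), time.
#' @export
meridian_direction_scatter <- function(movie,
                                       orientation = c("horizontal",
                                                       "vertical"),
                                       offset, window = c(0, 1),
                                       band_frac = 0.1,
                                       extrema = "global") {
  orientation <- match.arg(orientation)
  fr <- movie$frames
  nt <- dim(fr)[3]
  ks <- seq(max(1L, floor(window[1] * nt) + 1L), floor(window[2] * nt))
  vr <- if (extrema == "global") range(fr) else NULL
  out <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    k <- ks[i]
    m <- wavefront_mask(movie, k, band_frac = band_frac, extrema = extrema,
                        vrange = vr)
    line_mask <- matrix(FALSE, dim(fr)[1], dim(fr)[2])
    if (orientation == "horizontal") line_mask[, offset] <- TRUE
    else line_mask[offset, ] <- TRUE
    d <- propagation_direction(movie, k, mask = m & line_mask)
    if (nrow(d))
      out[[i]] <- data.frame(pos = if (orientation == "horizontal") d$x else d$y,
                             psi = d$psi, t = d$t)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(pos = numeric(0), psi = numeric(0),
                                      t = numeric(0))
  res
}

#' Circular spread of a set of angles
#'
#' `1 - R` where `R` is the mean resultant length of the unit vectors;
#' 0 for perfectly aligned angles, -> 1 for uniformly spread ones.
#' @param psi angles in radians.
#' @return spread in \[0, 1\] (`NA` for empty input).
#' @export
circ_spread <- function(psi) {
  if (!length(psi)) return(NA_real_)
  1 - Mod(mean(exp(1i * psi)))
}

#' Sliding-window circular spread along a meridian line
#'
#' @param scatter result of [meridian_direction_scatter()].
#' @param n_line number of nodes along the line.
#' @param half half-width of the sliding window (default 5, i.e. an
#'   11-node segment).
#' @param min_n minimum samples for a defined spread.
#' @return numeric vector, spread (1 - R) per line position.
#' @export
meridian_spread_profile <- function(scatter, n_line, half = 5, min_n = 8) {
  vapply(seq_len(n_line), function(p) {
    s <- scatter$psi[abs(scatter$pos - p) <= half]
    if (length(s) < min_n) NA_real_ else circ_spread(s)
  }, numeric(1))
}
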