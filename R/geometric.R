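#' Analytic rigidly rotating spiral-wave model
#'
#' An idealized Archimedean spiral with a constant voltage gradient
#' across the wavefront, used to study entropy maps free of any ionic
#' model. The front arms satisfy
#' \eqn{r = a (\phi + \omega t \mod 2\pi)/2\pi + a n} and the voltage is
#' a linear ramp of slope `v_amp / front_width` across the signed
#' distance to the nearest arm, clipped to \[0, v_amp\] (the excited
#' plateau behind the ramp ends abruptly at the next period: the back of
#' the wave is not modelled beyond the single ramp).
#'
#' @param a spiral pitch: radial growth per turn (length units).
#' @param omega angular velocity, rad per time unit (rotation period
#'   `2*pi/omega`).
#' @param front_width width of the linear voltage ramp (length units,
#'   `< a`).
#' @param back_width width of the linear repolarizing ramp closing the
#'   excited band (keeps the profile continuous, so the current-source
#'   kernel sees crease lines rather than a jump discontinuity).
#' @param v_amp ramp amplitude.
#' @param arm_extent maximal radius represented (length units).
#' @return object of class `geo_spiral_spec`.
#' @export
geo_spiral_spec <- function(a = 4, omega = 2 * pi / 100, front_width = 1,
                            back_width = 1, v_amp = 1, arm_extent = 48) {
  stopifnot(a > 0, omega != 0, front_width > 0, back_width > 0,
            front_width + back_width < a, v_amp > 0, arm_extent > 0)
  structure(list(a = a, omega = omega, front_width = front_width,
                 back_width = back_width, v_amp = v_amp,
                 arm_extent = arm_extent),
            class = "geo_spiral_spec")
}

#' Voltage of the geometric spiral at points and time
#'
#' @param spec a [geo_spiral_spec()].
#' @param x,y coordinates (length units; vectorized).
#' @param t time.
#' @return voltage value(s) in \[0, v_amp\].
#' @export
spiral_voltage <- function(spec, x, y, t) {
  r <- sqrt(x^2 + y^2)
  phi <- atan2(y, x)
  # signed radial distance to the nearest front arm, wrapped to [-a/2, a/2)
  chi <- r - spec$a * (phi + spec$omega * t) / (2 * pi)
  delta <- chi %% spec$a
  delta <- delta - spec$a * (delta >= spec$a / 2)
  # continuous trapezoid: linear front ramp (constant gradient
  # v_amp/front_width), excited plateau, linear repolarizing back
  up <- spec$v_amp * (0.5 + delta / spec$front_width)
  down <- spec$v_amp * (spec$a / 2 - delta) / spec$back_width
  pmin(pmax(pmin(up, down), 0), spec$v_amp)
}

#' Sample the geometric spiral onto a quadrature mesh
#'
#' Builds a `voltage_movie` of the analytic spiral on a square mesh, the
#' substrate for the same forward-EGM and entropy machinery used for the
#' simulated tissues.
#'
#' @param spec a [geo_spiral_spec()].
#' @param mesh quadrature mesh spacing (length units; must resolve the
#'   front: `mesh < front_width`).
#' @param t_grid time samples; default two rotations at 100 frames per
#'   rotation.
#' @param extent half-width of the simulated sheet; default
#'   `arm_extent`.
#' @return a `voltage_movie` (grid in mesh units, centered on the
#'   spiral core).
#' @export
geo_movie <- function(spec, mesh = 0.25, t_grid = NULL, extent = NULL) {
  if (mesh >= spec$front_width)
    stop("quadrature mesh (", mesh, ") must be finer than front_width (",
         spec$front_width, ")")
  if (is.null(extent)) extent <- spec$arm_extent
  period <- 2 * pi / abs(spec$omega)
  if (is.null(t_grid)) t_grid <- seq(0, 2 * period, length.out = 201)[-201]
  xs <- seq(-extent, extent, by = mesh)
  n <- length(xs)
  xm <- matrix(xs, n, n)
  ym <- matrix(xs, n, n, byrow = TRUE)
  frames <- array(NA_real_, c(n, n, length(t_grid)))
  for (k in seq_along(t_grid))
    frames[, , k] <- spiral_voltage(spec, xm, ym, t_grid[k])
  g <- grid_spec(n, n, dx = mesh, D = 1, small_ok = TRUE)
  mv <- voltage_movie(frames, dt_sample = t_grid[2] - t_grid[1], g,
                      model_tag = "geometric")
  mv$t <- t_grid
  mv$origin <- c(x = -extent, y = -extent)   # node 1 sits at -extent
  mv
}

#' Unipolar electrogram of the geometric spiral at one electrode
#'
#' Inverse-distance quadrature of the source field over the sheet,
#' with the electrode elevated `h` length units above the plane.
#'
#' @param spec a [geo_spiral_spec()].
#' @param xe,ye electrode coordinates (length units).
#' @param h electrode elevation (length units).
#' @param t_grid time samples (>= 2 rotations recommended).
#' @param mesh quadrature mesh spacing.
#' @param source_mode `"laplacian"` or `"voltage"` (see
#'   [unipolar_field()]).
#' @param movie optionally a precomputed [geo_movie()] (with matching
#'   `t_grid`).
#' @return an `egm_trace`.
#' @export
geo_unipolar <- function(spec, xe, ye, h = 0.5, t_grid = NULL, mesh = 0.25,
                         source_mode = "laplacian", movie = NULL) {
  if (is.null(movie)) movie <- geo_movie(spec, mesh = mesh, t_grid = t_grid)
  uf <- unipolar_field(movie, h = h / movie$grid$dx, source_mode = source_mode)
  ij <- nearest_site_xy(movie, xe, ye)
  tr <- egm_trace(uf, ij[1], ij[2])
  tr$t <- movie$t
  tr$config$position <- c(x = xe, y = ye)
  tr
}

# nearest mesh node of a geometric movie to physical coordinates
nearest_site_xy <- function(movie, xe, ye) {
  ox <- movie$origin["x"]; oy <- movie$origin["y"]
  c(round((xe - ox) / movie$grid$dx) + 1, round((ye - oy) / movie$grid$dx) + 1)
}

#' Bipolar entropy maps of the geometric spiral over electrode spacings
#'
#' For each inter-electrode distance `d` (in length units), builds the
#' horizontal bipolar field on the quadrature mesh and its Shannon
#' entropy map, using the same histogram rule as the tissue pipeline.
#'
#' @param spec a [geo_spiral_spec()].
#' @param spacings inter-electrode distances in length units.
#' @param h electrode elevation (length units).
#' @param mesh quadrature mesh spacing.
#' @param map_extent half-width of the mapped region (length units).
#' @param hist_spec a [histogram_spec()].
#' @param source_mode forward-model source mode.
#' @param t_grid time samples.
#' @return named list of `shen_map` objects (one per spacing), with the
#'   movie attached as attribute `movie`. Map site coordinates are in
#'   spiral length units.
#' @export
geo_bipolar_and_map <- function(spec, spacings = c(1, 2, 4, 8, 12, 16),
                                h = 0.5, mesh = 0.25, map_extent = NULL,
                                hist_spec = histogram_spec(),
                                source_mode = "laplacian", t_grid = NULL) {
  movie <- geo_movie(spec, mesh = mesh, t_grid = t_grid)
  uf <- unipolar_field(movie, h = h / mesh, source_mode = source_mode)
  ox <- movie$origin["x"]
  maps <- lapply(spacings, function(d) {
    s_nodes <- max(1L, as.integer(round(d / mesh)))
    bf <- bipolar_field(uf, s_nodes, "horizontal")
    m <- shen_map(bf, hist_spec, window = c(0, 1))
    # convert site coordinates from node indices to length units
    m$sites_x <- ox + (bf$sites_x - 1) * mesh
    m$sites_y <- movie$origin["y"] + (bf$sites_y - 1) * mesh
    m$spacing_units <- d
    if (!is.null(map_extent)) {
      kx <- which(abs(m$sites_x) <= map_extent)
      ky <- which(abs(m$sites_y) <= map_extent)
      m$values <- m$values[kx, ky]
      m$sites_x <- m$sites_x[kx]; m$sites_y <- m$sites_y[ky]
      m$stats <- c(min = min(m$values), median = median(m$values),
                   max = max(m$values))
    }
    m
  })
  names(maps) <- paste0("d", spacings)
  attr(maps, "movie") <- movie
  maps
}

#' Count zero crossings of a trace
#' @param x numeric vector or `egm_trace`.
#' @return number of strict sign changes.
#' @export
zero_crossings <- function(x) {
  if (inherits(x, "egm_trace")) x <- x$samples
  s <- sign(x)
  s <- s[s != 0]
  sum(diff(s) != 0)
}
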