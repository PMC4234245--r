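#' Isotropic square tissue grid
#'
#' @param nx,ny node counts (>= 50 for simulations; smaller grids are
#'   allowed for toy/forward-model tests via `small_ok`).
#' @param dx node spacing (cm for LR91/CRN, dimensionless for FHN).
#' @param D isotropic diffusion coefficient (cm^2/ms or dimensionless).
#' @param small_ok allow grids below the 50-node simulation minimum.
#' @return object of class `grid_spec`.
#' @export
grid_spec <- function(nx, ny, dx, D, small_ok = FALSE) {
  stopifnot(dx > 0, D > 0)
  if (!small_ok && (nx < 50 || ny < 50))
    stop("simulation grids need nx, ny >= 50 (use small_ok = TRUE for toys)")
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 dx = dx, D = D), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat("<grid_spec>", x$nx, "x", x$ny, " dx =", x$dx, " D =", x$D,
      " (CFL dt <=", signif(x$dx^2 / (4 * x$D), 3), ")\n")
  invisible(x)
}

#' Spiral-initiation phase field
#'
#' Assigns every grid node a phase
#' \deqn{\theta(r, \phi) = \mathrm{frac}\left(k \phi / 2\pi + r / \lambda\right)}
#' where (r, phi) are polar coordinates about `center`, `k` is the
#' winding number and `lambda` the radial wavelength (use `Inf` for a
#' purely angular phase). The fractional part plays the role of the
#' additive integer that keeps the phase inside \[0, 1).
#'
#' @param grid a [grid_spec()].
#' @param center spiral center `c(x, y)` in node units (1-based).
#' @param k nonzero integer winding number; negative `k` mirrors the
#'   chirality.
#' @param wavelength radial wavelength in node units; `Inf` disables the
#'   radial term.
#' @return `nx` x `ny` matrix of phases in \[0, 1).
#' @export
initial_phase_field <- function(grid, center = c((grid$nx + 1) / 2,
                                                 (grid$ny + 1) / 2),
                                k = 1, wavelength = Inf) {
  stopifnot(inherits(grid, "grid_spec"), k != 0, wavelength > 0)
  if (center[1] < 1 || center[1] > grid$nx ||
      center[2] < 1 || center[2] > grid$ny)
    stop("spiral center must lie inside the grid")
  x <- seq_len(grid$nx) - center[1]
  y <- seq_len(grid$ny) - center[2]
  xm <- matrix(x, grid$nx, grid$ny)
  ym <- matrix(y, grid$nx, grid$ny, byrow = TRUE)
  phi <- atan2(ym, xm)
  r <- sqrt(xm^2 + ym^2)
  th <- k * phi / (2 * pi) + if (is.finite(wavelength)) r / wavelength else 0
  th - floor(th)
}

#' Tissue state from a phase field
#'
#' Sets every node's full kinetic state to the cycle library evaluated at
#' that node's phase, mimicking a propagating spiral wave (or any other
#' phase distribution).
#'
#' @param grid a [grid_spec()].
#' @param library a [build_cycle_library()] for the model to simulate.
#' @param theta_field `nx` x `ny` phase matrix, e.g. from
#'   [initial_phase_field()]; alternatively pass `center`, `k`,
#'   `wavelength` to build one.
#' @param center,k,wavelength forwarded to [initial_phase_field()] when
#'   `theta_field` is missing.
#' @return `N x n_state` state matrix (node index runs x-fastest) with
#'   attribute `model`.
#' @export
init_spiral <- function(grid, library, theta_field = NULL,
                        center = c((grid$nx + 1) / 2, (grid$ny + 1) / 2),
                        k = 1, wavelength = Inf) {
  stopifnot(inherits(grid, "grid_spec"), inherits(library, "cycle_library"))
  if (is.null(theta_field))
    theta_field <- initial_phase_field(grid, center, k, wavelength)
  if (!all(dim(theta_field) == c(grid$nx, grid$ny)))
    stop("theta_field dimensions do not match the grid")
  st <- library_interp(library, as.vector(theta_field))
  attr(st, "model") <- library$model
  st
}

#' Uniform resting tissue state
#' @param grid a [grid_spec()].
#' @param model a [cell_model()].
#' @return `N x n_state` resting state matrix with attribute `model`.
#' @export
resting_tissue <- function(grid, model) {
  st <- matrix(rep(as.numeric(model$resting_state),
                   each = grid$nx * grid$ny),
               grid$nx * grid$ny, length(model$resting_state))
  attr(st, "model") <- model
  st
}

#' Single planar-wave initial condition
#'
#' Paints one wave travelling in +x (or +y): the phase ramps linearly
#' from 1 at the leading column down to `1 - span` over `extent` nodes
#' (rest beyond). Painting only the leading `span` fraction of the
#' cycle keeps the excited band wide enough to launch a wave: mapping a
#' whole pacing cycle (which is mostly diastole) onto a short band
#' paints an unsustainably thin pulse.
#'
#' @param grid a [grid_spec()].
#' @param library cycle library.
#' @param extent spatial extent of the painted band, nodes.
#' @param span fraction of the cycle painted across the band.
#' @param axis `"x"` or `"y"`.
#' @param front position of the wavefront (node index along `axis`).
#' @return state matrix as in [init_spiral()].
#' @export
planar_wave_state <- function(grid, library, extent = 20, span = 0.4,
                              axis = c("x", "y"), front = extent + 1) {
  axis <- match.arg(axis)
  coord <- if (axis == "x") {
    matrix(seq_len(grid$nx), grid$nx, grid$ny)
  } else {
    matrix(seq_len(grid$ny), grid$nx, grid$ny, byrow = TRUE)
  }
  th <- 1 - span * (front - coord) / extent
  th[coord > front | th < 1 - span] <- 0
  init_spiral(grid, library, theta_field = th)
}

#' Integrate the monodomain reaction-diffusion system
#'
#' Explicit Euler time stepping of `dstate/dt = rhs(state) + D lap(v)`
#' with Rush-Larsen updates for the gating variables, a 5-point Laplacian
#' and no-flux (mirror) boundaries. Voltage frames are recorded every
#' `dt_sample`; the run is bit-reproducible (no randomness).
#'
#' @param state `N x n_state` initial state (from [init_spiral()] etc.).
#' @param model a [cell_model()]; defaults to `attr(state, "model")`.
#' @param grid a [grid_spec()].
#' @param duration recorded duration (model time units).
#' @param dt integration step; must satisfy `dt <= dx^2 / (4 D)`.
#' @param dt_sample frame interval of the recording (default 0.5 ms,
#'   i.e. 2 kHz, so a 500 Hz low-pass filter stays below Nyquist).
#' @param settle unrecorded lead-in time before frame 0.
#' @return object of class `voltage_movie`: `frames` (`nx` x `ny` x
#'   `n_t` array), `t`, `dt_sample`, `grid`, `model_tag`, `final_state`.
#' @export
simulate_tissue <- function(state, model = attr(state, "model"), grid,
                            duration, dt = model$dt_default,
                            dt_sample = 0.5, settle = 0) {
  stopifnot(inherits(model, "cell_model"), inherits(grid, "grid_spec"))
  if (nrow(state) != grid$nx * grid$ny)
    stop("state rows must equal nx * ny")
  if (ncol(state) != length(model$state_names))
    stop("state/model mismatch: expected ", length(model$state_names),
         " state variables for ", model$name)
  cfl <- grid$dx^2 / (4 * grid$D)
  if (dt > cfl + 1e-12)
    stop("dt = ", dt, " violates the stability bound dx^2/(4D) = ",
         signif(cfl, 4))
  sample_every <- max(1L, as.integer(round(dt_sample / dt)))
  st <- state
  if (settle > 0) {
    pre <- integrate_tissue_cpp(model$model_id, st, model$params,
                                grid$nx, grid$ny, grid$dx, grid$D, dt,
                                as.integer(round(settle / dt)),
                                as.integer(round(settle / dt)))
    st <- pre$final
  }
  out <- integrate_tissue_cpp(model$model_id, st, model$params,
                              grid$nx, grid$ny, grid$dx, grid$D, dt,
                              as.integer(round(duration / dt)), sample_every)
  vb <- model$v_bounds
  vr <- range(out$frames)
  if (vr[1] < vb[1] || vr[2] > vb[2])
    warning("voltage range ", paste(signif(vr, 4), collapse = " .. "),
            " exceeds the plausible bounds for ", model$name)
  structure(list(frames = out$frames, t = out$t,
                 dt_sample = dt * sample_every,
                 grid = grid, model_tag = model$name,
                 model = model, final_state = out$final),
            class = "voltage_movie")
}

#' Construct a voltage movie from raw frames
#'
#' Mostly useful for tests and for analytic (non-simulated) voltage
#' fields.
#' @param frames `nx` x `ny` x `n_t` array.
#' @param dt_sample frame interval.
#' @param grid a [grid_spec()].
#' @param model_tag identifier string.
#' @return a `voltage_movie`.
#' @export
voltage_movie <- function(frames, dt_sample, grid, model_tag = "custom") {
  stopifnot(length(dim(frames)) == 3, dt_sample > 0,
            all(dim(frames)[1:2] == c(grid$nx, grid$ny)))
  structure(list(frames = frames,
                 t = (seq_len(dim(frames)[3]) - 1) * dt_sample,
                 dt_sample = dt_sample, grid = grid, model_tag = model_tag,
                 model = NULL, final_state = NULL),
            class = "voltage_movie")
}

#' @export
print.voltage_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat("<voltage_movie>", x$model_tag, ":", d[1], "x", d[2], "nodes,",
      d[3], "frames @ dt =", x$dt_sample, "\n")
  cat("  voltage range:", paste(signif(range(x$frames), 4),
                                collapse = " .. "), "\n")
  invisible(x)
}

#' Convenience wrapper: initiate and run a rotor
#'
#' Builds the cycle library, paints the spiral phase field, runs the
#' settling window and records the analysis window.
#'
#' @inheritParams simulate_tissue
#' @param model a [cell_model()].
#' @param grid a [grid_spec()].
#' @param k winding number (sign sets chirality).
#' @param wavelength radial wavelength of the initiation field in node
#'   units; default half the grid diagonal.
#' @param center spiral center, node units.
#' @param library optionally a prebuilt [build_cycle_library()].
#' @param ... passed to [build_cycle_library()].
#' @return a `voltage_movie`.
#' @export
simulate_rotor <- function(model, grid, duration, settle = 0,
                           dt = model$dt_default, dt_sample = 0.5,
                           k = 1, wavelength = max(grid$nx, grid$ny),
                           center = c((grid$nx + 1) / 2, (grid$ny + 1) / 2),
                           library = NULL, ...) {
  if (is.null(library)) library <- build_cycle_library(model, ...)
  st <- init_spiral(grid, library, center = center, k = k,
                    wavelength = wavelength)
  simulate_tissue(st, model, grid, duration, dt = dt,
                  dt_sample = dt_sample, settle = settle)
}

#' Extract the sub-movie of an analysis window
#' @param movie a `voltage_movie`.
#' @param window fraction of the recording to keep, e.g. `c(0.2, 1)`
#'   drops the first 20%.
#' @return a `voltage_movie`.
#' @export
movie_window <- function(movie, window = c(0.2, 1)) {
  nt <- dim(movie$frames)[3]
  idx <- seq(max(1L, floor(window[1] * nt) + 1L), floor(window[2] * nt))
  out <- movie
  out$frames <- movie$frames[, , idx, drop = FALSE]
  out$t <- movie$t[idx]
  out
}
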