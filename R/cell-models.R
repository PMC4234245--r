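#' Cell model specifications
#'
#' Constructs a cell-model specification for one of the three supported
#' membrane kinetics: the cubic two-variable FitzHugh-Nagumo model
#' (`"fhn"`), the Luo-Rudy 1991 guinea-pig ventricular myocyte model
#' (`"lr91"`) and the Courtemanche-Ramirez-Nattel 1998 human atrial
#' myocyte model (`"crn"`).
#'
#' The FHN kinetics are
#' \deqn{dv/dt = v (v - a)(1 - v) - w, \quad
#'       dw/dt = \epsilon (\beta v - \gamma w - \delta)}
#' with defaults `a = 0.1`, `eps = 0.01`, `beta = 0.5`, `gamma = 2`,
#' `delta = 0`, which sustain a rigidly rotating spiral in 2-D tissue.
#'
#' For LR91 the slow-inward Ca2+ conductance `gsi` (mS/cm^2, nominal
#' 0.09) replaces the published value directly; lowering it shortens the
#' action potential and controls rotor meander. For CRN, conductance
#' scale factors `s_cal`, `s_to`, `s_kur` multiply I_CaL, I_to and I_Kur;
#' all default to 1 (the published model). [af_remodeling()] returns the
#' scale set used for the rotor experiments.
#'
#' The resting state is obtained by letting a single quiescent cell relax
#' numerically, so it is a fixed point of the right-hand side for any
#' parameter choice.
#'
#' @param name one of `"fhn"`, `"lr91"`, `"crn"`.
#' @param params named list overriding default parameter values.
#' @param quiet suppress the notice emitted when CRN scale factors are
#'   left at their defaults.
#' @return an object of class `cell_model` with fields `name`,
#'   `state_names`, `params`, `resting_state`, `v_bounds`, `dt_default`.
#' @examples
#' m <- cell_model("fhn")
#' max(abs(model_rhs(m, m$resting_state)))   # fixed point
#' @export
cell_model <- function(name = c("fhn", "lr91", "crn"), params = list(),
                       quiet = FALSE) {
  name <- match.arg(name)
  defaults <- switch(name,
    fhn  = c(a = 0.1, eps = 0.01, beta = 0.5, gamma = 2, delta = 0),
    lr91 = c(gna = 23, gsi = 0.09, gk = 0.282, gk1 = 0.6047,
             gkp = 0.0183, gb = 0.03921, tau_d_scale = 1, tau_f_scale = 1),
    crn  = c(s_cal = 1, s_to = 1, s_kur = 1))
  if (length(params)) {
    bad <- setdiff(names(params), names(defaults))
    if (length(bad))
      stop("unknown ", name, " parameter(s): ", paste(bad, collapse = ", "))
    defaults[names(params)] <- unlist(params)
  }
  if (name == "lr91" && defaults[["gsi"]] < 0)
    stop("Gsi must be non-negative")
  if (name == "crn" && !quiet &&
      !any(c("s_cal", "s_to", "s_kur") %in% names(params)))
    message("crn: no conductance scale factors supplied; ",
            "using the unmodified published model (all scales = 1)")
  m <- structure(list(
    name = name,
    state_names = switch(name,
      fhn  = c("v", "w"),
      lr91 = c("V", "m", "h", "j", "d", "f", "X", "Cai"),
      crn  = c("V", "m", "h", "j", "oa", "oi", "ua", "ui", "xr", "xs",
               "d", "f", "fca", "Cai", "Caup", "Carel", "Nai", "Ki",
               "u", "v", "w")),
    params = defaults,
    v_bounds = switch(name, fhn = c(-0.5, 1.5), c(-100, 60)),
    dt_default = switch(name, fhn = 0.05, 0.02),
    model_id = switch(name, fhn = 0L, lr91 = 1L, crn = 2L)
  ), class = "cell_model")
  m$resting_state <- settle_to_rest(m)
  names(m$resting_state) <- m$state_names
  m
}

#' @export
print.cell_model <- function(x, ...) {
  cat("<cell_model>", x$name, "\n")
  cat("  states:", paste(x$state_names, collapse = ", "), "\n")
  cat("  params:", paste(names(x$params), signif(x$params, 4),
                         sep = "=", collapse = ", "), "\n")
  cat("  resting V:", signif(x$resting_state[[1]], 5), "\n")
  invisible(x)
}

#' AF-remodeling conductance scale factors for the CRN model
#'
#' Scale set (I_CaL x 0.3, I_to x 0.5, I_Kur x 0.5) that shortens the
#' atrial action potential enough to sustain a stable rotor in a
#' desk-scale sheet; a typical electrically remodelled parameterization.
#' @return named list suitable for `cell_model("crn", params = ...)`.
#' @export
af_remodeling <- function() list(s_cal = 0.3, s_to = 0.5, s_kur = 0.5)

# relax a quiescent cell to its rest state
settle_to_rest <- function(model) {
  seed <- switch(model$name,
    fhn  = c(0, 0),
    lr91 = c(-84.5, 0.0017, 0.983, 0.995, 0.003, 1, 0.0057, 2e-4),
    crn  = c(-81.18, 2.908e-3, 0.9649, 0.9775, 3.043e-2, 0.9992, 4.966e-3,
             0.9986, 3.296e-5, 1.869e-2, 1.367e-4, 0.9996, 0.7755, 1.013e-4,
             1.488, 1.488, 11.17, 139.0, 0, 1, 0.9992))
  dur <- switch(model$name, fhn = 500, lr91 = 5000, crn = 10000)
  dt <- model$dt_default
  out <- integrate_cell_cpp(model$model_id, seed, model$params, dt,
                            as.integer(round(dur / dt)), as.integer(round(dur / dt)),
                            0, 0, 0, 0)
  out$final
}

#' Evaluate the model right-hand side
#'
#' Time derivatives of the kinetic state (local reaction term only; the
#' diffusion term is added by [simulate_tissue()]).
#'
#' @param model a [cell_model()].
#' @param state numeric state vector (voltage first).
#' @return numeric vector of time derivatives (model-native units per
#'   time unit; ms for LR91/CRN).
#' @export
model_rhs <- function(model, state) {
  stopifnot(inherits(model, "cell_model"))
  fun <- switch(model$name, fhn = fhn_rhs_cpp, lr91 = lr91_rhs_cpp,
                crn = crn_rhs_cpp)
  out <- fun(as.numeric(state), model$params)
  names(out) <- model$state_names
  out
}

#' Pace a single cell with a periodic current stimulus
#'
#' @param model a [cell_model()].
#' @param cl pacing cycle length (model time units).
#' @param n_beats number of stimuli.
#' @param dt integration step; default `model$dt_default`.
#' @param record_dt sampling interval of the returned recording.
#' @param stim_amp,stim_dur stimulus amplitude (added to dV/dt) and
#'   duration; defaults chosen per model to be ~2x threshold.
#' @param state0 initial state; defaults to the resting state.
#' @return list with `time`, `states` (matrix, one row per state
#'   variable) and `final` state vector.
#' @export
pace_cell <- function(model, cl, n_beats = 1, dt = model$dt_default,
                      record_dt = max(dt, cl / 2000),
                      stim_amp = switch(model$name, fhn = 0.5, lr91 = 40, 20),
                      stim_dur = switch(model$name, fhn = 1, 2),
                      state0 = model$resting_state) {
  rec_every <- max(1L, as.integer(round(record_dt / dt)))
  n_steps <- as.integer(round(cl * n_beats / dt))
  out <- integrate_cell_cpp(model$model_id, as.numeric(state0), model$params,
                            dt, n_steps, rec_every, cl, stim_dur, stim_amp, 0)
  rownames(out$states) <- model$state_names
  list(time = out$time, states = out$states, final = out$final)
}

#' Action potential duration at 90% repolarization
#'
#' Measured on a single AP: from maximal upstroke velocity to recovery
#' through 90% of the peak-to-rest amplitude.
#'
#' @param time,v time and voltage vectors covering one action potential.
#' @return APD90 in the units of `time`, or `NA` if the AP does not
#'   repolarize within the trace.
#' @export
apd90 <- function(time, v) {
  up <- which.max(diff(v))
  rest <- v[1]
  peak <- max(v)
  thr <- peak - 0.9 * (peak - rest)
  after <- which(v[-seq_len(up)] < thr)
  if (!length(after)) return(NA_real_)
  time[up + after[1]] - time[up]
}

#' Build a phase-indexed action-potential cycle library
#'
#' Paces a single cell to a periodic steady state, extracts one full
#' cycle and indexes it by a phase coordinate theta in \[0, 1\]:
#' theta = 1 is the wavefront depolarization (maximal dv/dt) and
#' theta = 0 is the resting state. Intermediate phases copy the
#' stationary distribution of all kinetic variables within the cycle,
#' so that [init_spiral()] can paint a propagating-wave state onto a
#' tissue grid.
#'
#' @param model a [cell_model()].
#' @param pacing_cl pacing cycle length; defaults: FHN 200 t.u.,
#'   LR91 400 ms, CRN 500 ms.
#' @param n_theta number of phase samples (>= 100).
#' @param dt integration step.
#' @param budget_beats maximum number of beats allowed to reach the
#'   periodic steady state.
#' @param tol steady-state criterion: maximal voltage difference between
#'   consecutive beats (model voltage units).
#' @return object of class `cycle_library`: `theta` (monotone grid on
#'   \[0,1\]), `states` (n_theta x n_state matrix), `model`, `pacing_cl`.
#' @export
build_cycle_library <- function(model,
                                pacing_cl = switch(model$name, fhn = 200,
                                                   lr91 = 400, 500),
                                n_theta = 256, dt = model$dt_default,
                                budget_beats = 20,
                                tol = switch(model$name, fhn = 5e-3, 0.5)) {
  stopifnot(inherits(model, "cell_model"), n_theta >= 100)
  rec_every <- max(1L, as.integer(floor(pacing_cl / 2000 / dt)))
  steps_beat <- as.integer(round(pacing_cl / dt))
  state <- as.numeric(model$resting_state)
  prev_v <- NULL
  cycle <- NULL
  for (b in seq_len(budget_beats)) {
    out <- integrate_cell_cpp(model$model_id, state, model$params, dt,
                              steps_beat, rec_every, pacing_cl,
                              switch(model$name, fhn = 1, 2),
                              switch(model$name, fhn = 0.5, lr91 = 40, 20), 0)
    state <- out$final
    v <- out$states[1, ]
    if (!is.null(prev_v) && max(abs(v - prev_v)) < tol) {
      cycle <- out
      break
    }
    prev_v <- v
  }
  if (is.null(cycle))
    stop("no periodic steady state within ", budget_beats,
         " beats at CL = ", pacing_cl,
         " (last beat-to-beat voltage change = ",
         signif(max(abs(out$states[1, ] - prev_v)), 3), ", tol = ", tol, ")")
  tt <- cycle$time
  st <- cycle$states                       # ns x nt
  # theta = 1 anchors at the maximal instantaneous dv/dt of the cycle
  rhs_fun <- switch(model$name, fhn = fhn_rhs_cpp, lr91 = lr91_rhs_cpp,
                    crn = crn_rhs_cpp)
  dvdt <- vapply(seq_len(ncol(st)),
                 function(k) rhs_fun(st[, k], model$params)[1], numeric(1))
  t_up <- tt[which.max(dvdt)]
  theta <- seq(0, 1, length.out = n_theta)
  # phase theta maps to elapsed time (1 - theta) * CL after the upstroke
  tq <- (t_up + (1 - theta) * pacing_cl) %% pacing_cl
  ns <- nrow(st)
  lib <- matrix(NA_real_, n_theta, ns)
  for (k in seq_len(ns))
    lib[, k] <- approx(tt, st[k, ], xout = tq, rule = 2)$y
  lib[1, ] <- as.numeric(model$resting_state)   # theta = 0 is rest by definition
  colnames(lib) <- model$state_names
  structure(list(theta = theta, states = lib, model = model,
                 pacing_cl = pacing_cl),
            class = "cycle_library")
}

#' @export
print.cycle_library <- function(x, ...) {
  cat("<cycle_library>", x$model$name, " CL =", x$pacing_cl,
      " n_theta =", length(x$theta), "\n")
  cat("  voltage range:", paste(signif(range(x$states[, 1]), 4),
                                collapse = " .. "), "\n")
  invisible(x)
}

#' Interpolate a cycle library at arbitrary phases
#'
#' @param library a [build_cycle_library()] result.
#' @param theta numeric vector of phases in \[0, 1\].
#' @return matrix `length(theta)` x n_state of interpolated states.
#' @export
library_interp <- function(library, theta) {
  stopifnot(inherits(library, "cycle_library"))
  if (any(theta < 0 | theta > 1)) stop("theta must lie in [0, 1]")
  th <- library$theta
  n <- length(th)
  pos <- pmin(pmax(theta, 0), 1) * (n - 1) + 1
  i0 <- pmin(floor(pos), n - 1)
  f <- pos - i0
  library$states[i0, , drop = FALSE] * (1 - f) +
    library$states[i0 + 1, , drop = FALSE] * f
}
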