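#' Turgor error signal
#'
#' The input to both controller branches: the deviation of the turgor
#' pressure from its resting value, `e = Pt0 - Pt`. Positive under turgor
#' loss, negative on overshoot.
#'
#' @param Pt Current turgor pressure(s).
#' @param Pt0 Resting turgor pressure.
#' @return Error signal(s).
#' @export
error_signal <- function(Pt, Pt0) Pt0 - Pt

#' Glycerol flux over the Fps1 channel
#'
#' Fick diffusion between the intracellular and extracellular glycerol
#' concentrations, gated by the channel permeability:
#' \deqn{u_{Diff} = u_{Fps1}\left(\frac{Gly}{V - V_b} -
#'       \frac{Gly_e}{V_e}\right).}
#' Positive flux is export. The flux vanishes when the concentrations are
#' equal or the channel is closed.
#'
#' @param uFps1 Channel permeability.
#' @param Gly,Glye Intracellular and extracellular glycerol amounts.
#' @param V Cell volume (must exceed `Vb`).
#' @param params An [osmo_params()] set.
#' @return Glycerol flux (amount per minute).
#' @export
glycerol_diffusion <- function(uFps1, Gly, Glye, V, params = osmo_params()) {
  params <- validate_params(params)
  if (any(V <= params$Vb)) {
    stop("V <= Vb: osmotic volume is nonpositive", call. = FALSE)
  }
  uFps1 * (Gly / (V - params$Vb) - Glye / params$Ve)
}

#' Full model right-hand side (reference implementation)
#'
#' Assembles pressures, error, controller outputs and fluxes at one state
#' and returns the state derivative. This is the plain-R reference for
#' the compiled right-hand side used by the integrators; the two agree to
#' machine precision and the tests hold them to that.
#'
#' The state is `c(V, uHOG, Gly, Glye, z, Q)`: `z` accumulates the Hog1
#' activation (it drives the integral Hog branches; the finite window
#' evaluates `z(t) - z(t - Tm)`) and `Q` accumulates the glycerol
#' production `vHOG`, so that `Gly + Glye - Q` is an exact invariant of
#' the dynamics.
#'
#' @param t Time (minutes).
#' @param state Named state vector as returned by [equilibrium_state()].
#' @param scheme A [scheme_config()].
#' @param shock A [shock_input()].
#' @param params An [osmo_params()] set.
#' @param zlag Lagged cumulative activation `z(t - Tm)` (finite-window
#'   Hog branch only; 0 before the window fills).
#' @return A list with `deriv` (named derivative vector) and `outputs`
#'   (named vector `uFps1, vHOG, uDiff, e, Pt, Pi, Pe`).
#' @export
model_rhs <- function(t, state, scheme, shock, params = osmo_params(),
                      zlag = 0) {
  params <- validate_params(params)
  br <- scheme_branches(scheme, params)
  V <- unname(state[["V"]])
  uHOG <- unname(state[["uHOG"]])
  Gly <- max(unname(state[["Gly"]]), 0)
  Glye <- max(unname(state[["Glye"]]), 0)
  z <- unname(state[["z"]])

  Pe <- extracellular_pressure(t, shock, params)
  Pt <- turgor_pressure(V, params)
  Pi <- intracellular_pressure(Gly, V, params)
  e <- error_signal(Pt, params$Pt0)

  uFps1 <- fps1_output(e, br$fps1)
  vHOG <- if (inherits(br$hog, "hog_integral")) {
    zwin <- if (is.finite(br$hog$Tm)) z - zlag else z
    br$hog$kHOG * zwin
  } else {
    hog_unf_output(uHOG, br$hog)
  }
  uDiff <- glycerol_diffusion(uFps1, Gly, Glye, V, params)

  deriv <- c(
    V = volume_derivative(Pi, Pe, Pt, params),
    uHOG = hog_activation_rhs(e, uHOG, br$activation),
    Gly = vHOG - uDiff,
    Glye = uDiff,
    z = uHOG,
    Q = vHOG
  )
  list(deriv = deriv,
       outputs = c(uFps1 = uFps1, vHOG = vHOG, uDiff = uDiff, e = e,
                   Pt = Pt, Pi = Pi, Pe = Pe))
}

# Parameter vector for the compiled right-hand side; layout must match
# src/osmo.c. hog_kind codes: 1 Hill (incl. proportional), 2 ideal
# integral, 3 finite-window integral.
.osmo_parms_vector <- function(scheme, shock, params) {
  br <- scheme_branches(scheme, params)
  hog_kind <- switch(scheme$hog_kind, PNF = 1, UNF = 1, INF = 2, FINF = 3)
  if (hog_kind == 1) {
    kHOG <- br$hog$kHOG; betaHOG <- br$hog$betaHOG; KHOG <- br$hog$KHOG
    nHOG <- br$hog$nHOG; Tm <- Inf
  } else {
    kHOG <- br$hog$kHOG; betaHOG <- 0; KHOG <- 1; nHOG <- 1
    Tm <- br$hog$Tm
  }
  c(params$kp1, params$s, params$Vb, params$V0, params$Pt0,
    params$Pe_equil, params$VPt0, params$Ve,
    br$activation$bHOG, br$activation$aHOG,
    br$fps1$kFps1, br$fps1$betaFps1, br$fps1$KFps1, br$fps1$nFps1,
    hog_kind, kHOG, betaHOG, KHOG, nHOG, Tm,
    params$c_osm * shock$amplitude_M, shock$t_on)
}

.traj_outputs <- c("uFps1", "vHOG", "uDiff", "e", "Pt", "Pi", "Pe")

# Adaptive integration with the integration restarted at the shock onset,
# so the step discontinuity in Pe is never stepped across.
.lsoda_osmo <- function(pv, y0, times, rtol, atol) {
  run <- function(pv, y0, tt) {
    sol <- deSolve::lsoda(y = unname(y0), times = tt, func = "osmo_derivs",
                          parms = pv, dllname = "osmounf",
                          initfunc = "osmo_initmod", nout = 7,
                          rtol = rtol, atol = atol, maxsteps = 20000)
    diagn <- attr(sol, "istate")
    if (!is.null(diagn) && diagn[1] < 0) {
      stop("ODE solver failed (istate = ", diagn[1], ")", call. = FALSE)
    }
    mat <- unclass(sol)
    if (nrow(mat) < length(tt) || any(!is.finite(mat))) {
      stop("ODE solution incomplete or non-finite", call. = FALSE)
    }
    mat
  }
  amp <- pv[21]
  t_on <- pv[22]
  if (amp == 0 || t_on <= min(times) || t_on >= max(times)) {
    return(run(pv, y0, times))
  }
  t1 <- sort(unique(c(times[times < t_on], t_on)))
  pv1 <- pv
  pv1[21] <- 0
  sol1 <- run(pv1, y0, t1)
  y_on <- sol1[nrow(sol1), 2:7]
  t2 <- sort(unique(c(t_on, times[times >= t_on])))
  sol2 <- run(pv, y_on, t2)
  rbind(sol1[sol1[, 1] %in% times[times < t_on], , drop = FALSE],
        sol2[sol2[, 1] %in% times[times >= t_on], , drop = FALSE])
}

.as_trajectory <- function(mat, scheme, shock) {
  colnames(mat) <- c("time", "V", "uHOG", "Gly", "Glye", "z", "Q",
                     .traj_outputs)
  out <- tibble::as_tibble(as.data.frame(mat))
  out <- out[, c("time", "V", "uHOG", "Gly", "Glye", .traj_outputs,
                 "z", "Q")]
  class(out) <- c("osmo_trajectory", class(out))
  attr(out, "scheme") <- scheme$name
  attr(out, "shock") <- shock
  out
}

#' Simulate the closed-loop osmoshock response
#'
#' Integrates the full model from its consistent resting state under a
#' step osmoshock and reports the state together with the controller
#' outputs, fluxes, error and pressures on a uniform grid.
#'
#' Smooth schemes (Hill or ideal-integral Hog branch) are integrated with
#' the adaptive stiff-capable `lsoda` solver through a compiled
#' right-hand side; the finite-window integral branch, which needs a
#' lagged state, uses a fixed-step fourth-order Runge-Kutta integrator
#' with a per-step history buffer (the same engine that carries the
#' noisy simulations).
#'
#' @param scheme A [scheme_config()].
#' @param shock A [shock_input()].
#' @param params An [osmo_params()] set.
#' @param t_end Simulation horizon, minutes.
#' @param dt Reporting grid step, minutes.
#' @param method `"auto"` (default: adaptive where possible), `"adaptive"`
#'   or `"fixed"`.
#' @param h Step size of the fixed-step integrator, minutes.
#' @param rtol,atol Tolerances of the adaptive solver.
#' @return A tibble of class `osmo_trajectory` with columns `time`, `V`,
#'   `uHOG`, `Gly`, `Glye`, `uFps1`, `vHOG`, `uDiff`, `e`, `Pt`, `Pi`,
#'   `Pe` plus the bookkeeping states `z`, `Q`.
#' @examples
#' traj <- simulate_osmo(scheme_config("UNF-UNF"), shock_input(0.4))
#' traj[traj$time %in% c(0, 10, 60), c("time", "V", "uHOG", "e")]
#' @export
simulate_osmo <- function(scheme, shock, params = osmo_params(),
                          t_end = 60, dt = 1,
                          method = c("auto", "adaptive", "fixed"),
                          h = 0.01, rtol = 1e-8, atol = 1e-10) {
  method <- match.arg(method)
  stopifnot(inherits(scheme, "scheme_config"), inherits(shock, "shock_input"),
            t_end > 0, dt > 0, h > 0)
  params <- validate_params(params)
  y0 <- equilibrium_state(params)
  if (method == "auto") {
    method <- if (scheme$hog_kind == "FINF") "fixed" else "adaptive"
  }
  if (method == "adaptive" && scheme$hog_kind == "FINF") {
    stop("the finite-window integral branch requires method = \"fixed\"",
         call. = FALSE)
  }
  pv <- .osmo_parms_vector(scheme, shock, params)

  if (method == "adaptive") {
    times <- seq(0, t_end, by = dt)
    mat <- tryCatch(
      .lsoda_osmo(pv, y0, times, rtol, atol),
      error = function(e) {
        stop(conditionMessage(e), " for scheme ", scheme$name, ", shock ",
             shock$label, call. = FALSE)
      }
    )
    if (any(mat[, 2] <= params$Vb)) {
      stop("volume left the validity region (V <= Vb) for scheme ",
           scheme$name, ", shock ", shock$label, call. = FALSE)
    }
  } else {
    nstep <- ceiling(t_end / h)
    rep_every <- max(1L, round(dt / h))
    mat <- .Call(C_osmo_fixed, as.numeric(pv), unname(y0), as.numeric(h),
                 as.integer(nstep), as.integer(rep_every), c(0, 0))
  }
  .as_trajectory(mat, scheme, shock)
}

#' Simulate with noise on the controller outputs
#'
#' Fixed-step integration of the closed loop with independent Gaussian
#' perturbations added to the two controller outputs (`uFps1` and `vHOG`)
#' at every step. Perturbations are drawn per step with standard
#' deviation `sigma / sqrt(h)` and held across the Runge-Kutta stages, so
#' the integrated disturbance over a step has standard deviation
#' `sigma * sqrt(h)` independent of the step size.
#'
#' @inheritParams simulate_osmo
#' @param sigma_fps1,sigma_hog Noise standard deviations on the Fps1 and
#'   Hog1 controller outputs (>= 0; flux units per sqrt-minute).
#' @param n_rep Number of independent replicates (>= 1).
#' @param seed Optional RNG seed for reproducibility.
#' @return A tibble with the same columns as [simulate_osmo()] plus a
#'   leading `rep` column. The reported output columns are the
#'   deterministic maps evaluated at the (noisy) states.
#' @examples
#' ens <- simulate_noisy(scheme_config("UNF-UNF"), shock_input(0.4),
#'                       sigma_fps1 = 0.01, sigma_hog = 0.01,
#'                       n_rep = 3, seed = 1)
#' dplyr::count(ens, rep)
#' @export
simulate_noisy <- function(scheme, shock, params = osmo_params(),
                           t_end = 60, dt = 1,
                           sigma_fps1 = 0.01, sigma_hog = 0.01,
                           n_rep = 1, seed = NULL, h = 0.01) {
  stopifnot(inherits(scheme, "scheme_config"), inherits(shock, "shock_input"),
            sigma_fps1 >= 0, sigma_hog >= 0, n_rep >= 1, h > 0, t_end > 0)
  params <- validate_params(params)
  if (!is.null(seed)) set.seed(seed)
  y0 <- equilibrium_state(params)
  pv <- .osmo_parms_vector(scheme, shock, params)
  nstep <- ceiling(t_end / h)
  rep_every <- max(1L, round(dt / h))
  reps <- purrr::map(seq_len(n_rep), function(r) {
    mat <- .Call(C_osmo_fixed, as.numeric(pv), unname(y0), as.numeric(h),
                 as.integer(nstep), as.integer(rep_every),
                 as.numeric(c(sigma_fps1, sigma_hog)))
    tr <- .as_trajectory(mat, scheme, shock)
    tr$rep <- r
    tr
  })
  out <- dplyr::bind_rows(reps)
  dplyr::relocate(out, "rep")
}

#' Write or read a simulated trajectory as CSV
#'
#' Trajectories are stored with the header
#' `time,V,uHOG,Gly,Glye,uFps1,vHOG,uDiff,e,Pt,Pi,Pe`.
#'
#' @param traj An `osmo_trajectory` tibble.
#' @param path File path.
#' @return `write_trajectory` returns `path` invisibly;
#'   `read_trajectory` returns a tibble.
#' @export
write_trajectory <- function(traj, path) {
  cols <- c("time", "V", "uHOG", "Gly", "Glye", .traj_outputs)
  utils::write.csv(as.data.frame(traj)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}
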