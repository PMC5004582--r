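#' Turgor pressure as a function of cell volume
#'
#' Linear turgor-volume law: turgor falls linearly from its resting value
#' `Pt0` at `V = V0` to zero at the turgor-loss volume `VPt0`, and is zero
#' below it,
#' \deqn{P_t(V) = P_t(0)\,\frac{V - V^{P_t=0}}{V(0) - V^{P_t=0}}
#'       \quad (V > V^{P_t=0}), \qquad 0 \text{ otherwise.}}
#' The function is continuous, piecewise linear, nonnegative and
#' nondecreasing in `V`.
#'
#' @param V Cell volume(s), fraction of initial volume. Must be finite and
#'   positive.
#' @param params An `osmo_params` object.
#' @return Turgor pressure, same length as `V`.
#' @examples
#' p <- osmo_params()
#' turgor_pressure(1, p)       # resting turgor Pt0
#' turgor_pressure(p$VPt0, p)  # zero at the turgor-loss volume
#' @export
turgor_pressure <- function(V, params = osmo_params()) {
  params <- validate_params(params)
  if (!all(is.finite(V))) stop("V must be finite", call. = FALSE)
  if (any(V <= 0)) stop("V must be positive", call. = FALSE)
  pmax(0, params$Pt0 * (V - params$VPt0) / (params$V0 - params$VPt0))
}

#' Intracellular osmotic pressure (van't Hoff)
#'
#' Osmotic pressure from the constant non-glycerol osmolyte pool `s` plus
#' glycerol, over the osmotically active volume:
#' \deqn{P_i = \frac{s + Gly}{V - V_b}.}
#'
#' @param Gly Intracellular glycerol amount(s), nonnegative.
#' @param V Cell volume(s); must exceed the non-osmotic volume `Vb`.
#' @param params An `osmo_params` object.
#' @return Intracellular osmotic pressure.
#' @export
intracellular_pressure <- function(Gly, V, params = osmo_params()) {
  params <- validate_params(params)
  if (any(!is.finite(V)) || any(!is.finite(Gly))) {
    stop("V and Gly must be finite", call. = FALSE)
  }
  if (any(V <= params$Vb)) {
    stop("V <= Vb: osmotic volume is nonpositive", call. = FALSE)
  }
  if (any(Gly < 0)) stop("Gly must be nonnegative", call. = FALSE)
  (params$s + Gly) / (V - params$Vb)
}

#' Extracellular osmotic pressure under a step osmoshock
#'
#' The resting extracellular pressure plus the step input: zero before the
#' shock onset, and the shock amplitude (NaCl molarity converted to
#' pressure units by `c_osm`) at and after it. Superposed steps add.
#'
#' @param t Time(s), minutes.
#' @param shock A [shock_input()] (or a list of them, whose amplitudes
#'   superpose).
#' @param params An `osmo_params` object.
#' @return Extracellular osmotic pressure at each `t`.
#' @examples
#' sh <- shock_input(0.4, t_on = 5)
#' extracellular_pressure(c(0, 10), sh)
#' @export
extracellular_pressure <- function(t, shock, params = osmo_params()) {
  params <- validate_params(params)
  shocks <- if (inherits(shock, "shock_input")) list(shock) else shock
  u <- rep(0, length(t))
  for (sh in shocks) {
    stopifnot(inherits(sh, "shock_input"))
    u <- u + ifelse(t >= sh$t_on, params$c_osm * sh$amplitude_M, 0)
  }
  params$Pe_equil + u
}

#' Rate of volume change from the water-flux balance
#'
#' Water flows across the membrane in proportion to the pressure
#' imbalance: \deqn{\dot V = k_{p1} (P_i - P_e - P_t).}
#' The rate is zero exactly on the equilibrium manifold
#' \eqn{P_i = P_e + P_t}.
#'
#' @param Pi,Pe,Pt Intracellular, extracellular and turgor pressures
#'   (finite, recyclable vectors).
#' @param params An `osmo_params` object.
#' @return Volume rate of change (volume per minute).
#' @export
volume_derivative <- function(Pi, Pe, Pt, params = osmo_params()) {
  params <- validate_params(params)
  if (any(!is.finite(c(Pi, Pe, Pt)))) {
    stop("pressures must be finite", call. = FALSE)
  }
  params$kp1 * (Pi - Pe - Pt)
}

#' Consistent resting state of the closed-loop model
#'
#' Solves the no-shock equilibrium of the full model: volume at `V0`,
#' Hog1 activation at zero, intracellular glycerol inverting the van't
#' Hoff law so that `Pi = Pe_equil + Pt0`, and extracellular glycerol
#' matching the intracellular concentration so the Fps1 diffusion flux
#' vanishes. Every component of the model right-hand side is zero at this
#' state for any controller scheme whose laws vanish at zero error and
#' zero activation.
#'
#' @param params An `osmo_params` object.
#' @return A named numeric state vector
#'   `c(V, uHOG, Gly, Glye, z, Q)` where `z` is the cumulative integral of
#'   Hog1 activation (used by the integral controller branches) and `Q`
#'   the cumulative glycerol production (bookkeeping).
#' @examples
#' equilibrium_state(osmo_params())
#' @export
equilibrium_state <- function(params = osmo_params()) {
  params <- validate_params(params)
  Gly0 <- (params$Pe_equil + params$Pt0) * (params$V0 - params$Vb) - params$s
  if (Gly0 < 0) {
    stop("inconsistent parameters: equilibrium glycerol is negative ",
         "(Gly(0) = ", signif(Gly0, 4), "); decrease s or increase ",
         "Pe_equil + Pt0", call. = FALSE)
  }
  Glye0 <- params$Ve * Gly0 / (params$V0 - params$Vb)
  c(V = params$V0, uHOG = 0, Gly = Gly0, Glye = Glye0, z = 0, Q = 0)
}
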