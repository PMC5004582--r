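#' Generic first-order closed loop
#'
#' The testbed process is first order with pole `a` and input gain `b`:
#' the internal state obeys `x' = -a x + b (v0 + u)`, the measured output
#' is `y = x + u_d` (the step disturbance enters additively at the
#' output) and the controller sees `e = r - y`. `v0 = a y0 / b` is the
#' nominal controller-side bias sustaining the pre-disturbance
#' equilibrium at `y0`; with `y0 = 0` it vanishes and the loop reduces to
#' the bias-free form whose steady states lie on
#' `a (r - e - a_ud) = b g(e)`.
#'
#' @param a Process pole (> 0), inverse minutes.
#' @param b Process input gain.
#' @param r Reference (set-point).
#' @param y0 Initial output; defaults to the reference.
#' @return A list of class `feedback_loop` (includes the derived time
#'   constant `tau = 1/a` and bias `v0`).
#' @examples
#' feedback_loop()              # a = b = r = y0 = 1
#' feedback_loop(y0 = 0)        # starts away from the set-point
#' @export
feedback_loop <- function(a = 1, b = 1, r = 1, y0 = r) {
  stopifnot(a > 0, b != 0)
  structure(list(a = a, b = b, r = r, y0 = y0, tau = 1 / a,
                 v0 = a * y0 / b),
            class = "feedback_loop")
}

#' Step disturbance
#'
#' @param a_ud Step amplitude (any sign).
#' @param t_on Onset time, minutes.
#' @return A list of class `disturbance`.
#' @export
disturbance <- function(a_ud, t_on = 1) {
  stopifnot(is.finite(a_ud), is.finite(t_on), t_on >= 0)
  structure(list(a_ud = a_ud, t_on = t_on), class = "disturbance")
}

.loop_kind_code <- c(P = 1, I = 2, FI = 3, UNF = 4, SMC = 5, SAT = 6)

# Conservative default step for the fixed-step loop integrator: resolves
# the fastest closed-loop rate (including the high local slope of a
# near-switching UNF law) and keeps the discontinuous laws at 1e-3.
.loop_default_h <- function(ctrl, loop) {
  switch(ctrl$kind,
    SMC = 1e-3,
    SAT = min(1e-3, 0.2 / (abs(loop$b) * ctrl$kp * ctrl$m + loop$a)),
    UNF = {
      slope_max <- 0.65 * ctrl$kp * ctrl$n / ctrl$K
      min(0.01, 0.5 / (abs(loop$b) * slope_max + loop$a))
    },
    P = min(0.01, 0.5 / (abs(loop$b * ctrl$kp) + loop$a)),
    0.01
  )
}

#' Simulate the generic closed loop
#'
#' Fixed-step fourth-order Runge-Kutta integration of the loop under a
#' step disturbance, for any controller kind. The default step is 1e-3
#' minutes for the discontinuous laws (sliding mode and saturation, whose
#' chattering must be resolved) and is shrunk automatically for
#' ultrasensitive laws with small `K`, whose local slope near the
#' manifold is large.
#'
#' @param ctrl A [generic_controller()].
#' @param loop A [feedback_loop()].
#' @param dist A [disturbance()].
#' @param t_end Horizon, minutes (> disturbance onset).
#' @param h Step size; `NULL` for the law-dependent default.
#' @param report_every Record every this-many steps (1 = all).
#' @return A tibble of class `loop_trajectory` with columns `time`, `y`,
#'   `e`, `u` (the controller's corrective output, excluding the nominal
#'   bias `v0`).
#' @examples
#' smc <- generic_controller("SMC", kp = 0.25)
#' tr <- simulate_loop(smc, feedback_loop(), disturbance(0.2), t_end = 10)
#' tail(tr$e, 1)  # confined to a chattering band around zero
#' @export
simulate_loop <- function(ctrl, loop = feedback_loop(),
                          dist = disturbance(0.2), t_end = 30,
                          h = NULL, report_every = 1L) {
  stopifnot(inherits(ctrl, "generic_controller"),
            inherits(loop, "feedback_loop"),
            inherits(dist, "disturbance"))
  if (t_end <= dist$t_on) stop("t_end must exceed the disturbance onset",
                               call. = FALSE)
  if (is.null(h)) h <- .loop_default_h(ctrl, loop)
  stopifnot(h > 0)
  get0c <- function(nm, default) ctrl[[nm, exact = TRUE]] %||% default
  cpar <- c(get0c("kp", 0), get0c("ki", 0), get0c("K", 0),
            get0c("n", 0), get0c("m", 0), get0c("Tm", Inf))
  lpar <- c(loop$a, loop$b, loop$r, loop$y0, loop$v0, dist$a_ud, dist$t_on)
  nstep <- ceiling(t_end / h)
  mat <- .Call(C_loop_fixed, as.integer(.loop_kind_code[[ctrl$kind]]),
               as.numeric(cpar), as.numeric(lpar), as.numeric(h),
               as.integer(nstep), as.integer(report_every))
  colnames(mat) <- c("time", "y", "e", "u")
  out <- tibble::as_tibble(as.data.frame(mat))
  class(out) <- c("loop_trajectory", class(out))
  attr(out, "ctrl") <- ctrl
  attr(out, "h") <- h
  out
}

#' Steady-state error of the closed loop
#'
#' For the static laws (P, UNF, SAT, SMC) the steady state solves
#' \deqn{a (r - e - a_{ud}) = b\,(v_0 + g(e)),}
#' where `g` is the controller's static map and `v0` the nominal bias of
#' the loop; the left-hand side minus the right is strictly decreasing in
#' `e`, so the root is unique and found by bracketed root finding. For
#' the ideal sliding-mode law the manifold `e = 0` is an equilibrium
#' (in the set-valued sense, `sgn(0)` free in `[-1, 1]`) whenever the
#' required holding control lies within `[-kp, kp]`; in that case the
#' steady error is exactly 0, otherwise the saturated branch is solved.
#' The ideal integral law gives exactly 0 for any step disturbance.
#'
#' @param ctrl A [generic_controller()] (`P`, `I`, `UNF`, `SAT` or
#'   `SMC`).
#' @param loop A [feedback_loop()].
#' @param a_ud Step disturbance amplitude.
#' @return The steady-state error (scalar).
#' @examples
#' ss <- steady_state_error(generic_controller("UNF", kp = 1, K = 0.01, n = 2),
#'                          feedback_loop(), a_ud = 0.2)
#' abs(ss) < boundary_layer(0.01, 2)
#' @export
steady_state_error <- function(ctrl, loop = feedback_loop(), a_ud = 0.2) {
  stopifnot(inherits(ctrl, "generic_controller"),
            inherits(loop, "feedback_loop"))
  if (ctrl$kind == "I") return(0)
  if (ctrl$kind == "FI") {
    stop("the finite-window integral law has no static steady-state map; ",
         "use simulate_loop()", call. = FALSE)
  }
  # residual of the steady-state balance; strictly decreasing in e
  f <- function(e) {
    loop$a * (loop$r - e - a_ud) -
      loop$b * (loop$v0 + generic_controller_output(e, ctrl))
  }
  if (ctrl$kind == "SMC") {
    hold <- loop$a * (loop$r - a_ud) / loop$b - loop$v0
    if (abs(hold) <= ctrl$kp) return(0)
  }
  lo <- -1; hi <- 1
  span <- abs(loop$r) + abs(a_ud) + abs(loop$v0) + 1
  while (f(lo) < 0 && lo > -1e6) lo <- lo - span
  while (f(hi) > 0 && hi < 1e6) hi <- hi + span
  if (!(f(lo) >= 0 && f(hi) <= 0)) {
    stop("no bracketing interval for the steady-state error", call. = FALSE)
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
}

#' Sliding-mode gain condition
#'
#' For a loop starting on the set-point (`y0 = r`), a sliding-mode gain
#' strictly exceeding the disturbance amplitude is sufficient to reject a
#' step disturbance completely (the sliding manifold `e = 0` is reached
#' and held). The condition is strict: `kp = |a_ud|` fails. When the
#' output starts away from the set-point an additional reaching term
#' enters the gain requirement; unless that term is supplied the result
#' is indeterminate.
#'
#' @param kp Sliding-mode gain.
#' @param a_ud Step disturbance amplitude.
#' @param y0 Initial output.
#' @param r Reference.
#' @param L Optional reaching-gain term for the `y0 != r` case; if
#'   supplied, the condition checked is `kp > |a_ud| + L`.
#' @return A tibble with columns `pass` (logical, `NA` when
#'   indeterminate), `margin` (`kp - |a_ud|` minus any reaching term) and
#'   `case` (`"sliding"` or `"reaching"`).
#' @examples
#' smc_gain_condition(0.25, 0.2)  # pass, margin 0.05
#' smc_gain_condition(0.2, 0.2)   # boundary case fails (strict)
#' @export
smc_gain_condition <- function(kp, a_ud, y0 = 1, r = 1, L = NULL) {
  if (isTRUE(all.equal(y0, r))) {
    margin <- kp - abs(a_ud)
    return(tibble::tibble(pass = margin > 0, margin = margin,
                          case = "sliding"))
  }
  if (is.null(L)) {
    return(tibble::tibble(pass = NA, margin = NA_real_, case = "reaching"))
  }
  margin <- kp - abs(a_ud) - L
  tibble::tibble(pass = margin > 0, margin = margin, case = "reaching")
}

#' Chattering-aware steady error of a simulated loop
#'
#' Summarizes the tail of a loop trajectory: the mean error over the last
#' fraction of the horizon (the chattering-band midpoint for sliding-mode
#' laws) and the band half-width around it.
#'
#' @param traj A `loop_trajectory` tibble.
#' @param tail_frac Fraction of the horizon to average over.
#' @return A tibble with columns `e_ss` (band midpoint) and `half_width`.
#' @export
loop_steady_summary <- function(traj, tail_frac = 0.1) {
  stopifnot(inherits(traj, "loop_trajectory"), tail_frac > 0, tail_frac <= 1)
  t1 <- max(traj$time)
  tail <- traj$e[traj$time >= t1 - tail_frac * (t1 - min(traj$time))]
  tibble::tibble(e_ss = mean(tail),
                 half_width = (max(tail) - min(tail)) / 2)
}
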