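#' Generic controller specification
#'
#' Describes one static or integral control law for the generic
#' first-order closed loop:
#'
#' * `"P"` — proportional, `u = kp * e`;
#' * `"I"` — ideal integral, `u = ki * \int_0^t e`;
#' * `"FI"` — finite-window integral, `u = ki * \int_{t-Tm}^t e`;
#' * `"UNF"` — ultrasensitive negative feedback,
#'   `u = sgn(e) kp |e|^n / (|e|^n + K^n)`;
#' * `"SMC"` — ideal sliding mode, `u = kp * sgn(e)` (with `sgn(0) = 0`);
#' * `"SAT"` — saturated high-slope linear law, `u = kp * sat(m e)` where
#'   `sat` clips at +/-1. When `m` is omitted but `K` and `n` are given,
#'   the slope defaults to `m = n / (4 K)`, the piecewise-linear
#'   approximation of the matching UNF law.
#'
#' @param kind One of `"P"`, `"I"`, `"FI"`, `"UNF"`, `"SMC"`, `"SAT"`.
#' @param kp Gain of the static laws.
#' @param ki Integral gain.
#' @param K Half-max constant of the UNF law (> 0).
#' @param n Hill exponent of the UNF law (>= 1).
#' @param m Slope of the saturation law.
#' @param Tm Integration window, minutes (finite for `"FI"`).
#' @return A classed list of kind and constants.
#' @examples
#' generic_controller("UNF", kp = 1, K = 0.01, n = 2)
#' generic_controller("SAT", kp = 1, K = 0.01, n = 2)  # m = n/(4K) = 50
#' @export
generic_controller <- function(kind = c("P", "I", "FI", "UNF", "SMC", "SAT"),
                               kp = NULL, ki = NULL, K = NULL, n = NULL,
                               m = NULL, Tm = Inf) {
  kind <- match.arg(kind)
  need <- function(x, what) {
    if (is.null(x)) {
      stop("controller kind ", kind, " requires constant ", what,
           call. = FALSE)
    }
    x
  }
  spec <- switch(kind,
    P = list(kp = need(kp, "kp")),
    I = list(ki = need(ki, "ki")),
    FI = {
      if (!is.finite(Tm) || Tm <= 0) {
        stop("FI requires a finite positive window Tm", call. = FALSE)
      }
      list(ki = need(ki, "ki"), Tm = Tm)
    },
    UNF = {
      K <- need(K, "K"); n <- need(n, "n")
      stopifnot(K > 0, n >= 1)
      list(kp = need(kp, "kp"), K = K, n = n)
    },
    SMC = list(kp = need(kp, "kp")),
    SAT = {
      if (is.null(m)) {
        if (is.null(K) || is.null(n)) {
          stop("SAT requires m (or K and n for m = n/(4K))", call. = FALSE)
        }
        m <- n / (4 * K)
      }
      stopifnot(m > 0)
      c(list(kp = need(kp, "kp"), m = m),
        if (!is.null(K)) list(K = K), if (!is.null(n)) list(n = n))
    }
  )
  structure(c(list(kind = kind), spec), class = "generic_controller")
}

#' Static output of a generic controller
#'
#' Evaluates the control signal for an error value. The integral laws
#' (`I`, `FI`) take their (windowed) error integral through `state`.
#'
#' @param e Error value(s).
#' @param ctrl A [generic_controller()].
#' @param state For `I`/`FI`: the (windowed) time-integral of the error.
#' @return Control signal, same length as `e`.
#' @examples
#' u <- generic_controller("UNF", kp = 1, K = 0.1, n = 2)
#' generic_controller_output(0.1, u)  # half-max: kp/2
#' @export
generic_controller_output <- function(e, ctrl, state = 0) {
  stopifnot(inherits(ctrl, "generic_controller"))
  switch(ctrl$kind,
    P = ctrl$kp * e,
    I = ctrl$ki * state,
    FI = ctrl$ki * state,
    UNF = {
      ae <- abs(e)
      out <- sign(e) * ctrl$kp * ae^ctrl$n / (ae^ctrl$n + ctrl$K^ctrl$n)
      out[ae == 0] <- 0
      out
    },
    SMC = ctrl$kp * sign(e),
    SAT = ctrl$kp * pmax(-1, pmin(1, ctrl$m * e))
  )
}

#' Boundary layer of the ultrasensitive quasi-sliding-mode controller
#'
#' The ultrasensitive law is a smooth approximation of ideal sliding mode
#' control; instead of confining the error to the manifold `e = 0`, it
#' confines it to the boundary layer
#' \deqn{|e| < \frac{4K}{n},}
#' which therefore bounds the achievable steady-state error and serves as
#' a design rule relating the Hill constants to closed-loop precision.
#'
#' @param K Half-max constant (> 0).
#' @param n Hill exponent (>= 1).
#' @return The guaranteed steady-error bound `4 K / n`.
#' @examples
#' boundary_layer(0.01, 2)  # 0.02
#' @export
boundary_layer <- function(K, n) {
  if (any(K <= 0)) stop("K must be positive", call. = FALSE)
  if (any(n < 1)) stop("n must be >= 1", call. = FALSE)
  4 * K / n
}
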