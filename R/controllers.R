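#' Controller branch specifications
#'
#' Constructors for the four control laws a branch of the osmoregulation
#' model can carry:
#'
#' * `fps1_unf()` — the ultrasensitive (Hill-type) law of the Fps1
#'   glycerol channel. At Hill exponent 1 it reduces exactly to the
#'   proportional law `kFps1 (Pt0 - e) / Pt0`, because the dependent
#'   constants collapse to `betaFps1 = 0`, `KFps1 = Pt0`.
#' * `hog_unf()` — the ultrasensitive law of the Hog1-mediated glycerol
#'   production branch; at Hill exponent 1 it reduces to the proportional
#'   law `kHOG * uHOG` (with `betaHOG = 0`, `KHOG = 1`).
#' * `hog_activation()` — the first-order linear filter turning the turgor
#'   error into Hog1 activation.
#' * `hog_integral()` — the (finite-window) integral law driving glycerol
#'   production from the integrated Hog1 activation; `Tm = Inf` gives the
#'   ideal integrator.
#'
#' @param kFps1 Maximal Fps1 glycerol permeability (> 0).
#' @param keFps1,keHOG Shape constants of the ultrasensitive laws.
#' @param nFps1,nHOG Hill exponents (>= 1; real-valued).
#' @param Pt0 Resting turgor pressure (enters the dependent `KFps1`).
#' @param kHOG Gain of the Hog1 branch (> 0).
#' @param bHOG,aHOG Activation gain and decay rate of the Hog1 filter
#'   (both > 0, and expected to take similar values).
#' @param Tm Integration window in minutes (> 0, or `Inf` for the ideal
#'   integrator).
#' @param ratio_band Band for `bHOG/aHOG` outside which
#'   `hog_activation()` warns.
#' @return A classed list describing the branch.
#' @name controller_specs
NULL

#' @rdname controller_specs
#' @export
fps1_unf <- function(kFps1, keFps1, nFps1, Pt0) {
  stopifnot(kFps1 > 0, nFps1 >= 1, is.finite(keFps1), Pt0 >= 0)
  structure(list(
    kFps1 = kFps1, keFps1 = keFps1, nFps1 = nFps1, Pt0 = Pt0,
    betaFps1 = 1 - exp(keFps1 * (1 - nFps1)),
    KFps1 = Pt0 * exp(keFps1 * (1 - nFps1))
  ), class = "fps1_unf")
}

#' @rdname controller_specs
#' @export
hog_unf <- function(kHOG, keHOG, nHOG) {
  stopifnot(kHOG > 0, nHOG >= 1, is.finite(keHOG))
  structure(list(
    kHOG = kHOG, keHOG = keHOG, nHOG = nHOG,
    betaHOG = 1 - exp(keHOG * (1 - nHOG)),
    KHOG = exp(keHOG * (1 - nHOG))
  ), class = "hog_unf")
}

#' @rdname controller_specs
#' @export
hog_activation <- function(bHOG, aHOG, ratio_band = c(0.2, 5)) {
  stopifnot(bHOG > 0, aHOG > 0)
  ratio <- bHOG / aHOG
  if (ratio < ratio_band[1] || ratio > ratio_band[2]) {
    warning("bHOG/aHOG = ", signif(ratio, 3),
            " is outside the similar-values band", call. = FALSE)
  }
  structure(list(bHOG = bHOG, aHOG = aHOG), class = "hog_activation")
}

#' @rdname controller_specs
#' @export
hog_integral <- function(kHOG, Tm = Inf) {
  stopifnot(kHOG > 0, Tm > 0)
  structure(list(kHOG = kHOG, Tm = Tm), class = "hog_integral")
}

#' Fps1 channel output
#'
#' Glycerol permeability of the Fps1 channel as a function of the turgor
#' error,
#' \deqn{u_{Fps1}(e) = k_{Fps1} - \mathrm{sgn}(e)\,
#'   \frac{k_{Fps1} |e|^{n}}{\beta_{Fps1} |e|^{n} + K_{Fps1}},}
#' clamped below at zero (fully closed channel). Positive error (turgor
#' loss) closes the channel; negative error opens it beyond the baseline,
#' the sign/absolute-value form making the law symmetrical. The
#' denominator uses `KFps1` as printed, not raised to the Hill exponent.
#'
#' @param e Turgor pressure error(s), `Pt0 - Pt`.
#' @param spec An [fps1_unf()] spec.
#' @return Channel permeability, same length as `e`.
#' @examples
#' sp <- fps1_unf(0.5, 6, 2, Pt0 = 0.5)
#' fps1_output(0, sp)    # fully open at zero error
#' fps1_output(0.4, sp)  # closed under strong turgor loss
#' @export
fps1_output <- function(e, spec) {
  stopifnot(inherits(spec, "fps1_unf"))
  ae <- abs(e)
  denom <- spec$betaFps1 * ae^spec$nFps1 + spec$KFps1
  if (any(denom <= 0)) {
    stop("nonpositive denominator in Fps1 law; check keFps1/nFps1/Pt0",
         call. = FALSE)
  }
  pmax(0, spec$kFps1 - sign(e) * spec$kFps1 * ae^spec$nFps1 / denom)
}

#' Hog1 activation dynamics
#'
#' Right-hand side of the first-order linear filter turning the turgor
#' error into Hog1 activation: \eqn{\dot u_{HOG} = b_{HOG} e - a_{HOG} u_{HOG}}.
#'
#' @param e Turgor error(s).
#' @param uHOG Current Hog1 activation(s).
#' @param spec A [hog_activation()] spec.
#' @return Activation rate of change.
#' @export
hog_activation_rhs <- function(e, uHOG, spec) {
  stopifnot(inherits(spec, "hog_activation"))
  spec$bHOG * e - spec$aHOG * uHOG
}

#' Hog1-mediated glycerol production (ultrasensitive law)
#'
#' \deqn{v_{HOG}(u) = \frac{k_{HOG} u^{n}}{\beta_{HOG} u^{n} + K_{HOG}}
#'   \quad (u > 0), \qquad 0 \text{ otherwise:}}
#' the branch only produces glycerol for positive activation and is
#' switched off otherwise. For Hill exponent > 1 the output saturates at
#' `kHOG / betaHOG`.
#'
#' @param uHOG Hog1 activation(s).
#' @param spec A [hog_unf()] spec.
#' @return Glycerol production rate, same length as `uHOG`.
#' @export
hog_unf_output <- function(uHOG, spec) {
  stopifnot(inherits(spec, "hog_unf"))
  up <- pmax(uHOG, 0)
  out <- spec$kHOG * up^spec$nHOG / (spec$betaHOG * up^spec$nHOG + spec$KHOG)
  out[uHOG <= 0] <- 0
  out
}

#' Hog1-mediated glycerol production (windowed integral law)
#'
#' \deqn{v_{HOG}(t) = k_{HOG} \int_{t - T_m}^{t} u_{HOG}(\tau)\, d\tau,}
#' with the window truncated at 0 for `t < Tm` and the ideal integrator
#' (full history) for `Tm = Inf`. The activation history is interpolated
#' linearly between samples and integrated by the trapezoid rule on the
#' refined grid including the window endpoints.
#'
#' @param history A data frame with columns `time` and `uHOG` covering
#'   `[max(0, t - Tm), t]`.
#' @param spec A [hog_integral()] spec.
#' @param t Evaluation time.
#' @return Glycerol production rate at `t`.
#' @examples
#' h <- data.frame(time = 0:10, uHOG = rep(0.3, 11))
#' hog_integral_output(h, hog_integral(0.05, Tm = 4), t = 10)  # 0.05*0.3*4
#' @export
hog_integral_output <- function(history, spec, t) {
  stopifnot(inherits(spec, "hog_integral"), is.data.frame(history))
  if (!all(c("time", "uHOG") %in% names(history))) {
    stop("history needs columns time and uHOG", call. = FALSE)
  }
  lo <- max(0, t - spec$Tm)
  if (min(history$time) > lo + 1e-12 || max(history$time) < t - 1e-12) {
    stop("history does not cover [", signif(lo, 6), ", ", signif(t, 6), "]",
         call. = FALSE)
  }
  if (t <= lo) return(0)
  o <- order(history$time)
  ht <- history$time[o]
  hu <- history$uHOG[o]
  grid <- sort(unique(c(lo, ht[ht > lo & ht < t], t)))
  vals <- stats::approx(ht, hu, xout = grid, rule = 2)$y
  spec$kHOG * sum(diff(grid) * (utils::head(vals, -1) + utils::tail(vals, -1)) / 2)
}
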