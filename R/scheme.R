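#' The six controller schemes of the osmoregulation model
#'
#' A scheme names the control law carried by each of the two feedback
#' branches: the Fps1 glycerol channel (proportional `PNF` or
#' ultrasensitive `UNF`) and the Hog1-mediated glycerol production branch
#' (proportional `PNF`, ideal integral `INF`, finite-window integral
#' `FINF`, or ultrasensitive `UNF`).
#'
#' @return Character vector of the six scheme names.
#' @export
scheme_names <- function() {
  c("PNF-PNF", "PNF-INF", "PNF-FINF", "UNF-INF", "UNF-FINF", "UNF-UNF")
}

#' Configure a controller scheme
#'
#' Selects the control laws of the two branches. The proportional laws are
#' the Hill exponent 1 special cases of the ultrasensitive ones, so both
#' branches always draw their constants from the shared parameter set
#' ([osmo_params()]); the integral Hog branches additionally carry their
#' own gain `ki` and window `Tm`.
#'
#' @param name One of [scheme_names()].
#' @param ki Integral gain for the `INF`/`FINF` Hog branches.
#' @param Tm Integration window (minutes) for the `FINF` Hog branch.
#' @return A list of class `scheme_config` with fields `name`,
#'   `fps1_kind` (`"PNF"`/`"UNF"`), `hog_kind`
#'   (`"PNF"`/`"INF"`/`"FINF"`/`"UNF"`), `ki`, `Tm`.
#' @examples
#' scheme_config("UNF-UNF")
#' scheme_config("PNF-FINF", ki = 0.02, Tm = 10)
#' @export
scheme_config <- function(name, ki = 0.02, Tm = 10) {
  name <- match.arg(name, scheme_names())
  parts <- strsplit(name, "-", fixed = TRUE)[[1]]
  stopifnot(ki > 0, Tm > 0)
  structure(list(name = name, fps1_kind = parts[1], hog_kind = parts[2],
                 ki = ki, Tm = Tm),
            class = "scheme_config")
}

#' @export
print.scheme_config <- function(x, ...) {
  cat("<scheme_config> ", x$name, "\n", sep = "")
  cat("  Fps1 branch: ", x$fps1_kind, "\n", sep = "")
  cat("  Hog1 branch: ", x$hog_kind,
      if (x$hog_kind %in% c("INF", "FINF")) {
        paste0("  (ki = ", x$ki,
               if (x$hog_kind == "FINF") paste0(", Tm = ", x$Tm), ")")
      }, "\n", sep = "")
  invisible(x)
}

#' Branch specs of a scheme under a parameter set
#'
#' Materializes the controller branch specifications of a scheme from a
#' parameter set: the Fps1 law (Hill exponent forced to 1 for `PNF`), the
#' Hog1 production law, and the Hog1 activation filter.
#'
#' @param scheme A [scheme_config()].
#' @param params An [osmo_params()] set.
#' @return A list with elements `fps1`, `hog`, `activation`.
#' @export
scheme_branches <- function(scheme, params = osmo_params()) {
  stopifnot(inherits(scheme, "scheme_config"))
  params <- validate_params(params)
  fps1 <- if (scheme$fps1_kind == "UNF") {
    fps1_unf(params$kFps1, params$keFps1, params$nFps1, params$Pt0)
  } else {
    fps1_unf(params$kFps1, params$keFps1, nFps1 = 1, Pt0 = params$Pt0)
  }
  hog <- switch(scheme$hog_kind,
    UNF = hog_unf(params$kHOG, params$keHOG, params$nHOG),
    PNF = hog_unf(params$kHOG, params$keHOG, nHOG = 1),
    INF = hog_integral(scheme$ki, Tm = Inf),
    FINF = hog_integral(scheme$ki, Tm = scheme$Tm)
  )
  list(fps1 = fps1, hog = hog,
       activation = hog_activation(params$bHOG, params$aHOG))
}

#' Step osmoshock input
#'
#' A step increase of the extracellular osmolarity, given as NaCl molarity
#' applied from an onset time. The molarity is converted to osmotic
#' pressure units by the `c_osm` factor of the parameter set at
#' simulation time.
#'
#' @param amplitude_M Shock amplitude in M NaCl (>= 0).
#' @param t_on Onset time, minutes.
#' @param label Optional identifier; defaults to e.g. `"0.4M"`.
#' @return A list of class `shock_input`.
#' @examples
#' shock_input(0.4)
#' @export
shock_input <- function(amplitude_M, t_on = 5, label = NULL) {
  stopifnot(amplitude_M >= 0, is.finite(t_on), t_on >= 0)
  structure(list(
    amplitude_M = amplitude_M, t_on = t_on,
    label = label %||% paste0(format(amplitude_M), "M")
  ), class = "shock_input")
}
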