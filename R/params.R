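#' Parameter set for the osmoregulation model
#'
#' Builds the full constant set of the osmoshock model: the biophysical
#' constants of the pressure/volume module, the Hog1 activation constants,
#' and the Hill-law constants of the two ultrasensitive controller branches
#' (Fps1 channel and Hog1-mediated glycerol production). The model has 20
#' constants in total; 16 are free and 4 are dependent — the
#' `(betaFps1, KFps1)` and `(betaHOG, KHOG)` pairs, which are recomputed
#' from the shape constants and Hill exponents every time a parameter set
#' is built or updated:
#' \deqn{\beta = 1 - e^{k_e (1 - n)}, \qquad
#'       K_{Fps1} = P_t(0)\, e^{k_{e_{Fps1}} (1 - n_{Fps1})}, \qquad
#'       K_{HOG} = e^{k_{e_{HOG}} (1 - n_{HOG})}.}
#'
#' Volumes are dimensionless fractions of the initial volume (`V0 = 1`);
#' pressures are in osmolarity-equivalent units (van't Hoff with RT
#' absorbed); time is in minutes. The NaCl-molarity-to-pressure conversion
#' factor `c_osm` (default 2 osmotic units per M, full dissociation) is a
#' units convention carried alongside the parameter set, not a model
#' constant.
#'
#' @param ... Named parameter overrides, e.g. `osmo_params(kFps1 = 0.8)`.
#'   Free parameters only; the dependent `beta`/`K` values are always
#'   recomputed and cannot be set directly.
#' @param base An existing `osmo_params` object to start from (defaults to
#'   the package defaults).
#'
#' @return A named list of class `osmo_params` holding the 16 free
#'   constants, the 4 dependent constants and `c_osm`.
#'
#' @details Default values are package choices producing physiological
#'   dip-and-recover volume dynamics on 0.2–0.6 M NaCl step shocks; see the
#'   methods vignette for the rationale behind each value.
#'
#' @examples
#' p <- osmo_params(nFps1 = 1, nHOG = 1)
#' p$betaFps1   # exactly 0 at Hill exponent 1
#' p$KFps1      # equals Pt0 at Hill exponent 1
#' @export
osmo_params <- function(..., base = NULL) {
  defaults <- list(
    kp1 = 0.2, s = 0.4, Vb = 0.368, V0 = 1, Pt0 = 0.5,
    Pe_equil = 0.24, VPt0 = 0.9, Ve = 10,
    bHOG = 0.5, aHOG = 0.5,
    kFps1 = 0.5, keFps1 = 6, nFps1 = 2,
    kHOG = 0.2, keHOG = 6, nHOG = 2,
    c_osm = 2
  )
  p <- if (is.null(base)) defaults else unclass(base)[names(defaults)]
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(!nzchar(names(dots)))) {
      stop("parameter overrides must be named", call. = FALSE)
    }
    bad <- setdiff(names(dots), names(defaults))
    if (length(bad)) {
      stop("unknown or non-settable parameter(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    p[names(dots)] <- dots
  }
  p <- lapply(p, as.numeric)
  p$betaFps1 <- 1 - exp(p$keFps1 * (1 - p$nFps1))
  p$KFps1 <- p$Pt0 * exp(p$keFps1 * (1 - p$nFps1))
  p$betaHOG <- 1 - exp(p$keHOG * (1 - p$nHOG))
  p$KHOG <- exp(p$keHOG * (1 - p$nHOG))
  validate_params(structure(p, class = "osmo_params"))
}

#' @export
print.osmo_params <- function(x, ...) {
  cat("<osmo_params> 20 model constants (16 free, 4 dependent)\n")
  print(param_registry(x), n = 20)
  invisible(x)
}

.free_param_names <- c(
  "kp1", "s", "Vb", "V0", "Pt0", "Pe_equil", "VPt0", "Ve",
  "bHOG", "aHOG", "kFps1", "keFps1", "nFps1", "kHOG", "keHOG", "nHOG"
)
.dependent_param_names <- c("betaFps1", "KFps1", "betaHOG", "KHOG")

#' Enumerate the model constants
#'
#' Tabulates the full parameter registry of the osmoregulation model: the
#' 16 free constants and the 4 dependent Hill-law constants (the
#' `beta`/`K` pairs of the two ultrasensitive branches).
#'
#' @param params An `osmo_params` object (defaults to package defaults).
#' @return A tibble with columns `name`, `value`, `role`
#'   (`"free"`/`"dependent"`) and `description`, one row per model
#'   constant (20 rows).
#' @examples
#' param_registry()
#' dplyr::count(param_registry(), role)
#' @export
param_registry <- function(params = osmo_params()) {
  params <- validate_params(params)
  desc <- c(
    kp1 = "hydraulic water permeability (volume pressure^-1 min^-1)",
    s = "non-glycerol osmolyte amount (pressure * volume)",
    Vb = "non-osmotic volume",
    V0 = "initial (normalized) volume",
    Pt0 = "initial turgor pressure",
    Pe_equil = "extracellular osmotic pressure at equilibrium",
    VPt0 = "volume at which turgor pressure is zero",
    Ve = "extracellular volume",
    bHOG = "error-to-Hog1-activation gain (min^-1)",
    aHOG = "Hog1 activation decay rate (min^-1)",
    kFps1 = "maximal Fps1 glycerol permeability",
    keFps1 = "Fps1 branch shape constant",
    nFps1 = "Fps1 branch Hill exponent",
    kHOG = "Hog1 branch gain",
    keHOG = "Hog1 branch shape constant",
    nHOG = "Hog1 branch Hill exponent",
    betaFps1 = "dependent: 1 - exp(keFps1 (1 - nFps1))",
    KFps1 = "dependent: Pt0 exp(keFps1 (1 - nFps1))",
    betaHOG = "dependent: 1 - exp(keHOG (1 - nHOG))",
    KHOG = "dependent: exp(keHOG (1 - nHOG))"
  )
  nm <- c(.free_param_names, .dependent_param_names)
  tibble::tibble(
    name = nm,
    value = vapply(nm, function(n) params[[n]], numeric(1)),
    role = rep(c("free", "dependent"),
               c(length(.free_param_names), length(.dependent_param_names))),
    description = unname(desc[nm])
  )
}

#' @rdname param_registry
#' @param x An `osmo_params` object.
#' @param ... Unused.
#' @export
tidy.osmo_params <- function(x, ...) param_registry(x)

#' Volumetric elastic modulus
#'
#' The elastic modulus of the linear turgor law, derived from the turgor
#' zero-crossing volume: `eps = Pt0 * V0 / (V0 - VPt0)`. It is a derived
#' quantity (the registry optimizes `VPt0` instead) linking the two
#' equivalent forms of the turgor-volume relation.
#'
#' @param params An `osmo_params` object.
#' @return The elastic modulus (pressure units).
#' @export
elastic_modulus <- function(params = osmo_params()) {
  params <- validate_params(params)
  params$Pt0 * params$V0 / (params$V0 - params$VPt0)
}

#' Validate a parameter set
#'
#' Checks the structural invariants of the model constants:
#' `Vb < VPt0 < V0`, `Pt0 >= 0`, positive permeabilities, gains and rates,
#' Hill exponents `>= 1`, and consistency of the dependent `beta`/`K`
#' pairs. Warns (without failing) when `bHOG` and `aHOG` are strongly
#' dissimilar, since the Hog1 activation stage is meant to be a roughly
#' unit-gain linear filter of the error.
#'
#' @param params An `osmo_params` object (or plain named list).
#' @param ratio_band Acceptable band for `bHOG / aHOG` before a warning is
#'   raised.
#' @return The validated `osmo_params` object, invisibly usable in place.
#' @export
validate_params <- function(params, ratio_band = c(0.2, 5)) {
  if (!inherits(params, "osmo_params")) {
    params <- do.call(osmo_params, params[.free_param_names])
  }
  stopifnot_params <- function(ok, msg) {
    if (!isTRUE(ok)) stop("invalid parameters: ", msg, call. = FALSE)
  }
  p <- params
  stopifnot_params(all(vapply(p, is.finite, logical(1))),
                   "all constants must be finite")
  stopifnot_params(p$Vb < p$VPt0, "Vb < VPt0 required")
  stopifnot_params(p$VPt0 < p$V0, "VPt0 < V0 required")
  stopifnot_params(p$Pt0 >= 0, "Pt0 >= 0 required")
  stopifnot_params(p$kp1 > 0, "kp1 > 0 required")
  stopifnot_params(p$Ve > 0, "Ve > 0 required")
  stopifnot_params(p$s >= 0, "s >= 0 required")
  stopifnot_params(p$kFps1 > 0, "kFps1 > 0 required")
  stopifnot_params(p$kHOG > 0, "kHOG > 0 required")
  stopifnot_params(p$nFps1 >= 1, "nFps1 >= 1 required")
  stopifnot_params(p$nHOG >= 1, "nHOG >= 1 required")
  stopifnot_params(p$bHOG > 0 && p$aHOG > 0, "bHOG, aHOG > 0 required")
  stopifnot_params(p$c_osm > 0, "c_osm > 0 required")
  ratio <- p$bHOG / p$aHOG
  if (ratio < ratio_band[1] || ratio > ratio_band[2]) {
    warning("bHOG/aHOG = ", signif(ratio, 3),
            " is outside the similar-values band [",
            ratio_band[1], ", ", ratio_band[2],
            "]; the Hog1 activation stage is intended as a near-unit-gain ",
            "filter of the error", call. = FALSE)
  }
  params
}

#' Read or write a parameter configuration file
#'
#' Parameter sets are serialized as YAML with keys named exactly as the
#' model symbols (`kp1`, `s`, `Vb`, `V0`, `Pt0`, `Pe_equil`, `VPt0`, `Ve`,
#' `c_osm`, ...). Only free parameters are written; dependent constants
#' are recomputed on read.
#'
#' @param params An `osmo_params` object.
#' @param path File path.
#' @return `read_osmo_config` returns an `osmo_params` object;
#'   `write_osmo_config` returns `path` invisibly.
#' @export
write_osmo_config <- function(params, path) {
  params <- validate_params(params)
  keep <- c(.free_param_names, "c_osm")
  yaml::write_yaml(unclass(params)[keep], path)
  invisible(path)
}

#' @rdname write_osmo_config
#' @export
read_osmo_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- c(.free_param_names, "c_osm")
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown key(s) in config: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  validate_params(do.call(osmo_params, vals))
}
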