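#' Clip recovered volume samples at 1
#'
#' The model carries no growth mechanism, so observed volume above the
#' initial (normalized) value carries no information for it: volume
#' samples exceeding 1 are set to exactly 1 before fitting. Hog1 samples
#' are never modified.
#'
#' @param data A dataset tibble with at least a `volume` column.
#' @return The tibble with `volume` clipped at 1.
#' @examples
#' clip_volume(tibble::tibble(volume = c(1, 0.8, 1.03), hog1 = 0))
#' @export
clip_volume <- function(data) {
  stopifnot("volume" %in% names(data))
  dplyr::mutate(data, volume = pmin(.data$volume, 1))
}

# Resolve a named free-parameter vector into an updated (params, scheme)
# pair; "ki" and "Tm" live on the scheme, everything else on params.
.apply_free <- function(par, params, scheme) {
  nm <- names(par)
  sch_nm <- intersect(nm, c("ki", "Tm"))
  par_nm <- setdiff(nm, sch_nm)
  bad <- setdiff(par_nm, .free_param_names)
  if (length(bad)) {
    stop("unknown free parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (length(par_nm)) {
    params <- do.call(osmo_params,
                      c(as.list(par[par_nm]), list(base = params)))
  }
  if (length(sch_nm)) {
    scheme <- scheme_config(scheme$name,
                            ki = if ("ki" %in% sch_nm) par[["ki"]] else scheme$ki,
                            Tm = if ("Tm" %in% sch_nm) par[["Tm"]] else scheme$Tm)
  }
  list(params = params, scheme = scheme)
}

#' Least-squares cost of a scheme against osmoshock datasets
#'
#' The fitting objective: for every shock experiment `j` and sampling
#' time `i`, the squared volume residual plus the squared Hog1 residual,
#' \deqn{J = \sum_j \sum_i \left(V_j(t_i) - \hat V_j(t_i, p)\right)^2 +
#'       \left(u_{HOG_j}(t_i) - \hat u_{HOG_j}(t_i, p)\right)^2,}
#' with model curves sampled exactly at the dataset times. Residuals are
#' unweighted (volume and Hog1 are in comparable normalized units) and
#' the model Hog1 output enters as the activation state directly. A
#' failed simulation yields `Inf` (optimizer-safe) with a warning.
#'
#' @param data Dataset tibble (`shock_id`, `time`, `volume`, `hog1`);
#'   `shock_id` is the NaCl molarity of each step shock.
#' @param scheme A [scheme_config()].
#' @param params An [osmo_params()] set.
#' @param t_on Shock onset time shared by all shocks, minutes.
#' @return The scalar cost `J >= 0`.
#' @examples
#' sch <- scheme_config("UNF-UNF")
#' d <- generate_shock_data(sch, sigma_v = 0, sigma_h = 0, seed = 1)
#' osmo_cost(d, sch, osmo_params())  # ~0: data generated by this model
#' @export
osmo_cost <- function(data, scheme, params = osmo_params(), t_on = 5) {
  stopifnot(inherits(scheme, "scheme_config"),
            all(c("shock_id", "time", "volume", "hog1") %in% names(data)))
  params <- validate_params(params)
  total <- 0
  for (sid in unique(data$shock_id)) {
    d <- data[data$shock_id == sid, ]
    d <- d[order(d$time), ]
    traj <- tryCatch(
      .sample_trajectory(scheme, shock_input(sid, t_on = t_on), params,
                         d$time),
      error = function(e) {
        warning("simulation failed for shock ", sid, " (",
                conditionMessage(e), "); cost set to Inf", call. = FALSE)
        NULL
      }
    )
    if (is.null(traj)) return(Inf)
    total <- total + sum((d$volume - traj$V)^2 + (d$hog1 - traj$uHOG)^2)
  }
  total
}

#' Information criteria for a least-squares fit
#'
#' Gaussian least-squares forms of the Akaike information criterion, the
#' Bayesian information criterion and Akaike's final prediction-error
#' criterion:
#' \deqn{AIC = N \ln(J/N) + 2 p, \quad
#'       BIC = N \ln(J/N) + p \ln N, \quad
#'       FPE = \frac{J}{N}\,\frac{N + p}{N - p},}
#' with `J` the residual sum, `N` the total number of data points
#' (volume and Hog1 samples jointly) and `p` the number of free
#' parameters. Lower is better for all three.
#'
#' @param J Residual sum of squares (> 0).
#' @param N Total data-point count (> `p_free`).
#' @param p_free Number of free parameters.
#' @return A tibble with columns `AIC`, `BIC`, `FPE`.
#' @examples
#' info_criteria(J = 7.389056, N = 7.389056, p_free = 0)  # AIC = BIC = 0
#' @export
info_criteria <- function(J, N, p_free) {
  if (N <= p_free) stop("N must exceed the free-parameter count",
                        call. = FALSE)
  if (J <= 0) stop("J must be positive for the log-likelihood forms",
                   call. = FALSE)
  tibble::tibble(
    AIC = N * log(J / N) + 2 * p_free,
    BIC = N * log(J / N) + p_free * log(N),
    FPE = (J / N) * (N + p_free) / (N - p_free)
  )
}

#' Default fitting bounds
#'
#' Box constraints used by [fit_scheme()] when none are supplied:
#' controller constants plus the two optimized biophysical parameters
#' (the turgor-loss volume `VPt0` and the water permeability `kp1`).
#' Hill exponents are real-valued with range `[1, 8]`.
#'
#' @return A tibble with columns `name`, `lower`, `upper`.
#' @export
default_fit_bounds <- function() {
  tibble::tribble(
    ~name,     ~lower, ~upper,
    "kFps1",    0.05,   2,
    "keFps1",   0.5,    12,
    "nFps1",    1,      8,
    "kHOG",     0.01,   1,
    "keHOG",    0.5,    12,
    "nHOG",     1,      8,
    "bHOG",     0.05,   5,
    "aHOG",     0.05,   5,
    "VPt0",     0.75,   0.98,
    "kp1",      0.02,   2,
    "ki",       0.001,  0.5,
    "Tm",       1,      30
  )
}

#' Fit a controller scheme to osmoshock data
#'
#' Hybrid global/local estimation of the free parameters of a scheme
#' against volume and Hog1 step-shock datasets, minimizing [osmo_cost()]:
#' an evolutionary global search ([ga_optimize()]) followed by a bounded
#' derivative-free simplex refinement, repeated `n_restart` times
#' (default 5) with distinct derived seeds; the best-cost restart wins
#' and every restart's scores are recorded. Deterministic given `seed`.
#'
#' @param data Dataset tibble (`shock_id`, `time`, `volume`, `hog1`).
#' @param scheme A [scheme_config()] naming the scheme to fit.
#' @param params Baseline [osmo_params()]; free parameters start from the
#'   GA search, everything else stays fixed at these values.
#' @param free Character vector of free parameter names (model constants
#'   plus optionally `"ki"`/`"Tm"` for integral Hog branches).
#' @param bounds Data frame `name`/`lower`/`upper` covering every free
#'   parameter; defaults to [default_fit_bounds()].
#' @param n_restart Number of hybrid restarts.
#' @param seed Master seed; restart seeds are derived from it.
#' @param ga_control List overriding [ga_optimize()] settings
#'   (`pop_size`, `generations`, ...).
#' @param local_maxit Iteration cap of the simplex refinement.
#' @param t_on Shock onset time, minutes.
#' @return An object of class `osmo_fit`: fitted parameters, cost `J`,
#'   information criteria, per-restart scores and everything needed to
#'   reproduce the fit. Use [tidy()] / [glance()] / `autoplot()` on it.
#' @examples
#' \donttest{
#' sch <- scheme_config("UNF-UNF")
#' d <- generate_shock_data(sch, sigma_v = 0, sigma_h = 0, seed = 1)
#' fit <- fit_scheme(d, sch, free = c("kHOG", "nHOG"), n_restart = 1,
#'                   seed = 1, ga_control = list(pop_size = 16,
#'                                               generations = 10))
#' glance(fit)
#' }
#' @export
fit_scheme <- function(data, scheme, params = osmo_params(),
                       free = c("kFps1", "nFps1", "kHOG", "nHOG"),
                       bounds = default_fit_bounds(),
                       n_restart = 5, seed = 1,
                       ga_control = list(), local_maxit = 200, t_on = 5) {
  stopifnot(inherits(scheme, "scheme_config"), n_restart >= 1,
            length(free) >= 1)
  params <- validate_params(params)
  data <- dplyr::arrange(tibble::as_tibble(data), .data$shock_id,
                         .data$time)
  miss <- setdiff(free, bounds$name)
  if (length(miss)) {
    stop("no bounds supplied for free parameter(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  b <- bounds[match(free, bounds$name), ]
  lower <- b$lower
  upper <- b$upper

  objective <- function(x) {
    names(x) <- free
    upd <- tryCatch(suppressWarnings(.apply_free(x, params, scheme)),
                    error = function(e) NULL)
    if (is.null(upd)) return(Inf)
    suppressWarnings(osmo_cost(data, upd$scheme, upd$params, t_on = t_on))
  }

  ga_args <- utils::modifyList(
    list(pop_size = 40, generations = 60), ga_control
  )
  restarts <- vector("list", n_restart)
  for (r in seq_len(n_restart)) {
    seed_r <- (as.numeric(seed) * 1009 + r * 7919) %% 2147483647
    set.seed(seed_r)
    ga <- do.call(ga_optimize,
                  c(list(fn = objective, lower = lower, upper = upper),
                    ga_args))
    loc <- .local_refine(objective, ga$par, lower, upper,
                         maxit = local_maxit)
    best <- if (loc$value <= ga$value) loc else ga
    restarts[[r]] <- tibble::tibble(
      restart = r, seed = seed_r, J_ga = ga$value, J = best$value,
      par = list(stats::setNames(best$par, free))
    )
  }
  restarts <- dplyr::bind_rows(restarts)
  if (all(!is.finite(restarts$J))) {
    stop("all restarts failed to produce a finite cost", call. = FALSE)
  }
  winner <- which.min(restarts$J)
  par <- restarts$par[[winner]]
  upd <- suppressWarnings(.apply_free(par, params, scheme))

  N <- 2L * nrow(data)  # volume and Hog1 samples jointly
  J <- restarts$J[winner]
  ic <- if (J > 0) info_criteria(J, N, length(free)) else {
    tibble::tibble(AIC = -Inf, BIC = -Inf, FPE = 0)
  }
  structure(list(
    scheme = upd$scheme, params = upd$params, par = par, free = free,
    lower = stats::setNames(lower, free),
    upper = stats::setNames(upper, free),
    J = J, N = N, n_free = length(free),
    AIC = ic$AIC, BIC = ic$BIC, FPE = ic$FPE,
    restarts = restarts[c("restart", "seed", "J_ga", "J")],
    seed = seed, t_on = t_on, data = data,
    fingerprint = .data_fingerprint(data)
  ), class = "osmo_fit")
}

.data_fingerprint <- function(data) {
  list(n = nrow(data), shocks = sort(unique(data$shock_id)),
       checksum = signif(sum(data$time) + sum(data$volume) +
                           sum(data$hog1), 12))
}

#' @export
print.osmo_fit <- function(x, ...) {
  cat("<osmo_fit> scheme ", x$scheme$name, "\n", sep = "")
  cat("  J = ", format(x$J), "  (N = ", x$N, ", ", x$n_free,
      " free parameters, ", nrow(x$restarts), " restarts)\n", sep = "")
  cat("  AIC = ", format(x$AIC), "  BIC = ", format(x$BIC),
      "  FPE = ", format(x$FPE), "\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' Tidy and glance methods for fitted schemes
#'
#' `tidy()` returns one row per fitted parameter with its bounds;
#' `glance()` returns the one-row fit summary (cost and information
#' criteria).
#'
#' @param x An `osmo_fit` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.osmo_fit <- function(x, ...) {
  tibble::tibble(term = x$free, estimate = unname(x$par[x$free]),
                 lower = unname(x$lower[x$free]),
                 upper = unname(x$upper[x$free]))
}

#' @rdname tidy.osmo_fit
#' @export
glance.osmo_fit <- function(x, ...) {
  tibble::tibble(scheme = x$scheme$name, J = x$J, n_free = x$n_free,
                 N = x$N, AIC = x$AIC, BIC = x$BIC, FPE = x$FPE,
                 n_restart = nrow(x$restarts))
}

#' Rank fitted schemes by cost and information criteria
#'
#' Collects fits of different schemes to the same datasets into a
#' ranking table sorted by each score. Ties are broken by the smaller
#' free-parameter count, then by scheme name.
#'
#' @param fits A list of `osmo_fit` objects (>= 1) fitted to identical
#'   data.
#' @return A tibble with one row per scheme, the four scores, and rank
#'   columns `rank_J`, `rank_AIC`, `rank_BIC`, `rank_FPE`, sorted by
#'   `J`. Attributes `winners` (named character of per-score winners)
#'   and `winners_agree` summarize the comparison.
#' @examples
#' \donttest{
#' # fits fitted to one dataset, then:
#' # rank_schemes(list(fit_unf, fit_pnf))
#' }
#' @export
rank_schemes <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 1,
            all(vapply(fits, inherits, logical(1), "osmo_fit")))
  fps <- lapply(fits, `[[`, "fingerprint")
  if (length(fits) > 1) {
    same <- vapply(fps[-1], function(f) isTRUE(all.equal(f, fps[[1]])),
                   logical(1))
    if (!all(same)) {
      stop("fits were not computed on identical datasets", call. = FALSE)
    }
  }
  tab <- dplyr::bind_rows(lapply(fits, glance))
  rank_by <- function(score) {
    ord <- order(score, tab$n_free, tab$scheme)
    rank <- integer(length(ord)); rank[ord] <- seq_along(ord)
    rank
  }
  tab$rank_J <- rank_by(tab$J)
  tab$rank_AIC <- rank_by(tab$AIC)
  tab$rank_BIC <- rank_by(tab$BIC)
  tab$rank_FPE <- rank_by(tab$FPE)
  tab <- dplyr::arrange(tab, .data$rank_J)
  winners <- c(J = tab$scheme[tab$rank_J == 1],
               AIC = tab$scheme[tab$rank_AIC == 1],
               BIC = tab$scheme[tab$rank_BIC == 1],
               FPE = tab$scheme[tab$rank_FPE == 1])
  attr(tab, "winners") <- winners
  attr(tab, "winners_agree") <- length(unique(winners)) == 1
  tab
}
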