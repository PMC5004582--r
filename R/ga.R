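#' Genetic algorithm for box-constrained minimization
#'
#' A real-coded genetic algorithm: tournament selection, blend (BLX-alpha)
#' crossover, Gaussian mutation scaled to the box, and elitism. Used as
#' the global stage of the hybrid fitting procedure; exposed for reuse
#' and testing.
#'
#' @param fn Objective to minimize; takes a numeric vector, returns a
#'   scalar (non-finite values are treated as very poor fitness).
#' @param lower,upper Box constraints (equal-length numeric vectors).
#' @param pop_size Population size.
#' @param generations Number of generations.
#' @param p_cross,p_mut Crossover and per-gene mutation probabilities.
#' @param blend_alpha BLX-alpha expansion factor.
#' @param tournament Tournament size.
#' @param elite Number of elites copied unchanged each generation.
#' @param mut_sd Mutation standard deviation as a fraction of the box
#'   width.
#' @return A list with `par`, `value`, and `trace` (best objective per
#'   generation).
#' @export
ga_optimize <- function(fn, lower, upper, pop_size = 40, generations = 60,
                        p_cross = 0.8, p_mut = 0.15, blend_alpha = 0.5,
                        tournament = 3, elite = 2, mut_sd = 0.1) {
  stopifnot(length(lower) == length(upper), all(upper > lower),
            pop_size >= 4, generations >= 1)
  d <- length(lower)
  width <- upper - lower
  clampv <- function(x) pmin(pmax(x, lower), upper)
  evaluate <- function(x) {
    v <- tryCatch(fn(x), error = function(e) Inf)
    if (!is.finite(v)) Inf else v
  }

  pop <- matrix(stats::runif(pop_size * d), pop_size, d)
  pop <- sweep(sweep(pop, 2, width, "*"), 2, lower, "+")
  fit <- apply(pop, 1, evaluate)
  trace <- numeric(generations)

  for (g in seq_len(generations)) {
    ord <- order(fit)
    newpop <- pop[ord[seq_len(elite)], , drop = FALSE]
    while (nrow(newpop) < pop_size) {
      pick <- function() {
        cand <- sample.int(pop_size, tournament)
        cand[which.min(fit[cand])]
      }
      p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
      if (stats::runif(1) < p_cross) {
        cmin <- pmin(p1, p2); cmax <- pmax(p1, p2)
        ext <- blend_alpha * (cmax - cmin)
        child <- stats::runif(d, cmin - ext, cmax + ext)
      } else {
        child <- p1
      }
      mut <- stats::runif(d) < p_mut
      child[mut] <- child[mut] + stats::rnorm(sum(mut), 0,
                                              mut_sd * width[mut])
      newpop <- rbind(newpop, clampv(child))
    }
    keep <- seq_len(min(elite, pop_size))
    elite_fit <- fit[ord[keep]]
    pop <- newpop[seq_len(pop_size), , drop = FALSE]
    fit <- c(elite_fit, apply(pop[-keep, , drop = FALSE], 1, evaluate))
    trace[g] <- min(fit)
  }
  best <- which.min(fit)
  list(par = pop[best, ], value = fit[best], trace = trace)
}

# Bounded local refinement: Nelder-Mead simplex on a sigmoid
# reparameterization of the box, so every trial point respects the
# bounds without penalty terms.
.local_refine <- function(fn, par, lower, upper, maxit = 200) {
  width <- upper - lower
  eps <- 1e-6
  frac <- pmin(pmax((par - lower) / width, eps), 1 - eps)
  x0 <- stats::qlogis(frac)
  to_par <- function(x) lower + width * stats::plogis(x)
  obj <- function(x) {
    v <- tryCatch(fn(to_par(x)), error = function(e) Inf)
    if (!is.finite(v)) 1e12 else v
  }
  if (length(par) == 1) {
    # golden-section/parabolic search in a window around the GA solution
    res <- stats::optimize(obj, c(x0 - 3, x0 + 3), tol = 1e-10)
    return(list(par = to_par(res$minimum), value = res$objective))
  }
  res <- stats::optim(x0, obj, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-10))
  list(par = to_par(res$par), value = res$value)
}
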