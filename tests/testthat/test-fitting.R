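test_that("volume clipping caps recovered samples at 1 and touches nothing else", {
  d <- tibble::tibble(shock_id = 0.2, time = 0:3,
                      volume = c(1.0, 0.8, 0.95, 1.03),
                      hog1 = c(0, 1.5, 0.3, 1.02))
  out <- clip_volume(d)
  expect_equal(out$volume, c(1.0, 0.8, 0.95, 1.0))
  expect_identical(out$hog1, d$hog1)
  expect_identical(clip_volume(d[2:3, ])$volume, d$volume[2:3])
})

test_that("cost is the summed squared residuals and is order-invariant", {
  sch <- scheme_config("UNF-UNF")
  p <- osmo_params()
  # single point: residuals 0.1 (volume) and 0.2 (hog1) give 0.05
  base <- generate_shock_data(sch, p, shocks = 0.4, times = c(0, 10),
                              sigma_v = 0, sigma_h = 0)
  pert <- base
  pert$volume[2] <- pert$volume[2] + 0.1
  pert$hog1[2] <- pert$hog1[2] - 0.2
  expect_equal(osmo_cost(pert, sch, p), 0.05, tolerance = 1e-8)

  d <- generate_shock_data(sch, p, seed = 4)
  expect_equal(osmo_cost(d[sample(nrow(d)), ], sch, p),
               osmo_cost(d, sch, p))
  # data from the generating scheme score better under it than under PNF-PNF
  d0 <- generate_shock_data(sch, p, sigma_v = 0, sigma_h = 0)
  expect_lt(osmo_cost(d0, sch, p), osmo_cost(d0, scheme_config("PNF-PNF"), p))
})

test_that("information criteria follow the Gaussian least-squares forms", {
  ic <- info_criteria(J = 10, N = 10, p_free = 0)
  expect_equal(ic$AIC, 0)
  expect_equal(ic$BIC, 0)
  expect_equal(ic$FPE, 1)
  # penalties grow with the parameter count at equal J
  ic2 <- info_criteria(10, 10, 2)
  ic4 <- info_criteria(10, 10, 4)
  expect_true(ic4$AIC > ic2$AIC && ic4$BIC > ic2$BIC && ic4$FPE > ic2$FPE)
  # BIC outweighs AIC per parameter exactly when ln N > 2
  N <- 60
  expect_gt(info_criteria(5, N, 3)$BIC, info_criteria(5, N, 3)$AIC)
  expect_lt(info_criteria(5, 7, 3)$BIC, info_criteria(5, 7, 3)$AIC)
  expect_error(info_criteria(5, 3, 4), "exceed")
  expect_error(info_criteria(0, 10, 2), "positive")
})

test_that("GA minimizes a multimodal box-constrained function", {
  set.seed(1)
  # Rastrigin-like surface with global minimum at (1, -1)
  fn <- function(x) sum((x - c(1, -1))^2) +
    0.3 * sum(1 - cos(6 * (x - c(1, -1))))
  res <- ga_optimize(fn, lower = c(-5, -5), upper = c(5, 5),
                     pop_size = 30, generations = 40)
  expect_lt(fn(res$par), 0.1)
  expect_true(all(diff(res$trace) <= 1e-12))   # elitism: monotone best
})

test_that("hybrid fitting is seed-deterministic and refinement only improves", {
  sch <- scheme_config("UNF-UNF")
  d <- generate_shock_data(sch, sigma_v = 0, sigma_h = 0, shocks = 0.4,
                           times = seq(0, 40, 4))
  ctl <- list(pop_size = 12, generations = 8)
  f1 <- fit_scheme(d, sch, free = c("kHOG", "nHOG"), n_restart = 2,
                   seed = 3, ga_control = ctl, local_maxit = 60)
  f2 <- fit_scheme(d, sch, free = c("kHOG", "nHOG"), n_restart = 2,
                   seed = 3, ga_control = ctl, local_maxit = 60)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$restarts, f2$restarts)
  expect_true(all(f1$restarts$J <= f1$restarts$J_ga + 1e-12))
  expect_equal(f1$J, min(f1$restarts$J))
  expect_equal(nrow(f1$restarts), 2L)
  expect_s3_class(tidy(f1), "tbl_df")
  expect_identical(glance(f1)$scheme, "UNF-UNF")
})

test_that("two free Hog constants are recovered from noiseless data", {
  sch <- scheme_config("UNF-UNF")
  d <- generate_shock_data(sch, sigma_v = 0, sigma_h = 0)
  fit <- fit_scheme(d, sch, free = c("kHOG", "nHOG"), n_restart = 2,
                    seed = 2, ga_control = list(pop_size = 20,
                                                generations = 15))
  truth <- c(kHOG = 0.2, nHOG = 2)
  expect_lt(max(abs(fit$par - truth) / truth), 0.05)
})

test_that("integral gain fitted to low shocks exceeds the gain fitted to high shocks", {
  # data come from the ultrasensitive scheme; a proportional+integral
  # scheme must trade speed against overshoot across shock levels
  truth <- scheme_config("UNF-UNF")
  lo <- generate_shock_data(truth, shocks = 0.2, sigma_v = 0, sigma_h = 0)
  hi <- generate_shock_data(truth, shocks = 0.6, sigma_v = 0, sigma_h = 0)
  sch <- scheme_config("PNF-INF")
  b <- default_fit_bounds()
  b$upper[b$name == "ki"] <- 5    # let the gain run free of its cap
  free <- c("ki", "kFps1", "kp1", "VPt0")
  ctl <- list(pop_size = 24, generations = 25)
  f_lo <- fit_scheme(lo, sch, free = free, bounds = b, n_restart = 2,
                     seed = 5, ga_control = ctl)
  f_hi <- fit_scheme(hi, sch, free = free, bounds = b, n_restart = 2,
                     seed = 5, ga_control = ctl)
  expect_gt(f_lo$par[["ki"]], f_hi$par[["ki"]])
})

test_that("ranking sorts by every score with documented tie-breaks", {
  sch <- scheme_config("UNF-UNF")
  d <- generate_shock_data(sch, sigma_v = 0.01, sigma_h = 0.01, seed = 7)
  ctl <- list(pop_size = 12, generations = 8)
  f1 <- fit_scheme(d, sch, free = c("kHOG", "nHOG"), n_restart = 1,
                   seed = 1, ga_control = ctl, local_maxit = 60)
  f2 <- fit_scheme(d, scheme_config("PNF-PNF"), free = c("kFps1", "kHOG"),
                   n_restart = 1, seed = 1, ga_control = ctl,
                   local_maxit = 60)
  r <- rank_schemes(list(f2, f1))
  expect_identical(r$scheme[1], "UNF-UNF")
  expect_true(attr(r, "winners_agree"))

  expect_identical(rank_schemes(list(f1))$rank_J, 1L)

  other <- generate_shock_data(sch, sigma_v = 0.01, sigma_h = 0.01,
                               seed = 8)
  f3 <- fit_scheme(other, sch, free = c("kHOG", "nHOG"), n_restart = 1,
                   seed = 1, ga_control = ctl, local_maxit = 60)
  expect_error(rank_schemes(list(f1, f3)), "identical datasets")

  # ties: equal scores rank by fewer free parameters, then name
  g1 <- f1; g2 <- f1
  g1$J <- g2$J <- 1; g1$AIC <- g2$AIC <- 1; g1$BIC <- g2$BIC <- 1
  g1$FPE <- g2$FPE <- 1
  g2$scheme <- scheme_config("UNF-INF")
  g2$free <- g2$free[1]; g2$n_free <- 1L
  r2 <- rank_schemes(list(g1, g2))
  expect_identical(r2$scheme[1], "UNF-INF")
})
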