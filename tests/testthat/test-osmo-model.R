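test_that("error signal and glycerol diffusion have the stated signs", {
  p <- default_p
  expect_equal(error_signal(p$Pt0, p$Pt0), 0)
  expect_equal(error_signal(0, p$Pt0), p$Pt0)
  expect_lt(error_signal(p$Pt0 + 0.1, p$Pt0), 0)

  st <- equilibrium_state(p)
  expect_equal(glycerol_diffusion(0.5, st[["Gly"]], st[["Glye"]], 1, p), 0)
  expect_equal(glycerol_diffusion(0, 2, 0.1, 1, p), 0)
  expect_gt(glycerol_diffusion(0.5, st[["Gly"]] + 0.2, st[["Glye"]], 1, p), 0)
  expect_error(glycerol_diffusion(0.5, 1, 1, p$Vb, p), "nonpositive")
})

test_that("model right-hand side conserves total glycerol exactly", {
  p <- default_p
  st <- equilibrium_state(p) + c(-0.05, 0.2, 0.1, 0.05, 0.3, 0)
  for (nm in c("PNF-PNF", "UNF-INF", "UNF-UNF")) {
    rhs <- model_rhs(10, st, scheme_config(nm), shock_input(0.4), p)
    expect_equal(rhs$deriv[["Gly"]] + rhs$deriv[["Glye"]],
                 rhs$outputs[["vHOG"]], info = nm)
  }
})

test_that("compiled and plain-R integrators agree on a short horizon", {
  p <- default_p
  for (nm in c("UNF-UNF", "PNF-INF")) {
    sch <- scheme_config(nm)
    shk <- shock_input(0.4, t_on = 0.5)
    ref <- rk4_reference(sch, shk, p, t_end = 3, h = 0.01)
    got <- simulate_osmo(sch, shk, p, t_end = 3, dt = 0.01,
                         method = "fixed", h = 0.01)
    expect_lt(max(abs(got$V - ref[, "V"])), 1e-12)
    expect_lt(max(abs(got$Gly - ref[, "Gly"])), 1e-12)
    expect_lt(max(abs(got$uHOG - ref[, "uHOG"])), 1e-12)
  }
})

test_that("adaptive and fixed-step solutions converge to each other", {
  sch <- scheme_config("UNF-UNF")
  shk <- shock_input(0.4)
  ad <- simulate_osmo(sch, shk, t_end = 30)
  fx <- simulate_osmo(sch, shk, t_end = 30, method = "fixed", h = 0.01)
  expect_lt(max(abs(ad$V - fx$V)), 1e-6)
  # halving the step barely moves the reported volume
  fx2 <- simulate_osmo(sch, shk, t_end = 30, method = "fixed", h = 0.005)
  expect_lt(max(abs(fx$V - fx2$V)), 1e-4)
})

test_that("finite window equal to the whole horizon reproduces the ideal integrator", {
  shk <- shock_input(0.4)
  fi <- simulate_osmo(scheme_config("PNF-FINF", ki = 0.02, Tm = 1e6),
                      shk, t_end = 40)
  id <- simulate_osmo(scheme_config("PNF-INF", ki = 0.02), shk, t_end = 40)
  expect_lt(max(abs(fi$V - id$V)), 1e-4)
  # a genuinely short memory changes the response
  fi_short <- simulate_osmo(scheme_config("PNF-FINF", ki = 0.02, Tm = 5),
                            shk, t_end = 40)
  expect_gt(max(abs(fi_short$V - id$V)), 1e-3)
})

test_that("zero shock leaves every scheme at equilibrium", {
  for (nm in scheme_names()) {
    tr <- simulate_osmo(scheme_config(nm), shock_input(0), t_end = 30)
    dev <- max(abs(tr$V - tr$V[1]), abs(tr$uHOG), abs(tr$Gly - tr$Gly[1]),
               abs(tr$Glye - tr$Glye[1]))
    expect_lt(dev, 1e-8)
  }
})

test_that("hyperosmotic shock: volume dips then recovers, Fps1 closes then reopens", {
  tr <- simulate_osmo(scheme_config("UNF-UNF"), shock_input(0.4), t_end = 60)
  pre <- tr$time < 5
  expect_true(all(abs(tr$V[pre] - 1) < 1e-8))
  expect_lt(min(tr$V), 0.95)                       # dip
  expect_gt(tr$V[tr$time == 60], 0.97)             # recovery
  expect_lt(tr$uFps1[tr$time == 6], 0.01)          # channel shut post-shock
  # reopens only once the error has fallen below the ultrasensitive threshold
  expect_gt(tr$uFps1[tr$time == 60], 0.1)
  expect_lt(tr$e[tr$time == 60], 0.06)
  # immediately after the shock the volume rate is negative
  expect_lt(tr$V[tr$time == 6] - tr$V[tr$time == 5], 0)

  # proportional-only control leaves a persistent error (no adaptation)
  pr <- simulate_osmo(scheme_config("PNF-PNF"), shock_input(0.4), t_end = 60)
  expect_gt(pr$e[pr$time == 60], 0.2)
  expect_lt(pr$V[pr$time == 60], 0.96)
  expect_gt(tr$V[tr$time == 60], pr$V[pr$time == 60])
})

test_that("total glycerol change equals the integrated production", {
  for (nm in c("UNF-UNF", "PNF-INF", "PNF-FINF")) {
    tr <- simulate_osmo(scheme_config(nm), shock_input(0.6), t_end = 60)
    drift <- tr$Gly + tr$Glye - tr$Gly[1] - tr$Glye[1] - tr$Q
    expect_lt(max(abs(drift)) / max(tr$Q), 1e-6)
  }
})

test_that("noisy simulation: zero noise reproduces the deterministic path, seeds reproduce", {
  sch <- scheme_config("UNF-UNF")
  shk <- shock_input(0.4)
  det <- simulate_osmo(sch, shk, t_end = 20, method = "fixed")
  z <- simulate_noisy(sch, shk, t_end = 20, sigma_fps1 = 0, sigma_hog = 0,
                      n_rep = 1)
  expect_equal(z$V, det$V, tolerance = 1e-12)

  e1 <- simulate_noisy(sch, shk, t_end = 10, sigma_fps1 = 0.01,
                       sigma_hog = 0.01, n_rep = 3, seed = 5)
  e2 <- simulate_noisy(sch, shk, t_end = 10, sigma_fps1 = 0.01,
                       sigma_hog = 0.01, n_rep = 3, seed = 5)
  expect_identical(e1$V, e2$V)
  e3 <- simulate_noisy(sch, shk, t_end = 10, sigma_fps1 = 0.01,
                       sigma_hog = 0.01, n_rep = 3, seed = 6)
  expect_false(identical(e1$V, e3$V))
})

test_that("trajectory CSV roundtrip preserves the standard columns", {
  tr <- simulate_osmo(scheme_config("UNF-UNF"), shock_input(0.2), t_end = 10)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  back <- read_trajectory(path)
  expect_named(back, c("time", "V", "uHOG", "Gly", "Glye", "uFps1", "vHOG",
                       "uDiff", "e", "Pt", "Pi", "Pe"))
  expect_equal(back$V, tr$V, tolerance = 1e-9)
})
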