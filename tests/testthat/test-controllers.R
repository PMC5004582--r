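test_that("Fps1 law: open at zero error, closing with turgor loss", {
  sp <- fps1_unf(kFps1 = 0.5, keFps1 = 6, nFps1 = 2, Pt0 = 0.5)
  expect_equal(fps1_output(0, sp), sp$kFps1)
  # nonincreasing in e and below the baseline for positive error
  e <- seq(0.01, 0.5, length.out = 100)
  out <- fps1_output(e, sp)
  expect_true(all(out < sp$kFps1))
  expect_true(all(diff(out) <= 1e-12))
  expect_true(all(out >= 0))
  # opens beyond baseline for negative error (symmetrical sgn form)
  expect_gt(fps1_output(-0.1, sp), sp$kFps1)
})

test_that("ultrasensitive branches reduce to the proportional forms at n = 1", {
  p <- default_p
  f1 <- fps1_unf(p$kFps1, p$keFps1, nFps1 = 1, Pt0 = p$Pt0)
  expect_identical(f1$betaFps1, 0)
  expect_identical(f1$KFps1, p$Pt0)
  e <- seq(-p$Pt0, p$Pt0, length.out = 401)
  expect_lt(max(abs(fps1_output(e, f1) -
                      p$kFps1 * (p$Pt0 - e) / p$Pt0)), 1e-12)
  h1 <- hog_unf(p$kHOG, p$keHOG, nHOG = 1)
  expect_identical(h1$betaHOG, 0)
  expect_identical(h1$KHOG, 1)
  u <- seq(0.001, 2, length.out = 200)
  expect_lt(max(abs(hog_unf_output(u, h1) - p$kHOG * u)), 1e-12)
})

test_that("Hog1 production switches off for nonpositive activation and saturates", {
  sp <- hog_unf(kHOG = 0.2, keHOG = 6, nHOG = 2)
  expect_equal(hog_unf_output(-0.5, sp), 0)
  expect_equal(hog_unf_output(0, sp), 0)
  expect_equal(hog_unf_output(1e6, sp), sp$kHOG / sp$betaHOG,
               tolerance = 1e-5)
  expect_true(all(diff(hog_unf_output(seq(0, 3, 0.01), sp)) >= 0))
})

test_that("Hog1 activation is a first-order linear filter of the error", {
  sp <- hog_activation(0.5, 0.5)
  # steady state under constant error
  uss <- sp$bHOG * 0.3 / sp$aHOG
  expect_equal(hog_activation_rhs(0.3, uss, sp), 0)
  # pure decay at zero error
  expect_equal(hog_activation_rhs(0, 0.4, sp), -sp$aHOG * 0.4)
  expect_warning(hog_activation(1, 0.1), "similar-values")
  expect_silent(hog_activation(0.6, 0.5))
})

test_that("windowed integral output matches a fine trapezoid oracle", {
  set.seed(11)
  times <- seq(0, 20, by = 0.5)
  hist <- data.frame(time = times,
                     uHOG = pmax(0, 0.3 * sin(times / 3) +
                                   0.05 * rnorm(length(times))))
  sp <- hog_integral(kHOG = 0.05, Tm = 6)
  # oracle: trapezoid at 100x finer step on the linear interpolation
  fine <- seq(20 - sp$Tm, 20, length.out = 100 * 40 + 1)
  vals <- approx(hist$time, hist$uHOG, xout = fine)$y
  oracle <- sp$kHOG * sum(diff(fine) * (head(vals, -1) + tail(vals, -1)) / 2)
  expect_lt(abs(hog_integral_output(hist, sp, t = 20) - oracle), 1e-8)
  # constant integrand over a full window
  ch <- data.frame(time = 0:10, uHOG = 0.3)
  expect_equal(hog_integral_output(ch, hog_integral(0.05, Tm = 4), 10),
               0.05 * 0.3 * 4)
  # ideal integrator accumulates from zero; window truncated early on
  expect_equal(hog_integral_output(ch, hog_integral(0.05, Tm = Inf), 10),
               0.05 * 0.3 * 10)
  expect_equal(hog_integral_output(ch, hog_integral(0.05, Tm = 8), 3),
               0.05 * 0.3 * 3)
  expect_error(hog_integral_output(ch[1:3, ], hog_integral(0.05, 4), 10),
               "cover")
})

test_that("generic controller laws: half-max, sign limit, boundedness, symmetry", {
  unf <- generic_controller("UNF", kp = 1, K = 0.1, n = 2)
  expect_equal(generic_controller_output(0.1, unf), 0.5)
  expect_equal(generic_controller_output(-0.1, unf), -0.5)
  e <- seq(-2, 2, length.out = 801)
  u <- generic_controller_output(e, unf)
  expect_equal(u, -rev(u))                  # odd symmetry
  expect_true(all(abs(u) < unf$kp))         # strictly bounded
  # K -> 0 converges pointwise to the sliding-mode law
  for (e0 in c(-0.5, -0.01, 0.01, 0.5)) {
    small <- generic_controller("UNF", kp = 1, K = 1e-9, n = 2)
    expect_equal(generic_controller_output(e0, small), sign(e0),
                 tolerance = 1e-6)
  }
  smc <- generic_controller("SMC", kp = 0.25)
  expect_equal(generic_controller_output(c(-3, 0, 2), smc),
               c(-0.25, 0, 0.25))
  sat <- generic_controller("SAT", kp = 1, K = 0.01, n = 2)
  expect_equal(sat$m, 50)                   # m = n/(4K)
  expect_equal(generic_controller_output(c(-1, 0.01, 1), sat),
               c(-1, 0.5, 1))
  expect_true(all(abs(generic_controller_output(e, sat)) <= 1))
  expect_error(generic_controller("UNF", kp = 1), "requires constant K")
})

test_that("saturation approximation of the UNF law tightens as K shrinks", {
  # the two maps differ only inside a region of width ~ 4K around zero
  # (both maps rescale with e/K, so the raw sup-norm gap is K-invariant);
  # away from that shrinking region the approximation tightens
  sup_gap <- vapply(c(0.1, 0.05, 0.01), function(K) {
    unf <- generic_controller("UNF", kp = 1, K = K, n = 2)
    sat <- generic_controller("SAT", kp = 1, K = K, n = 2)
    e <- seq(0.05, 1, length.out = 2001)
    e <- c(-rev(e), e)
    max(abs(generic_controller_output(e, unf) -
              generic_controller_output(e, sat)))
  }, numeric(1))
  expect_true(all(diff(sup_gap) < 0))
  # and pointwise at any fixed error off the manifold the gap vanishes
  # once the boundary layer has shrunk past it
  for (e0 in c(-0.3, 0.7)) {
    g <- vapply(c(0.1, 0.01, 0.001), function(K) {
      abs(generic_controller_output(e0,
            generic_controller("UNF", kp = 1, K = K, n = 2)) -
          generic_controller_output(e0,
            generic_controller("SAT", kp = 1, K = K, n = 2)))
    }, numeric(1))
    expect_true(all(diff(g) < 1e-12))
  }
})

test_that("boundary layer is 4K/n with the right monotonicities", {
  expect_equal(boundary_layer(0.01, 2), 0.02)
  expect_true(all(diff(boundary_layer(c(0.001, 0.01, 0.1), 2)) > 0))
  expect_true(all(diff(boundary_layer(0.1, c(1, 2, 4))) < 0))
  expect_error(boundary_layer(0, 2), "positive")
  expect_error(boundary_layer(0.1, 0.5), ">= 1")
})
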