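# Forward Hertz-Sneddon model, contact-point estimation and the joint
# nonlinear fit.

test_that("noiseless forward model matches the closed-form contact law", {
  tip <- tip_model("cone", half_angle = 35, poisson = 0.5)
  st <- afm_settings(spring_constant = 1e6)   # rigid lever: delta = z - z0
  cv <- simulate_force_curve(1000, tip, z0 = 5, settings = st)
  d <- cv$z_extend - 5
  A <- (2 / pi) * (1000 / (1 - 0.5^2)) * tan(35 * pi / 180) * 1e-3
  expect_lt(max(abs(cv$force_extend - ifelse(d > 0, A * d^2, 0))), 1e-8)
  # curve stops at the setpoint
  expect_gte(cv$force_extend[length(cv$force_extend)], cv$setpoint)
})

test_that("pre-contact curve is pure baseline and seeded noise reproduces", {
  tip <- tip_model()
  # setpoint barely above the baseline: nearly the whole ramp is pre-contact
  st <- afm_settings(z_min = 0, z_max = 5, setpoint = 0.125)
  cv <- simulate_force_curve(500, tip, z0 = 4.5, baseline = 0.12, settings = st)
  pre <- cv$z_extend <= 4.5
  expect_gt(sum(pre), 100)
  expect_true(all(cv$force_extend[pre] == 0.12))
  a <- simulate_force_curve(800, tip, z0 = 6, noise_sd = 0.02, seed = 42)
  b <- simulate_force_curve(800, tip, z0 = 6, noise_sd = 0.02, seed = 42)
  expect_identical(a$force_extend, b$force_extend)
  # and the caller's RNG stream is untouched
  set.seed(10); x1 <- rnorm(1)
  set.seed(10); invisible(simulate_force_curve(800, tip, z0 = 6,
                                               noise_sd = 0.02, seed = 1))
  expect_identical(rnorm(1), x1)
})

test_that("unreachable setpoint raises an inconsistent-settings error", {
  st <- afm_settings(z_min = 0, z_max = 6)
  expect_error(simulate_force_curve(10, tip_model(), z0 = 5.9, settings = st),
               "setpoint")
})

test_that("contact point is located within one grid step on a piecewise curve", {
  z <- seq(0, 10, by = 0.05)
  F <- ifelse(z > 5, 0.3 * (z - 5)^2, 0)
  cv <- force_curve(z, F, spring_constant = 0.011, setpoint = 10)
  expect_lt(abs(estimate_contact_point(cv) - 5), 0.05 + 1e-12)
})

test_that("flat curves raise a no-contact error, from the fit too", {
  z <- seq(0, 10, by = 0.05)
  cv <- force_curve(z, rep(0, length(z)), spring_constant = 0.011, setpoint = 1)
  expect_error(estimate_contact_point(cv), "no contact")
  expect_error(fit_hertz(cv), "no contact")
  # constant nonzero baseline is equally contact-free
  cvb <- force_curve(z, rep(0.2, length(z)), spring_constant = 0.011,
                     setpoint = 1)
  expect_error(estimate_contact_point(cvb), "no contact")
})

test_that("contact-point estimate has sub-0.1-um median error on noisy curves", {
  set.seed(7)
  tip <- tip_model()
  err <- replicate(200, {
    z0 <- runif(1, 4, 8)
    cv <- simulate_force_curve(1000, tip, z0 = z0, noise_sd = 0.02)
    abs(estimate_contact_point(cv) - z0)
  })
  expect_lt(median(err), 0.1)
})

test_that("noiseless round-trip recovers E within 0.5% for all geometries", {
  for (geom in c("cone", "pyramid", "sphere")) {
    tip <- if (geom == "sphere") tip_model("sphere", radius = 2.5)
           else tip_model(geom)
    for (E in c(100, 1000, 50000)) {
      cv <- simulate_force_curve(E, tip, z0 = 5)
      ft <- fit_hertz(cv, tip)
      expect_true(ft$converged)
      expect_lt(abs(ft$E - E) / E, 0.005)
      expect_lt(abs(ft$z0 - 5), 0.05)
    }
  }
})

test_that("median fitted E over noisy curves is within 5% of truth", {
  set.seed(1)
  tip <- tip_model()
  Es <- replicate(200, fit_hertz(simulate_force_curve(
    1210, tip, z0 = 6, noise_sd = 0.02), tip)$E)
  expect_lt(abs(median(Es) - 1210) / 1210, 0.05)
})

test_that("fitted E scales with force (and lever) scale, baseline 0", {
  tip <- tip_model()
  cv <- simulate_force_curve(1500, tip, z0 = 5)
  for (c_scale in c(0.5, 3)) {
    # scaling F and k together preserves the indentation geometry exactly
    cv2 <- force_curve(cv$z_extend, cv$force_extend * c_scale,
                       spring_constant = cv$spring_constant * c_scale,
                       setpoint = cv$setpoint * c_scale)
    ft <- fit_hertz(cv2, tip)
    expect_lt(abs(ft$E - c_scale * 1500) / (c_scale * 1500), 1e-4)
  }
})

test_that("fitted E is invariant to translating the z axis", {
  tip <- tip_model()
  cv <- simulate_force_curve(900, tip, z0 = 5)
  ft0 <- fit_hertz(cv, tip)
  cv2 <- force_curve(cv$z_extend + 7.5, cv$force_extend,
                     spring_constant = cv$spring_constant,
                     setpoint = cv$setpoint)
  ft2 <- fit_hertz(cv2, tip)
  expect_lt(abs(ft2$E - ft0$E) / ft0$E, 1e-6)
  expect_lt(abs((ft2$z0 - ft0$z0) - 7.5), 1e-4)
})

test_that("bending correction vanishes for a rigid lever (closed-form oracle)", {
  tip <- tip_model("cone", half_angle = 30)
  st <- afm_settings(spring_constant = 1e6)
  cv <- simulate_force_curve(2000, tip, z0 = 4, noise_sd = 0, settings = st)
  ft <- fit_hertz(cv, tip)
  # uncorrected closed form: linear regression of F on (z - z0)^2
  d <- cv$z_extend - ft$z0
  sel <- d > 0
  slope <- sum(cv$force_extend[sel] * d[sel]^2) / sum(d[sel]^4)
  E_oracle <- slope / ((2 / pi) * tan(30 * pi / 180) / (1 - 0.5^2) * 1e-3)
  expect_lt(abs(ft$E - E_oracle) / E_oracle, 0.001)
})

test_that("hertz_fit methods are coherent", {
  tip <- tip_model()
  cv <- simulate_force_curve(1100, tip, z0 = 6, noise_sd = 0.02, seed = 9)
  ft <- fit_hertz(cv, tip)
  expect_named(coef(ft), c("E", "z0", "baseline"))
  expect_equal(fitted(ft) + residuals(ft), cv$force_extend)
  # predict at the data positions ~ fitted values (self-consistent solve
  # vs measured-force bending differ only through noise)
  expect_lt(max(abs(predict(ft) - fitted(ft))), 0.05)
  sims <- simulate(ft, nsim = 2, seed = 3)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "force_curve")
  s <- summary(ft)
  expect_s3_class(s, "summary.hertz_fit")
  expect_output(print(ft), "Hertz-Sneddon")
})

test_that("force_curve validates its invariants", {
  z <- seq(0, 10, by = 0.5)
  expect_error(force_curve(z, z[-1], 0.01, 1), "equal length")
  expect_error(force_curve(rep(1, 21), rnorm(21), 0.01, 1), "monotonic")
  expect_error(force_curve(z, rnorm(21), 0.01, -1), "setpoint")
  expect_error(force_curve(z, rnorm(21), -0.01, 1), "spring_constant")
  expect_error(tip_model("cone", half_angle = 95), "half_angle")
  expect_error(tip_model(poisson = 0.7), "poisson")
})
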