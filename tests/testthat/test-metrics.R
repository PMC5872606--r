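test_that("unobstructed wall metrics reproduce the Poiseuille closed forms", {
  fit <- cached_fit(0, "newtonian")
  R <- fit$geometry$R
  pois <- poiseuille(R, REF_Q, 0.00345)
  wss <- wall_shear_stress(fit)
  inwin <- wss$x >= -3 * R & wss$x <= 9 * R
  expect_equal(mean(wss$tau[inwin]), pois$tau_w, tolerance = 0.02)
  expect_lt(diff(range(wss$tau[inwin])) / pois$tau_w, 0.02)  # uniform
  wp <- wall_pressure_profile(fit)
  expect_identical(wp$p[nrow(wp)], 0)                         # gauge choice
  slope <- coef(stats::lm(p ~ x, data = wp))[["x"]]
  expect_equal(slope, pois$dpdx, tolerance = 0.02)
  # linear to within 1% of the total drop
  resid <- stats::lm(p ~ x, data = wp)$residuals
  expect_lt(max(abs(resid)) / (wp$p[1] - wp$p[nrow(wp)]), 0.01)
  expect_equal(pressure_drop(fit), -pois$dpdx * 12 * R, tolerance = 0.02)
  vx <- vortex_length(fit)
  expect_identical(vx$vortex_length_over_R, 0)
  expect_true(is.na(vx$separation_x) && is.na(vx$reattachment_x))
})

test_that("zero-velocity field has identically zero wall shear stress", {
  fit <- cached_fit(0, "newtonian")
  still <- fit
  still$u[] <- 0; still$v[] <- 0
  wss <- wall_shear_stress(still)
  expect_true(all(wss$tau == 0))
})

test_that("metrics refuse a stale (unconverged) field", {
  fit <- cached_fit(0, "newtonian")
  stale <- fit
  stale$converged <- FALSE
  expect_error(wall_shear_stress(stale), class = "stenoflow_stale_field")
  expect_error(pressure_drop(stale), class = "stenoflow_stale_field")
  expect_error(vortex_length(stale), class = "stenoflow_stale_field")
})

test_that("severe stenosis yields a recirculation bubble behind the throat", {
  fit <- cached_fit(0.625, "newtonian")
  vx <- vortex_length(fit)
  expect_gt(vx$vortex_length_over_R, 0)
  expect_lt(vx$separation_x, vx$reattachment_x)
  expect_gt(vx$separation_x, 0)
  expect_gte(vx$n_bubbles, 1L)
  s <- hemodynamic_summary(fit)
  expect_gt(s$delta_p, 0)
  expect_true(all(s$wss_profile$tau >= 0))
  expect_lt(abs(s$wss_peak_x), fit$geometry$Ls / 2)
  expect_output(print(s), "vortex length")
})

test_that("reporting window is validated and interpolated at its endpoints", {
  fit <- cached_fit(0, "newtonian")
  R <- fit$geometry$R
  expect_error(wall_pressure_profile(fit, c(-10 * R, 9 * R)), "out of domain")
  wp <- wall_pressure_profile(fit, c(-2 * R, 4 * R))
  expect_equal(wp$x[1], -2 * R)
  expect_equal(wp$x[nrow(wp)], 4 * R)
  expect_equal(pressure_drop(fit, c(-2 * R, 4 * R)),
               6 * R * 8 * 0.00345 * REF_UM / R^2, tolerance = 0.02)
})

test_that("diameter sensitivity of the pressure drop follows the D^-4 law", {
  expect_equal(poiseuille_sensitivity_check(-0.01), 0.04)
  expect_identical(poiseuille_sensitivity_check(0), 0)
  expect_equal(poiseuille_sensitivity_check(c(0.02, -0.005)),
               c(-0.08, 0.02))
})

test_that("fitted-model methods expose coefficients, residuals and predictions", {
  fit <- cached_fit(0, "newtonian")
  cf <- coef(fit)
  expect_named(cf, c("eta", "vortex_length_over_R", "delta_p", "wss_peak",
                     "wss_peak_x", "u_max"))
  r <- residuals(fit)
  expect_true(is.matrix(r) && all(colnames(r) == c("mass", "u_mom", "v_mom")))
  expect_lt(r[nrow(r), 1], 1e-6)
  pr <- predict(fit, data.frame(x = c(0.05, 0.05), r = c(0, 0.0025)))
  expect_equal(pr$u[1], 2 * REF_UM, tolerance = 0.01)
  expect_equal(pr$u[2], 2 * REF_UM * (1 - 0.25), tolerance = 0.02)
  expect_output(print(fit), "converged")
  expect_output(print(summary(fit)), "final residuals")
})
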