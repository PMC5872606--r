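# Unit checks of the SIMPLE solver run on deliberately coarse grids; the
# package-default resolution is exercised by the acceptance suite.

test_that("unobstructed Newtonian solve recovers Poiseuille flow", {
  fit <- cached_fit(0, "newtonian")
  expect_true(fit$converged)
  expect_equal(max(fit$u), 2 * REF_UM, tolerance = 0.01)
  expect_lt(stenoflow:::profile_l2_error(fit), 0.01)
  # global mass conservation at every axial station
  expect_lt(max(abs(fit$flux_x - REF_Q)) / REF_Q, 1e-3)
  # axis symmetry: radial velocity vanishes on the first cell row
  expect_lt(max(abs(fit$v[, 1])) / REF_UM, 1e-3)
  # no-slip: two-point extrapolation of u to the wall is zero
  g <- fit$grid; nj <- g$n_radial
  uw <- fit$u[, nj] + (fit$u[, nj] - fit$u[, nj - 1]) *
    g$wall$d1 / (g$wall$d2 - g$wall$d1)
  expect_lt(max(abs(uw)) / REF_UM, 0.01)
})

test_that("unobstructed Carreau solve matches the semi-analytic oracle", {
  fit <- cached_fit(0, "carreau")
  expect_true(fit$converged)
  expect_lt(stenoflow:::profile_l2_error(fit), 0.01)
})

test_that("velocity error against Poiseuille drops at second order under refinement", {
  ctl <- flow_control(tol_mass = 1e-9, tol_mom = 1e-9)
  err <- vapply(list(c(40, 10), c(80, 20)), function(lv) {
    f <- stenosis_flow(ref_geometry(0), rheology = newtonian(),
                       n_axial = lv[1], n_radial = lv[2], control = ctl)
    stenoflow:::profile_l2_error(f)
  }, numeric(1))
  expect_gte(err[1] / err[2], 3)
})

test_that("solver is bit-reproducible for identical configurations", {
  ctl <- flow_control(max_iter = 250)
  args <- list(ref_geometry(0.5), rheology = carreau(), n_axial = 64,
               n_radial = 16, control = ctl, on_nonconvergence = "warn")
  f1 <- suppressWarnings(do.call(stenosis_flow, args))
  f2 <- suppressWarnings(do.call(stenosis_flow, args))
  expect_identical(f1$residual_history, f2$residual_history)
  expect_identical(f1$u, f2$u)
  expect_identical(f1$p, f2$p)
})

test_that("carreau with lambda = 0 and mu_0 = plasma viscosity equals newtonian", {
  fa <- stenosis_flow(ref_geometry(0.5),
                      rheology = carreau(mu_inf = 0.001, mu_0 = 0.00345,
                                         lambda = 0),
                      n_axial = 64, n_radial = 16)
  fb <- stenosis_flow(ref_geometry(0.5), rheology = newtonian(0.00345),
                      n_axial = 64, n_radial = 16)
  expect_lt(max(abs(fa$u - fb$u)) / REF_UM, 1e-10)
  expect_lt(max(abs(fa$p - fb$p)), 1e-8)
})

test_that("effective viscosity is the constitutive law evaluated at the local shear rate", {
  fit <- cached_fit(0.5, "carreau", 64, 16)
  expect_lt(max(abs(fit$mu_eff - viscosity(carreau(), fit$gamma_dot))), 1e-6)
  # interior shear rate agrees with a finite-difference audit of du/dr
  g <- fit$grid; i <- which.min(abs(g$xc[, 1] - 0.1))
  j <- round(g$n_radial / 2)
  fd <- abs((fit$u[i, j + 1] - fit$u[i, j - 1]) / (g$rc[i, j + 1] - g$rc[i, j - 1]))
  expect_equal(fit$gamma_dot[i, j], fd, tolerance = 0.05)
})

test_that("mild stenosis produces no recirculation; uniform inlet is admissible", {
  f25 <- cached_fit(0.25, "carreau")
  wss <- wall_shear_stress(f25)
  expect_true(all(wss$tau_signed[wss$x > 0] > 0))
  fu <- stenosis_flow(ref_geometry(0), rheology = newtonian(), n_axial = 64,
                      n_radial = 16, inlet = "uniform")
  expect_true(fu$converged)
  expect_lt(max(abs(fu$flux_x - REF_Q)) / REF_Q, 1e-3)
  # far downstream the plug profile has developed toward Poiseuille
  expect_equal(max(fu$u), 2 * REF_UM, tolerance = 0.05)
})

test_that("non-convergence raises a classed error carrying the residual history", {
  err <- tryCatch(
    stenosis_flow(ref_geometry(0.5), rheology = carreau(), n_axial = 64,
                  n_radial = 16, control = flow_control(max_iter = 30)),
    error = function(e) e)
  expect_s3_class(err, "stenoflow_diverged")
  expect_true(is.matrix(err$residuals) && nrow(err$residuals) == 30)
})
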