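test_that("poiseuille closed forms at the reference conditions", {
  sol <- poiseuille(R = 0.005, Q = REF_Q, mu = 0.00345)
  expect_equal(sol$tau_w, 4 * 0.00345 * sol$Um / 0.005)
  expect_equal(sol$tau_w, 0.272, tolerance = 2e-3)
  expect_equal(sol$dpdx, -108.9, tolerance = 1e-3)
  expect_equal(sol$u_of_r(0.005), 0)
  expect_equal(sol$u_of_r(0), 2 * sol$Um)
  expect_equal(sol$Q_check, REF_Q)
  expect_error(poiseuille(-1, 1, 1), "positive")
})

test_that("generalized-Newtonian oracle reduces exactly to Poiseuille", {
  pn <- poiseuille(0.005, REF_Q, 0.00345)
  gn <- developed_pipe_flow(0.005, REF_Q, newtonian(0.00345))
  expect_identical(gn$dpdx, pn$dpdx)
  gz <- developed_pipe_flow(0.005, REF_Q, carreau(mu_inf = 0.001,
                                                  mu_0 = 0.00345, lambda = 0))
  expect_equal(gz$dpdx, pn$dpdx)
  expect_equal(gz$tau_w, pn$tau_w)
})

test_that("carreau oracle closes the flow rate and behaves physically", {
  for (cond in list(c(0.005, REF_Q), c(0.0031, 5.98e-5))) {
    sol <- developed_pipe_flow(cond[1], cond[2], carreau())
    expect_lt(abs(sol$Q_check - cond[2]) / cond[2], 1e-8)
    r <- seq(0, cond[1], length.out = 101)
    u <- sol$u_of_r(r)
    expect_equal(which.max(u), 1L)               # maximal on the axis
    expect_true(all(diff(u) < 0))                # monotone decreasing
    expect_equal(u[101] / max(u), 0, tolerance = 1e-6)
    # shear-thinning fluid is at least as viscous as its high-shear plateau
    expect_gte(sol$tau_w, poiseuille(cond[1], cond[2], 0.00345)$tau_w)
  }
})

test_that("carreau stress tau = mu(g) g is strictly increasing (unique inversion)", {
  m <- carreau()
  g <- 10^seq(-3, 6, length.out = 400)
  expect_true(all(diff(viscosity(m, g) * g) > 0))
})

test_that("developed-flow table exposes consistent samples", {
  tab <- developed_flow_table(poiseuille(0.005, REF_Q, 0.00345), n = 11)
  expect_identical(dim(tab), c(11L, 4L))
  expect_equal(tab$u[1], 2 * REF_UM, tolerance = 1e-12)
  expect_equal(tab$mu, rep(0.00345, 11))
})
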