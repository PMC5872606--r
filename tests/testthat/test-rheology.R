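test_that("carreau viscosity matches its closed form and limits", {
  m <- carreau()
  expect_equal(viscosity(m, 0), 0.056)
  # at gamma = 1/lambda the thinning factor is 2^((n-1)/2)
  expect_equal(viscosity(m, 1 / m$lambda),
               m$mu_inf + (m$mu_0 - m$mu_inf) * 2^((m$n - 1) / 2))
  expect_equal(viscosity(m, 1 / m$lambda), 0.0455, tolerance = 1e-2)
  expect_equal(viscosity(m, 1e6), m$mu_inf, tolerance = 1e-2)
  # monotone non-increasing over ten decades
  g <- 10^seq(-3, 6, length.out = 200)
  expect_true(all(diff(viscosity(m, g)) <= 0))
  # bounded in (mu_inf, mu_0]
  expect_true(all(viscosity(m, g) > m$mu_inf & viscosity(m, g) <= m$mu_0))
})

test_that("degenerate parameters collapse carreau onto newtonian behaviour", {
  m0 <- carreau(mu_inf = 0.001, mu_0 = 0.00345, lambda = 0)
  g <- c(0, 0.1, 10, 1e4)
  expect_equal(viscosity(m0, g), rep(0.00345, 4))
  expect_equal(viscosity(newtonian(0.0021), g), rep(0.0021, 4))
})

test_that("constructors and viscosity reject invalid input", {
  expect_error(carreau(mu_inf = 0.06, mu_0 = 0.056), "mu_inf < mu_0")
  expect_error(carreau(lambda = -1), "nonnegative")
  expect_error(carreau(n = 1.2), "power index")
  expect_error(newtonian(0), "positive")
  expect_error(viscosity(carreau(), -1), "nonnegative")
})

test_that("scalar shear rate reduces to the imposed gradient in simple shear", {
  expect_equal(shear_rate(0, 0, 0, 0, 0, 0.001), 0)
  g <- 37.5
  expect_equal(shear_rate(0, g, 0, 0, 0, 0.002), g)
  # parabolic profile at the wall: 4 Um / R
  Um <- 0.0986; R <- 0.005
  expect_equal(shear_rate(0, -4 * Um / R, 0, 0, 0, R), 4 * Um / R)
  expect_equal(4 * Um / R, 78.9, tolerance = 2e-3)
  # hoop term at the axis uses the dv/dr limit
  expect_equal(shear_rate(1, 0, 0, -0.5, 0, 0),
               sqrt(2 * (1 + 0.25 + 0.25)))
  expect_error(shear_rate(0, 0, 0, 0, 0, -1), "nonnegative")
})
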