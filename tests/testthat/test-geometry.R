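test_that("stenosis degree and throat radius invert each other", {
  expect_equal(stenosis_degree(0.005, 0.005), 0)
  expect_equal(stenosis_degree(0.005, 0.0025), 0.75)
  expect_equal(stenosis_degree(0.005, 0.005 / sqrt(2)), 0.5)
  expect_equal(throat_radius_from_degree(0.005, 0), 0.005)
  expect_equal(throat_radius_from_degree(0.005, 0.75), 0.0025)
  expect_equal(throat_radius_from_degree(0.005, 0.625), 0.005 * sqrt(0.375))
  for (eta in c(0, 0.25, 0.5, 0.625, 0.75))
    expect_equal(stenosis_degree(0.005, throat_radius_from_degree(0.005, eta)),
                 eta, tolerance = 1e-12)
  expect_error(stenosis_degree(0.005, 0), "invalid geometry")
  expect_error(stenosis_degree(0.005, 0.006), "invalid geometry")
  expect_error(throat_radius_from_degree(0.005, 1), "invalid degree")
  expect_error(throat_radius_from_degree(0.005, -0.1), "invalid degree")
})

test_that("cosine wall profile hits throat, shoulders and quarter point", {
  geom <- stenosis_geometry(R = 0.005, eta = 0.75)
  Ls <- geom$Ls
  expect_equal(wall_radius(geom, 0), geom$Rt)
  expect_equal(wall_radius(geom, c(-Ls / 2, Ls / 2, Ls, -0.025)),
               rep(geom$R, 4))
  # cos(pi/2) = 0 at x = Ls/4 gives the mid radius
  expect_equal(wall_radius(geom, Ls / 4), (geom$R + geom$Rt) / 2)
  # even in x, unique minimum at 0, monotone on [0, Ls/2]
  xs <- seq(0, Ls / 2, length.out = 101)
  expect_equal(wall_radius(geom, -xs), wall_radius(geom, xs))
  expect_true(all(diff(wall_radius(geom, xs)) > 0))
  expect_error(wall_radius(geom, geom$x_outlet + 1e-3), "out of domain")
})

test_that("geometry constructor validates its inputs", {
  expect_error(stenosis_geometry(eta = 0.5, Rt = 0.004), "not both")
  expect_error(stenosis_geometry(R = -1), "positive")
  expect_error(stenosis_geometry(eta = 0, x_inlet = 0.001), "domain")
  g <- stenosis_geometry()                   # default: unobstructed
  expect_equal(g$eta, 0)
  expect_equal(g$Rt, g$R)
})

test_that("grid metrics are positive, nested and wall-conforming", {
  geom0 <- stenosis_geometry(eta = 0)
  g <- axisymmetric_grid(geom0, 80, 20)
  expect_true(all(g$vol > 0))
  expect_true(all(diff(g$x_faces) > 0))
  expect_true(all(diff(g$r_fraction_faces) > 0))
  # unobstructed meshed volume equals pi R^2 L to near machine precision
  L <- geom0$x_outlet - geom0$x_inlet
  expect_equal(sum(g$vol), pi * geom0$R^2 * L, tolerance = 1e-10)
  # doubling both counts quadruples the cell count
  g2 <- axisymmetric_grid(geom0, 160, 40)
  expect_identical(length(g2$vol), 4L * length(g$vol))
  # wall faces lie exactly on the wall profile
  geom <- stenosis_geometry(eta = 0.75)
  gs <- axisymmetric_grid(geom, 120, 24)
  expect_equal(gs$wall_radius_faces, wall_radius(geom, gs$x_faces))
  expect_equal(min(gs$wall_radius_faces), geom$Rt, tolerance = 1e-2)
  expect_error(axisymmetric_grid(geom0, 20, 20), "configuration error")
  expect_error(axisymmetric_grid(geom0, 80, 4), "configuration error")
})

test_that("grid clusters radially toward the wall and axially near the stenosis", {
  geom <- stenosis_geometry(eta = 0.5)
  g <- axisymmetric_grid(geom, 120, 30)
  dr <- diff(g$r_fraction_faces)
  expect_true(all(diff(dr) < 1e-12))                  # monotone shrink to wall
  expect_lte(dr[length(dr)], 0.25 / 30 + 1e-12)       # quarter of uniform
  dx <- diff(g$x_faces)
  xm <- (g$x_faces[-1] + g$x_faces[-length(g$x_faces)]) / 2
  fine <- max(dx[abs(xm) <= geom$Ls / 2])
  coarse <- max(dx)
  expect_gte(coarse / fine, 3)                        # clustering factor >= 3
})
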