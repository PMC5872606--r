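test_that("reference suite spans five degrees and two rheologies at Re 300", {
  cases <- reference_cases()
  expect_length(cases, 10L)
  labs <- vapply(cases, `[[`, "", "label")
  expect_identical(anyDuplicated(labs), 0L)
  for (cs in cases) {
    Um <- cs$Q / (pi * cs$R^2)
    mu_ref <- if (cs$rheology$kind == "newtonian") cs$rheology$mu else cs$rheology$mu_inf
    expect_equal(cs$rho * Um * 2 * cs$R / mu_ref, 300, tolerance = 0.01)
    expect_equal(cs$Ls, 4 * cs$R)
  }
  e75 <- Filter(function(cs) cs$eta == 0.75, cases)[[1]]
  expect_equal(throat_radius_from_degree(e75$R, e75$eta), 0.0025)
  expect_output(print(cases), "10 cases")
})

test_that("suite runner collects one record per case and reruns bit-identically", {
  cases <- reference_cases(etas = c(0, 0.5), rheologies = "newtonian")
  r1 <- run_suite(cases, n_axial = 64, n_radial = 16, keep_fits = FALSE)
  r2 <- run_suite(cases, n_axial = 64, n_radial = 16, keep_fits = FALSE)
  expect_identical(nrow(r1$summary), 2L)
  expect_true(all(r1$summary$converged))
  expect_identical(r1$summary, r2$summary)
  empty <- run_suite(list(), n_axial = 64, n_radial = 16)
  expect_identical(nrow(empty$summary), 0L)
})

test_that("per-case failures are recorded and the suite continues", {
  cases <- reference_cases(etas = c(0, 0.5), rheologies = "carreau")
  res <- run_suite(cases, n_axial = 64, n_radial = 16,
                   control = flow_control(max_iter = 40))
  expect_identical(nrow(res$summary), 2L)
  expect_true(any(!is.na(res$summary$error)))
  expect_output(print(res), "Failures")
})

test_that("suite outputs land in the run directory with a manifest", {
  td <- file.path(tempdir(), "stenoflow_suite")
  on.exit(unlink(td, recursive = TRUE))
  cases <- reference_cases(etas = 0, rheologies = "newtonian")
  run_suite(cases, n_axial = 64, n_radial = 16, out_dir = td)
  expect_true(file.exists(file.path(td, "summary.csv")))
  expect_true(file.exists(file.path(td, "manifest.json")))
  lab <- cases[[1]]$label
  for (f in c("wss_profile.csv", "wall_pressure.csv", "residuals.log", "field.csv"))
    expect_true(file.exists(file.path(td, lab, f)))
  man <- jsonlite::read_json(file.path(td, "manifest.json"))
  expect_identical(man$n_axial, 64L)
})

test_that("grid convergence study reports zero change for identical levels", {
  cs <- reference_cases(etas = 0, rheologies = "newtonian")[[1]]
  tab <- grid_convergence_study(cs, levels = list(c(64, 16), c(64, 16)))
  expect_identical(nrow(tab), 2L)
  expect_equal(tab$rel_change_delta_p_Pa[2], 0)
  expect_equal(tab$rel_change_wss_peak_Pa[2], 0)
  expect_error(grid_convergence_study(cs, levels = list(c(64, 16))),
               "at least two")
})

test_that("config files resolve to complete solve inputs", {
  cfg_file <- tempfile(fileext = ".yaml")
  on.exit(unlink(cfg_file))
  writeLines(c("R_mm: 5", "eta: 0.625", "Ls_over_R: 4", "model: carreau",
               "n_axial: 80", "n_radial: 20", "Q_L_min: 0.465",
               "numerics:", "  relax_u: 0.6", "  max_iter: 500"), cfg_file)
  cfg <- read_case_config(cfg_file)
  expect_equal(cfg$geometry$eta, 0.625)
  expect_equal(cfg$geometry$Rt, 0.005 * sqrt(0.375))
  expect_identical(cfg$rheology$kind, "carreau")
  expect_equal(cfg$control$relax_u, 0.6)
  expect_equal(cfg$Q, 0.465e-3 / 60)
  expect_identical(cfg$n_axial, 80L)
})

test_that("field and grid exports are well-formed text files", {
  fit <- cached_fit(0, "newtonian", 64, 16)
  csv <- tempfile(fileext = ".csv")
  vtk <- tempfile(fileext = ".vtk")
  log <- tempfile(fileext = ".log")
  on.exit(unlink(c(csv, vtk, log)))
  write_flow_csv(fit, csv)
  expect_identical(nrow(utils::read.csv(csv)), 64L * 16L)
  write_vtk(fit, vtk)
  head <- readLines(vtk, n = 6)
  expect_identical(head[4], "DATASET STRUCTURED_GRID")
  expect_identical(head[5], "DIMENSIONS 65 17 1")
  write_residual_log(fit, log)
  expect_identical(readLines(log, n = 1), "iter mass u_mom v_mom")
})
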