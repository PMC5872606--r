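#' Reference case suite: five stenosis degrees, two rheologies
#'
#' The ten-case comparison at Reynolds number 300: stenosis degrees
#' 0, 0.25, 0.5, 0.625 and 0.75, each under the Newtonian (plasma-viscosity)
#' and Carreau blood models, sharing R = 5 mm, Ls = 4R, Q = 0.465 L/min and
#' rho = 1050 kg/m^3.
#'
#' @param etas Stenosis degrees (default the five reference values).
#' @param rheologies Character subset of `c("newtonian", "carreau")`.
#' @return A list of case specifications (class `stenosis_case_suite`), each
#'   with fields `label`, `eta`, `rheology`, `R`, `Ls`, `Q`, `rho`.
#' @export
#' @examples
#' length(reference_cases()) # 10
reference_cases <- function(etas = c(0, 0.25, 0.5, 0.625, 0.75),
                            rheologies = c("newtonian", "carreau")) {
  rheologies <- match.arg(rheologies, several.ok = TRUE)
  cases <- list()
  for (eta in etas)
    for (rh in rheologies) {
      model <- if (rh == "newtonian") newtonian() else carreau()
      cases[[length(cases) + 1L]] <- list(
        label = sprintf("eta%g_%s", eta, rh),
        eta = eta, rheology = model,
        R = 0.005, Ls = 0.02, Q = 0.465e-3 / 60, rho = 1050)
    }
  structure(cases, class = "stenosis_case_suite")
}

#' @export
print.stenosis_case_suite <- function(x, ...) {
  cat(sprintf("Stenosis case suite: %d cases\n", length(x)))
  for (cs in x) {
    Um <- cs$Q / (pi * cs$R^2)
    mu_ref <- if (cs$rheology$kind == "newtonian") cs$rheology$mu else cs$rheology$mu_inf
    cat(sprintf("  %-18s eta = %-6g Re = %.4g\n", cs$label, cs$eta,
                cs$rho * Um * 2 * cs$R / mu_ref))
  }
  invisible(x)
}

solve_case <- function(cs, n_axial, n_radial, control, inlet = "fully_developed") {
  geom <- stenosis_geometry(R = cs$R, eta = cs$eta, Ls = cs$Ls)
  stenosis_flow(geom, rheology = cs$rheology, Q = cs$Q, rho = cs$rho,
                n_axial = n_axial, n_radial = n_radial, inlet = inlet,
                control = control)
}

#' Run a case suite and collect hemodynamic summaries
#'
#' Solves each case independently (results are deterministic and
#' order-independent) and assembles one summary record per case. Failures are
#' recorded in the table, never dropped. When `out_dir` is given, the summary
#' table, per-case wall profiles and residual logs are written there as CSV,
#' together with a JSON manifest of the fully resolved configuration.
#'
#' @param cases A list from [reference_cases()] (or of the same shape).
#' @param n_axial,n_radial Grid resolution per case.
#' @param control A [flow_control()].
#' @param out_dir Optional output directory.
#' @param keep_fits Keep the fitted objects (`TRUE` by default; set `FALSE`
#'   to save memory on large suites).
#' @return An object of class `stenosis_suite_result`: a list with the
#'   summary data frame `$summary` and, if kept, the fits in `$fits`.
#' @export
run_suite <- function(cases, n_axial = 160, n_radial = 40,
                      control = flow_control(), out_dir = NULL,
                      keep_fits = TRUE) {
  rows <- list(); fits <- list()
  for (k in seq_along(cases)) {
    cs <- cases[[k]]
    res <- tryCatch(solve_case(cs, n_axial, n_radial, control),
                    error = function(e) e)
    if (inherits(res, "error")) {
      rows[[k]] <- data.frame(
        label = cs$label, eta = cs$eta, rheology = cs$rheology$kind,
        converged = FALSE, iterations = NA_integer_,
        vortex_length_over_R = NA_real_, separation_x_mm = NA_real_,
        reattachment_x_mm = NA_real_, delta_p_Pa = NA_real_,
        wss_peak_Pa = NA_real_, wss_peak_x_mm = NA_real_,
        error = conditionMessage(res))
      next
    }
    s <- res$summary
    rows[[k]] <- data.frame(
      label = cs$label, eta = cs$eta, rheology = cs$rheology$kind,
      converged = res$converged, iterations = res$iterations,
      vortex_length_over_R = s$vortex_length_over_R,
      separation_x_mm = 1e3 * s$separation_x,
      reattachment_x_mm = 1e3 * s$reattachment_x,
      delta_p_Pa = s$delta_p, wss_peak_Pa = s$wss_peak,
      wss_peak_x_mm = 1e3 * s$wss_peak_x, error = NA_character_)
    if (keep_fits) fits[[cs$label]] <- res
    if (!is.null(out_dir)) {
      dir.create(file.path(out_dir, cs$label), recursive = TRUE,
                 showWarnings = FALSE)
      write.csv(s$wss_profile,
                file.path(out_dir, cs$label, "wss_profile.csv"),
                row.names = FALSE)
      write.csv(s$wall_pressure_profile,
                file.path(out_dir, cs$label, "wall_pressure.csv"),
                row.names = FALSE)
      write_residual_log(res, file.path(out_dir, cs$label, "residuals.log"))
      write_flow_csv(res, file.path(out_dir, cs$label, "field.csv"))
    }
  }
  summary <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = character(), eta = numeric(), rheology = character(),
               converged = logical(), iterations = integer(),
               vortex_length_over_R = numeric(), separation_x_mm = numeric(),
               reattachment_x_mm = numeric(), delta_p_Pa = numeric(),
               wss_peak_Pa = numeric(), wss_peak_x_mm = numeric(),
               error = character())
  out <- structure(list(summary = summary, fits = fits,
                        n_axial = n_axial, n_radial = n_radial),
                   class = "stenosis_suite_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
    manifest <- list(n_axial = n_axial, n_radial = n_radial,
                     control = unclass(control),
                     cases = lapply(cases, function(cs)
                       list(label = cs$label, eta = cs$eta,
                            rheology = cs$rheology$kind, R = cs$R, Ls = cs$Ls,
                            Q = cs$Q, rho = cs$rho)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.stenosis_suite_result <- function(x, ...) {
  cat(sprintf("Suite of %d cases at %d x %d cells\n", nrow(x$summary),
              x$n_axial, x$n_radial))
  print(x$summary[, setdiff(names(x$summary), "error")], digits = 4,
        row.names = FALSE)
  if (any(!is.na(x$summary$error)))
    cat("Failures:\n", paste(x$summary$label[!is.na(x$summary$error)],
                             x$summary$error[!is.na(x$summary$error)],
                             sep = ": ", collapse = "\n "), "\n")
  invisible(x)
}

#' Grid convergence study of the summary metrics
#'
#' Solves one case at a sequence of grid resolutions and tabulates the
#' pressure drop, wall shear stress peak and vortex length, with the relative
#' change of each metric between successive levels.
#'
#' @param case One case specification (see [reference_cases()]).
#' @param levels List of `c(n_axial, n_radial)` pairs, coarsest first (at
#'   least two).
#' @param control A [flow_control()].
#' @return Data frame with one row per level; columns `rel_change_*` hold the
#'   relative change from the previous level (absolute change for metrics
#'   whose previous value is 0). Failed levels are flagged.
#' @export
grid_convergence_study <- function(case, levels = list(c(160, 40), c(320, 80)),
                                   control = flow_control()) {
  if (length(levels) < 2) stop("need at least two refinement levels")
  rows <- list()
  for (k in seq_along(levels)) {
    lv <- levels[[k]]
    res <- tryCatch(solve_case(case, lv[1], lv[2], control),
                    error = function(e) e)
    ok <- !inherits(res, "error")
    rows[[k]] <- data.frame(
      n_axial = lv[1], n_radial = lv[2], ok = ok,
      delta_p_Pa = if (ok) res$summary$delta_p else NA_real_,
      wss_peak_Pa = if (ok) res$summary$wss_peak else NA_real_,
      vortex_length_over_R = if (ok) res$summary$vortex_length_over_R else NA_real_)
  }
  tab <- do.call(rbind, rows)
  relch <- function(a, b) ifelse(a == 0, abs(b - a), abs(b - a) / abs(a))
  for (m in c("delta_p_Pa", "wss_peak_Pa", "vortex_length_over_R")) {
    v <- tab[[m]]
    tab[[paste0("rel_change_", m)]] <- c(NA, relch(v[-length(v)], v[-1]))
  }
  tab
}

#' Re-enact the developed-flow validation checks
#'
#' Two unobstructed-tube audits of the numerical scheme against the
#' semi-analytic developed-flow solutions: (i) the reference conditions
#' (R = 5 mm, Q = 0.465 L/min) under both rheologies, and (ii) the
#' independent Carreau validation conditions R = 0.0031 m,
#' Q = 5.98e-5 m^3/s, rho = 1000 kg/m^3. Each reports the relative L2
#' deviation of the computed outlet-region velocity profile from the oracle.
#'
#' @param n_axial,n_radial Grid resolution.
#' @param control A [flow_control()].
#' @return Data frame with one row per check: conditions, oracle wall shear
#'   stress, and relative L2 profile error.
#' @export
validate_solver <- function(n_axial = 160, n_radial = 40,
                            control = flow_control()) {
  checks <- list(
    list(label = "reference_newtonian", R = 0.005, Q = 0.465e-3 / 60,
         rho = 1050, model = newtonian()),
    list(label = "reference_carreau", R = 0.005, Q = 0.465e-3 / 60,
         rho = 1050, model = carreau()),
    list(label = "validation_carreau", R = 0.0031, Q = 5.98e-5,
         rho = 1000, model = carreau()))
  rows <- lapply(checks, function(ck) {
    geom <- stenosis_geometry(R = ck$R, eta = 0, Ls = 4 * ck$R)
    fit <- stenosis_flow(geom, rheology = ck$model, Q = ck$Q, rho = ck$rho,
                         n_axial = n_axial, n_radial = n_radial,
                         control = control)
    err <- profile_l2_error(fit)
    data.frame(label = ck$label, R = ck$R, Q = ck$Q, rho = ck$rho,
               rheology = ck$model$kind,
               tau_w_oracle = developed_pipe_flow(ck$R, ck$Q, ck$model)$tau_w,
               l2_error = err)
  })
  do.call(rbind, rows)
}

# relative L2 deviation of the mid-domain velocity profile from the
# developed-flow oracle of the fitted rheology
profile_l2_error <- function(fit, x_station = NULL) {
  g <- fit$grid
  R <- fit$geometry$R
  if (is.null(x_station)) x_station <- 0.5 * (6 * R + g$x_faces[g$n_axial + 1])
  i <- which.min(abs(g$xc[, 1] - x_station))
  dev <- developed_pipe_flow(R, fit$bc$Q, fit$rheology)
  uref <- dev$u_of_r(g$rc[i, ])
  sqrt(sum((fit$u[i, ] - uref)^2) / sum(uref^2))
}
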