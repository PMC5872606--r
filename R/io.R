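#' Read a case configuration file
#'
#' YAML configuration with geometry, rheology and numerics sections. Keys
#' follow the conventions `R_mm`, `eta` or `Rt_mm`, `Ls_over_R`,
#' `x_inlet_over_R`, `x_outlet_over_R`, `n_axial`, `n_radial`,
#' `axial_factor`, `wall_cell_fraction`, `Q_L_min`, `rho`, `inlet`,
#' `model` (`newtonian`/`carreau`) with optional parameter overrides, and any
#' [flow_control()] argument under `numerics`.
#'
#' @param path Path to a YAML file.
#' @return A list with `geometry`, `rheology`, `Q`, `rho`, `inlet`,
#'   `n_axial`, `n_radial`, `axial_factor`, `wall_cell_fraction`, `control` —
#'   ready to feed [stenosis_flow()].
#' @export
read_case_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  R <- (cfg$R_mm %||% 5) * 1e-3
  Ls <- (cfg$Ls_over_R %||% 4) * R
  geom <- stenosis_geometry(
    R = R,
    eta = if (!is.null(cfg$Rt_mm)) NULL else (cfg$eta %||% 0),
    Rt = if (!is.null(cfg$Rt_mm)) cfg$Rt_mm * 1e-3 else NULL,
    Ls = Ls,
    x_inlet = (cfg$x_inlet_over_R %||% -6) * R,
    x_outlet = (cfg$x_outlet_over_R %||% 30) * R)
  model_name <- cfg$model %||% "carreau"
  rpar <- cfg$rheology %||% list()
  rheo <- if (identical(model_name, "newtonian")) {
    newtonian(mu = rpar$mu %||% 0.00345)
  } else {
    carreau(mu_inf = rpar$mu_inf %||% 0.00345, mu_0 = rpar$mu_0 %||% 0.056,
            lambda = rpar$lambda %||% 3.313, n = rpar$n %||% 0.3568)
  }
  ctrl <- do.call(flow_control, cfg$numerics %||% list())
  list(geometry = geom, rheology = rheo,
       Q = (cfg$Q_L_min %||% 0.465) * 1e-3 / 60,
       rho = cfg$rho %||% 1050,
       inlet = cfg$inlet %||% "fully_developed",
       n_axial = cfg$n_axial %||% 160, n_radial = cfg$n_radial %||% 40,
       axial_factor = cfg$axial_factor %||% 4,
       wall_cell_fraction = cfg$wall_cell_fraction %||% 0.25,
       control = ctrl)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export the cell-centred fields as CSV
#'
#' One row per cell: position, velocity, pressure, effective viscosity and
#' shear rate.
#'
#' @param fit A [stenosis_flow()] object.
#' @param path Output file.
#' @export
write_flow_csv <- function(fit, path) {
  g <- fit$grid
  df <- data.frame(x = as.vector(g$xc), r = as.vector(g$rc),
                   u = as.vector(fit$u), v = as.vector(fit$v),
                   p = as.vector(fit$p), mu_eff = as.vector(fit$mu_eff),
                   gamma_dot = as.vector(fit$gamma_dot))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write the residual history as a plain-text log
#'
#' One line per outer iteration: iteration number and the normalized mass,
#' axial-momentum and radial-momentum residuals.
#'
#' @param fit A [stenosis_flow()] object.
#' @param path Output file.
#' @export
write_residual_log <- function(fit, path) {
  r <- fit$residual_history
  lines <- sprintf("%d %.6e %.6e %.6e", seq_len(nrow(r)), r[, 1], r[, 2], r[, 3])
  writeLines(c("iter mass u_mom v_mom", lines), path)
  invisible(path)
}

#' Export a solution (or bare grid) as a legacy-VTK structured grid
#'
#' ASCII legacy VTK with the mesh vertices as a structured grid; when a
#' fitted flow is given, cell data `u`, `v`, `p`, `mu_eff` are attached.
#' Intended for visualization in ParaView and similar tools.
#'
#' @param x An [axisymmetric_grid()] or [stenosis_flow()] object.
#' @param path Output `.vtk` file.
#' @export
write_vtk <- function(x, path) {
  fit <- NULL
  if (inherits(x, "stenosis_flow")) { fit <- x; g <- x$grid }
  else { stopifnot(inherits(x, "axisymmetric_grid")); g <- x }
  ni <- g$n_axial; nj <- g$n_radial
  RV <- outer(g$wall_radius_faces, g$r_fraction_faces)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "stenoflow axisymmetric structured grid", "ASCII",
               "DATASET STRUCTURED_GRID",
               sprintf("DIMENSIONS %d %d 1", ni + 1, nj + 1),
               sprintf("POINTS %d double", (ni + 1) * (nj + 1))), con)
  for (j in seq_len(nj + 1))
    writeLines(sprintf("%.9g %.9g 0", g$x_faces, RV[, j]), con)
  if (!is.null(fit)) {
    writeLines(sprintf("CELL_DATA %d", ni * nj), con)
    for (fld in c("u", "v", "p", "mu_eff")) {
      writeLines(c(sprintf("SCALARS %s double 1", fld),
                   "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.9g", as.vector(fit[[fld]])), con)
    }
  }
  invisible(path)
}
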