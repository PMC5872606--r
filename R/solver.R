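#' Numerical settings for the SIMPLE solver
#'
#' Collects the discretization and iteration controls. Defaults: momentum
#' under-relaxation 0.7, pressure under-relaxation 0.3, viscosity fixed-point
#' relaxation 0.8, convergence when the normalized mass and momentum residuals
#' all fall below 1e-6, second-order upwind convection applied by deferred
#' correction after `fou_iters` pure-upwind startup iterations.
#'
#' @param relax_u,relax_p Under-relaxation factors in (0, 1] for momentum and
#'   pressure.
#' @param relax_mu Relaxation of the viscosity fixed-point update.
#' @param tol_mass,tol_mom Convergence tolerances on the normalized residuals.
#' @param max_iter Outer iteration cap.
#' @param min_iter Minimum outer iterations before convergence may be declared.
#' @param fou_iters First-order upwind startup iterations before the
#'   higher-order deferred correction is switched on.
#' @param scheme Convection scheme: `"second_order_upwind"` (default),
#'   `"central_deferred"`, or `"first_order_upwind"`.
#' @param mom_sweeps Alternating line-relaxation sweeps per outer iteration.
#' @param lin_tol_p,lin_iter_p Relative tolerance and iteration cap of the
#'   conjugate-gradient pressure-correction solve.
#' @param pseudo_dt Optional pseudo-transient time step (s); 0 disables it.
#'   Purely a robustness aid: the reported state is always iteration-converged.
#' @param verbose Print residuals every `verbose` iterations (0 = silent).
#' @return A list of class `flow_control`.
#' @export
flow_control <- function(relax_u = 0.7, relax_p = 0.3, relax_mu = 0.8,
                         tol_mass = 1e-6, tol_mom = 1e-6,
                         max_iter = 20000L, min_iter = 20L, fou_iters = 50L,
                         scheme = c("second_order_upwind", "central_deferred",
                                    "first_order_upwind"),
                         mom_sweeps = 2L, lin_tol_p = 0.05, lin_iter_p = 400L,
                         pseudo_dt = 0, verbose = 0L) {
  scheme <- match.arg(scheme)
  if (relax_u <= 0 || relax_u > 1 || relax_p <= 0 || relax_p > 1)
    stop("relaxation factors must lie in (0, 1]")
  if (tol_mass <= 0 || tol_mom <= 0) stop("tolerances must be positive")
  structure(list(relax_u = relax_u, relax_p = relax_p, relax_mu = relax_mu,
                 tol_mass = tol_mass, tol_mom = tol_mom,
                 max_iter = as.integer(max_iter), min_iter = as.integer(min_iter),
                 fou_iters = as.integer(fou_iters), scheme = scheme,
                 mom_sweeps = as.integer(mom_sweeps), lin_tol_p = lin_tol_p,
                 lin_iter_p = as.integer(lin_iter_p), pseudo_dt = pseudo_dt,
                 verbose = as.integer(verbose)),
            class = "flow_control")
}

#' Solve steady axisymmetric flow through a stenosed tube
#'
#' Fits the steady incompressible axisymmetric Navier-Stokes equations with a
#' generalized-Newtonian viscosity on a boundary-fitted finite-volume grid,
#' using SIMPLE pressure-velocity coupling with colocated variables and
#' Rhie-Chow face-flux interpolation. The inlet carries a fixed flow rate
#' `Q`, imposed either as the fully developed profile of the active rheology
#' (computed by [developed_pipe_flow()]) or as a uniform plug; the wall is
#' no-slip, the axis a symmetry line, and the outlet zero-gradient with the
#' outflow scaled to conserve mass exactly. After the solve the pressure is
#' gauge-shifted so the wall pressure vanishes at `x = 9R` (or the domain end
#' if shorter).
#'
#' @param geometry A [stenosis_geometry()].
#' @param rheology A [newtonian()] or [carreau()] model (default the Carreau
#'   blood model).
#' @param Q Volumetric flow rate (m^3/s). Default 0.465 L/min, the reference
#'   flow through a 5 mm-radius vessel at Reynolds number 300.
#' @param rho Fluid density (kg/m^3). Default 1050.
#' @param grid An [axisymmetric_grid()]; built from `geometry` with
#'   `n_axial` x `n_radial` cells when omitted.
#' @param n_axial,n_radial Grid resolution used when `grid` is omitted.
#' @param inlet `"fully_developed"` (default) or `"uniform"`.
#' @param control A [flow_control()] list.
#' @param on_nonconvergence `"error"` (default) raises a classed error
#'   carrying the residual history; `"warn"` returns the unconverged field.
#' @return An object of class `stenosis_flow`: cell-centred fields `u`, `v`,
#'   `p`, `mu_eff`, `gamma_dot` (matrices, axial x radial), the per-station
#'   axial volume flux `flux_x`, the residual history, convergence metadata,
#'   and a precomputed [hemodynamic_summary()].
#' @seealso [wall_shear_stress()], [pressure_drop()], [vortex_length()]
#' @export
#' @examples
#' \donttest{
#' fit <- stenosis_flow(stenosis_geometry(eta = 0.5), rheology = newtonian(),
#'                      n_axial = 96, n_radial = 24)
#' coef(fit)
#' }
stenosis_flow <- function(geometry, rheology = carreau(), Q = 0.465e-3 / 60,
                          rho = 1050, grid = NULL,
                          n_axial = 160, n_radial = 40,
                          inlet = c("fully_developed", "uniform"),
                          control = flow_control(),
                          on_nonconvergence = c("error", "warn")) {
  stopifnot(inherits(geometry, "stenosis_geometry"),
            inherits(rheology, "rheology_model"))
  inlet <- match.arg(inlet)
  on_nonconvergence <- match.arg(on_nonconvergence)
  if (Q <= 0) stop("flow rate Q must be positive")
  if (is.null(grid)) grid <- axisymmetric_grid(geometry, n_axial, n_radial)
  stopifnot(inherits(grid, "axisymmetric_grid"))

  R <- geometry$R
  Um <- Q / (pi * R^2)
  mu_ref <- if (rheology$kind == "newtonian") rheology$mu else rheology$mu_inf
  Re <- rho * Um * 2 * R / mu_ref

  # inlet profile at inlet-column cell-centre radii
  r_in <- grid$rc[1, ]
  if (inlet == "fully_developed") {
    dev <- developed_pipe_flow(R, Q, rheology)
    u_in <- dev$u_of_r(r_in)
  } else {
    u_in <- rep(Um, length(r_in))
  }

  rc <- rheology_code(rheology)
  ctrl <- unclass(control)
  ctrl$scheme <- switch(control$scheme, first_order_upwind = 0L,
                        second_order_upwind = 1L, central_deferred = 2L)
  t0 <- proc.time()[["elapsed"]]
  out <- simple_solve_cpp(grid$x_faces, grid$r_fraction_faces,
                          grid$wall_radius_faces,
                          grid$xc, grid$rc, grid$vol,
                          rho, rc$kind, rc$par, u_in, Q, ctrl)
  elapsed <- proc.time()[["elapsed"]] - t0

  if (out$breakdown) {
    cond <- structure(class = c("stenoflow_breakdown", "error", "condition"),
                      list(message = "numerical breakdown: non-finite residuals",
                           call = sys.call(-1), residuals = out$residuals))
    stop(cond)
  }
  if (!out$converged && on_nonconvergence == "error") {
    cond <- structure(class = c("stenoflow_diverged", "error", "condition"),
                      list(message = sprintf(
                        "solution not converged in %d iterations (final residuals: mass %.3g, u %.3g, v %.3g)",
                        out$iterations,
                        out$residuals[nrow(out$residuals), 1],
                        out$residuals[nrow(out$residuals), 2],
                        out$residuals[nrow(out$residuals), 3]),
                        call = sys.call(-1), residuals = out$residuals))
    stop(cond)
  }
  if (!out$converged) warning("solution not converged; fields are the last iterate")

  fit <- structure(list(
    geometry = geometry, grid = grid, rheology = rheology,
    bc = list(Q = Q, rho = rho, Um = Um, Re = Re, inlet_profile = inlet,
              outlet = "zero_gradient",
              p_reference = list(location = "wall at x = 9R", value = 0)),
    control = control,
    u = out$u, v = out$v, p = out$p, mu_eff = out$mu_eff,
    gamma_dot = out$gamma_dot, flux_x = out$flux_x,
    u_inlet = out$u_inlet,
    residual_history = out$residuals,
    converged = out$converged, iterations = out$iterations,
    elapsed = elapsed
  ), class = "stenosis_flow")

  # gauge: zero wall pressure at x = 9R (or the last wall sample if shorter)
  x_gauge <- min(9 * R, max(grid$wall$x))
  wp <- wall_pressure_raw(fit)
  p0 <- approx(wp$x, wp$p, xout = x_gauge, rule = 2)$y
  fit$p <- fit$p - p0
  fit$summary <- hemodynamic_summary(fit)
  fit
}
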