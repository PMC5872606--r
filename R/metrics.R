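check_converged <- function(fit) {
  stopifnot(inherits(fit, "stenosis_flow"))
  if (!isTRUE(fit$converged))
    stop(structure(class = c("stenoflow_stale_field", "error", "condition"),
                   list(message = "stale field: flow solution is not converged",
                        call = sys.call(-1))))
  invisible(fit)
}

# wall pressure by two-point extrapolation of the two wall-adjacent cell rows
# to the wall along the wall normal (no convergence gate: used internally
# before the gauge shift)
wall_pressure_raw <- function(fit) {
  g <- fit$grid
  nj <- g$n_radial
  d1 <- g$wall$d1; d2 <- g$wall$d2
  p1 <- fit$p[, nj]; p2 <- fit$p[, nj - 1]
  pw <- p1 + (p1 - p2) * d1 / (d2 - d1)
  data.frame(x = g$wall$x, p = pw)
}

#' Wall shear stress profile
#'
#' The tangential viscous traction on the wall, evaluated per wall face from a
#' one-sided quadratic fit of the tangential velocity at the two wall-adjacent
#' cell rows (exact for a parabolic profile). For the Carreau model the wall
#' viscosity is evaluated at the wall shear rate. The signed value uses the
#' tangent oriented toward `+x`, so attached forward flow is positive and
#' recirculating flow negative.
#'
#' @param fit A converged [stenosis_flow()] object.
#' @return A data frame with wall-face columns `x` (m), `tau` (magnitude, Pa),
#'   `tau_signed` (Pa), `gamma_wall` (1/s) and `mu_wall` (Pa s).
#' @export
wall_shear_stress <- function(fit) {
  check_converged(fit)
  g <- fit$grid
  nj <- g$n_radial
  w <- g$wall
  ut1 <- fit$u[, nj] * w$tx + fit$v[, nj] * w$tr
  ut2 <- fit$u[, nj - 1] * w$tx + fit$v[, nj - 1] * w$tr
  dudn <- (w$d2^2 * ut1 - w$d1^2 * ut2) / (w$d1 * w$d2 * (w$d2 - w$d1))
  gw <- abs(dudn)
  muw <- viscosity(fit$rheology, gw)
  data.frame(x = w$x, tau = muw * gw, tau_signed = muw * dudn,
             gamma_wall = gw, mu_wall = muw)
}

#' Axial wall pressure distribution over a reporting window
#'
#' Wall pressures extrapolated from the wall-adjacent cells, sampled at wall
#' face centres, restricted to `window` with endpoints obtained by linear
#' interpolation, and gauge-shifted so the sample at the downstream window
#' edge is exactly zero.
#'
#' @param fit A converged [stenosis_flow()] object.
#' @param window Axial window (m); default `c(-3, 9) * R`, matching the
#'   reporting convention with the zero-pressure point at `x = 9R`.
#' @return A data frame with columns `x` (m) and `p` (Pa).
#' @export
wall_pressure_profile <- function(fit, window = c(-3, 9) * fit$geometry$R) {
  check_converged(fit)
  wp <- wall_pressure_raw(fit)
  if (window[1] < min(wp$x) - 1e-9 || window[2] > max(wp$x) + 1e-9)
    stop("out of domain: reporting window exceeds the meshed wall extent")
  pa <- approx(wp$x, wp$p, xout = window[1])$y
  pb <- approx(wp$x, wp$p, xout = window[2])$y
  keep <- wp$x > window[1] & wp$x < window[2]
  out <- rbind(data.frame(x = window[1], p = pa),
               wp[keep, ],
               data.frame(x = window[2], p = pb))
  out$p <- out$p - pb
  rownames(out) <- NULL
  out
}

#' Wall pressure drop over a reporting window
#'
#' @inheritParams wall_pressure_profile
#' @return `p_wall(window[1]) - p_wall(window[2])` in Pa (positive for
#'   forward flow).
#' @export
pressure_drop <- function(fit, window = c(-3, 9) * fit$geometry$R) {
  wp <- wall_pressure_profile(fit, window)
  wp$p[1] - wp$p[nrow(wp)]
}

#' Post-stenotic separation vortex length
#'
#' Locates the separation and reattachment points downstream of the throat as
#' the sign changes of the signed wall shear stress (with sub-cell linear
#' interpolation) and returns their distance nondimensionalized by the vessel
#' radius. When the wall shear never changes sign the length is zero and the
#' positions are `NA`. If several recirculation bubbles exist the primary
#' (longest) one is reported and the count flagged.
#'
#' @param fit A converged [stenosis_flow()] object.
#' @return A list with `vortex_length_over_R`, `separation_x`,
#'   `reattachment_x` (m) and `n_bubbles`.
#' @export
vortex_length <- function(fit) {
  check_converged(fit)
  wss <- wall_shear_stress(fit)
  keep <- wss$x > 0
  x <- wss$x[keep]; s <- wss$tau_signed[keep]
  cross <- which(s[-1] * s[-length(s)] < 0)
  xc <- x[cross] - s[cross] * (x[cross + 1] - x[cross]) / (s[cross + 1] - s[cross])
  # negative intervals: separation at + -> - crossing, reattachment at - -> +
  sep <- xc[s[cross] > 0]
  rea <- xc[s[cross] < 0]
  if (length(s) && s[1] < 0) sep <- c(x[1], sep)  # separated already at throat
  n_b <- min(length(sep), length(rea))
  if (n_b == 0)
    return(list(vortex_length_over_R = 0, separation_x = NA_real_,
                reattachment_x = NA_real_, n_bubbles = 0L))
  sep <- sep[seq_len(n_b)]; rea <- rea[seq_len(n_b)]
  len <- rea - sep
  k <- which.max(len)
  list(vortex_length_over_R = len[k] / fit$geometry$R,
       separation_x = sep[k], reattachment_x = rea[k],
       n_bubbles = as.integer(n_b))
}

#' Hemodynamic summary of a converged flow field
#'
#' Bundles the per-case reported quantities: the separation vortex length,
#' the wall pressure drop over the reporting window, and the wall shear
#' stress profile with its peak value and location.
#'
#' @inheritParams wall_pressure_profile
#' @return An object of class `hemodynamic_summary`.
#' @export
hemodynamic_summary <- function(fit, window = c(-3, 9) * fit$geometry$R) {
  check_converged(fit)
  wss <- wall_shear_stress(fit)
  vx <- vortex_length(fit)
  wp <- wall_pressure_profile(fit, window)
  pk <- which.max(wss$tau)
  structure(list(
    eta = fit$geometry$eta, rheology = fit$rheology$kind,
    vortex_length_over_R = vx$vortex_length_over_R,
    separation_x = vx$separation_x, reattachment_x = vx$reattachment_x,
    n_bubbles = vx$n_bubbles,
    delta_p = wp$p[1] - wp$p[nrow(wp)],
    wall_pressure_profile = wp,
    wss_profile = wss[, c("x", "tau", "tau_signed")],
    wss_peak = wss$tau[pk], wss_peak_x = wss$x[pk],
    window = window
  ), class = "hemodynamic_summary")
}

#' @export
print.hemodynamic_summary <- function(x, ...) {
  cat(sprintf("Hemodynamic summary (eta = %.3g, %s rheology)\n", x$eta, x$rheology))
  cat(sprintf("  vortex length       : %.4g R", x$vortex_length_over_R))
  if (x$n_bubbles > 0)
    cat(sprintf("  (separation x = %.4g mm, reattachment x = %.4g mm, %d bubble%s)",
                1e3 * x$separation_x, 1e3 * x$reattachment_x, x$n_bubbles,
                if (x$n_bubbles > 1) "s" else ""))
  cat("\n")
  cat(sprintf("  pressure drop       : %.4g Pa over x in [%.3g, %.3g] mm\n",
              x$delta_p, 1e3 * x$window[1], 1e3 * x$window[2]))
  cat(sprintf("  wall shear peak     : %.4g Pa at x = %.4g mm\n",
              x$wss_peak, 1e3 * x$wss_peak_x))
  invisible(x)
}

#' First-order sensitivity of the pipe pressure drop to diameter
#'
#' For fully developed Newtonian pipe flow at fixed flow rate the pressure
#' drop scales as `D^-4`, so a small relative diameter change `dD/D` produces
#' the relative pressure-drop change `-4 dD/D`. This is the linearized form
#' of the exact ratio `(1 + dD/D)^-4 - 1`.
#'
#' @param delta_D_over_D Small relative diameter change.
#' @return Predicted relative pressure-drop change `-4 * delta_D_over_D`.
#' @seealso [sensitivity_cross_check()] for the two-solve numerical audit.
#' @export
poiseuille_sensitivity_check <- function(delta_D_over_D) {
  -4 * delta_D_over_D
}

#' Numerical audit of the diameter sensitivity of the pressure drop
#'
#' Runs two unobstructed Newtonian solves at radii `R` and `R (1 + delta)` at
#' the same flow rate and identical physical domain and reporting window, and
#' returns the measured relative pressure-drop change next to the linearized
#' `-4 delta` prediction and the exact `(1 + delta)^-4 - 1` ratio.
#'
#' @param delta Relative radius (equivalently diameter) change, small.
#' @param R Base radius (m).
#' @param Q Flow rate (m^3/s).
#' @param mu Newtonian viscosity (Pa s).
#' @param rho Density (kg/m^3).
#' @param n_axial,n_radial Grid resolution.
#' @param control A [flow_control()].
#' @return A list with `measured`, `predicted_linear`, `exact`.
#' @export
sensitivity_cross_check <- function(delta = -0.01, R = 0.005,
                                    Q = 0.465e-3 / 60, mu = 0.00345,
                                    rho = 1050, n_axial = 120, n_radial = 32,
                                    control = flow_control()) {
  window <- c(-3, 9) * R
  solve_at <- function(Rv) {
    geom <- stenosis_geometry(R = Rv, eta = 0, Ls = 4 * R,
                              x_inlet = -6 * R, x_outlet = 30 * R)
    fit <- stenosis_flow(geom, rheology = newtonian(mu), Q = Q, rho = rho,
                         n_axial = n_axial, n_radial = n_radial,
                         control = control)
    pressure_drop(fit, window)
  }
  dp0 <- solve_at(R)
  dp1 <- solve_at(R * (1 + delta))
  list(measured = (dp1 - dp0) / dp0,
       predicted_linear = poiseuille_sensitivity_check(delta),
       exact = (1 + delta)^-4 - 1)
}
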