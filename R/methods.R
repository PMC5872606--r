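#' @export
print.stenosis_flow <- function(x, ...) {
  cat(sprintf("Steady axisymmetric stenosed-tube flow (%s rheology)\n",
              x$rheology$kind))
  cat(sprintf("  eta = %.3g, R = %.3g mm, Q = %.4g L/min, Re = %.4g\n",
              x$geometry$eta, 1e3 * x$geometry$R, x$bc$Q * 6e4, x$bc$Re))
  cat(sprintf("  grid %d x %d, %s after %d iterations (%.1f s)\n",
              x$grid$n_axial, x$grid$n_radial,
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$elapsed))
  invisible(x)
}

#' @export
summary.stenosis_flow <- function(object, ...) {
  structure(list(fit = object, summary = object$summary),
            class = "summary.stenosis_flow")
}

#' @export
print.summary.stenosis_flow <- function(x, ...) {
  print(x$fit)
  r <- x$fit$residual_history
  cat(sprintf("  final residuals: mass %.3g, u %.3g, v %.3g\n",
              r[nrow(r), 1], r[nrow(r), 2], r[nrow(r), 3]))
  fx <- x$fit$flux_x
  cat(sprintf("  axial flux spread: %.3g%% of Q\n",
              100 * (max(fx) - min(fx)) / x$fit$bc$Q))
  print(x$summary)
  invisible(x)
}

#' Headline hemodynamic coefficients of a fitted flow
#'
#' @param object A [stenosis_flow()] object.
#' @param ... Unused.
#' @return Named numeric vector: stenosis degree, vortex length over R,
#'   pressure drop (Pa), wall shear stress peak (Pa) and its location (m),
#'   centreline peak velocity (m/s).
#' @export
coef.stenosis_flow <- function(object, ...) {
  s <- object$summary
  c(eta = s$eta,
    vortex_length_over_R = s$vortex_length_over_R,
    delta_p = s$delta_p,
    wss_peak = s$wss_peak,
    wss_peak_x = s$wss_peak_x,
    u_max = max(object$u))
}

#' Residual history of the SIMPLE iteration
#'
#' @param object A [stenosis_flow()] object.
#' @param ... Unused.
#' @return Matrix with one row per outer iteration and columns `mass`,
#'   `u_mom`, `v_mom` (normalized residuals).
#' @export
residuals.stenosis_flow <- function(object, ...) {
  object$residual_history
}

#' Interpolate the fields of a fitted flow at arbitrary points
#'
#' Bilinear interpolation in the grid's (axial position, radial fraction)
#' index space of the cell-centred fields.
#'
#' @param object A [stenosis_flow()] object.
#' @param newdata Data frame with columns `x` and `r` (m), inside the meshed
#'   domain.
#' @param ... Unused.
#' @return `newdata` with columns `u`, `v`, `p`, `mu_eff` appended.
#' @export
predict.stenosis_flow <- function(object, newdata, ...) {
  stopifnot(is.data.frame(newdata), all(c("x", "r") %in% names(newdata)))
  g <- object$grid
  xcol <- g$xc[, 1]
  rw <- approx(g$x_faces, g$wall_radius_faces, xout = newdata$x, rule = 2)$y
  frac_q <- newdata$r / rw
  if (any(frac_q < 0 | frac_q > 1 + 1e-9))
    stop("out of domain: points outside the tube")
  interp1 <- function(M) {
    vapply(seq_len(nrow(newdata)), function(k) {
      i2 <- findInterval(newdata$x[k], xcol, all.inside = TRUE)
      i2 <- min(max(i2, 1), length(xcol) - 1)
      wts <- (newdata$x[k] - xcol[i2]) / (xcol[i2 + 1] - xcol[i2])
      wts <- min(max(wts, 0), 1)
      val <- function(i) {
        fr <- g$rc[i, ] / approx(g$x_faces, g$wall_radius_faces,
                                 xout = xcol[i], rule = 2)$y
        approx(fr, M[i, ], xout = min(max(frac_q[k], fr[1]), fr[length(fr)]),
               rule = 2)$y
      }
      (1 - wts) * val(i2) + wts * val(i2 + 1)
    }, numeric(1))
  }
  newdata$u <- interp1(object$u)
  newdata$v <- interp1(object$v)
  newdata$p <- interp1(object$p)
  newdata$mu_eff <- interp1(object$mu_eff)
  newdata
}

#' Diagnostic plots of a fitted stenosed-tube flow
#'
#' Four base-graphics panels: axial-velocity field, wall shear stress profile,
#' wall pressure over the reporting window, and the residual history.
#'
#' @param x A [stenosis_flow()] object.
#' @param which Subset of panels 1:4.
#' @param ... Unused.
#' @export
plot.stenosis_flow <- function(x, which = 1:4, ...) {
  op <- par(mfrow = c(length(which) > 2, 2) + c(1, 0) * (length(which) > 2),
            mar = c(4, 4, 2, 1))
  on.exit(par(op))
  R <- x$geometry$R
  if (1 %in% which) {
    image(x$grid$xc[, 1] / R, x$grid$r_fraction_faces[-1], x$u,
          col = hcl.colors(64, "viridis"), xlab = "x / R",
          ylab = "r / r_wall", main = "axial velocity u (m/s)")
  }
  if (2 %in% which) {
    w <- x$summary$wss_profile
    keep <- w$x >= -3 * R & w$x <= 9 * R
    plot(w$x[keep] / R, w$tau[keep], type = "l", xlab = "x / R",
         ylab = "wall shear stress (Pa)", main = "WSS")
    abline(h = 0, lty = 3)
  }
  if (3 %in% which) {
    wp <- x$summary$wall_pressure_profile
    plot(wp$x / R, wp$p, type = "l", xlab = "x / R",
         ylab = "wall pressure (Pa)", main = "wall pressure")
    abline(h = 0, lty = 3)
  }
  if (4 %in% which) {
    r <- x$residual_history
    plot(seq_len(nrow(r)), r[, 1], log = "y", type = "l", xlab = "iteration",
         ylab = "normalized residual", main = "convergence",
         ylim = range(r[r > 0]))
    lines(seq_len(nrow(r)), r[, 2], col = 2)
    lines(seq_len(nrow(r)), r[, 3], col = 4)
    legend("topright", c("mass", "u", "v"), col = c(1, 2, 4), lty = 1,
           bty = "n", cex = 0.8)
  }
  invisible(x)
}
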