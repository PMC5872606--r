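#' Constitutive models for blood viscosity
#'
#' `newtonian()` is a constant-viscosity fluid; its default, 0.00345 Pa s, is
#' the plasma viscosity — the value that makes the diameter-based Reynolds
#' number of the reference flow conditions equal 300. `carreau()` is the
#' four-parameter shear-thinning law
#' \deqn{\mu(\dot\gamma) = \mu_\infty + (\mu_0 - \mu_\infty)
#'   \left(1 + (\lambda\dot\gamma)^2\right)^{(n-1)/2},}
#' interpolating between the zero-shear plateau `mu_0` and the infinite-shear
#' plateau `mu_inf`; the defaults are standard whole-blood parameters.
#' `lambda = 0` is admitted and collapses the law onto a Newtonian fluid of
#' viscosity `mu_0`.
#'
#' @param mu Constant dynamic viscosity (Pa s).
#' @param mu_inf Infinite-shear viscosity (Pa s).
#' @param mu_0 Zero-shear viscosity (Pa s), `> mu_inf`.
#' @param lambda Time constant (s), `>= 0`.
#' @param n Power index in `(0, 1]`.
#' @return An object of class `rheology_model`.
#' @export
#' @examples
#' viscosity(carreau(), c(0, 1, 100, 1e6))
newtonian <- function(mu = 0.00345) {
  if (mu <= 0) stop("newtonian viscosity must be positive")
  structure(list(kind = "newtonian", mu = mu), class = "rheology_model")
}

#' @rdname newtonian
#' @export
carreau <- function(mu_inf = 0.00345, mu_0 = 0.056, lambda = 3.313,
                    n = 0.3568) {
  if (mu_inf <= 0 || mu_0 <= mu_inf)
    stop("carreau model requires 0 < mu_inf < mu_0")
  if (lambda < 0) stop("carreau time constant must be nonnegative")
  if (n <= 0 || n > 1) stop("carreau power index must lie in (0, 1]")
  structure(list(kind = "carreau", mu_inf = mu_inf, mu_0 = mu_0,
                 lambda = lambda, n = n), class = "rheology_model")
}

#' @export
print.rheology_model <- function(x, ...) {
  if (x$kind == "newtonian") {
    cat(sprintf("Newtonian fluid: mu = %.4g Pa s\n", x$mu))
  } else {
    cat(sprintf("Carreau fluid: mu_inf = %.4g, mu_0 = %.4g Pa s, lambda = %.4g s, n = %.4g\n",
                x$mu_inf, x$mu_0, x$lambda, x$n))
  }
  invisible(x)
}

#' Dynamic viscosity at a given shear rate
#'
#' @param model A [newtonian()] or [carreau()] model.
#' @param gamma_dot Scalar shear rate(s), 1/s, nonnegative.
#' @return Dynamic viscosity (Pa s), same length as `gamma_dot`.
#' @export
viscosity <- function(model, gamma_dot) {
  stopifnot(inherits(model, "rheology_model"))
  if (any(gamma_dot < 0)) stop("shear rate must be nonnegative")
  if (model$kind == "newtonian") {
    rep(model$mu, length(gamma_dot))
  } else {
    model$mu_inf + (model$mu_0 - model$mu_inf) *
      (1 + (model$lambda * gamma_dot)^2)^((model$n - 1) / 2)
  }
}

#' Scalar shear rate of an axisymmetric velocity field
#'
#' The generalized second-invariant measure
#' `sqrt(2 D:D)` of the axisymmetric rate-of-strain tensor, whose components
#' are `du/dx`, `dv/dr`, the hoop strain `v/r`, and `(du/dr + dv/dx)/2`.
#' It reduces to the imposed gradient in simple shear. On the axis (`r = 0`)
#' the hoop term is evaluated as its limit `dv/dr`.
#'
#' @param du_dx,du_dr,dv_dx,dv_dr Velocity gradients (1/s).
#' @param v Radial velocity (m/s).
#' @param r Radius (m), nonnegative.
#' @return Nonnegative scalar shear rate (1/s).
#' @export
shear_rate <- function(du_dx, du_dr, dv_dx, dv_dr, v, r) {
  if (any(r < 0)) stop("radius must be nonnegative")
  hoop <- ifelse(r > 0, v / r, dv_dr)
  dxr <- 0.5 * (du_dr + dv_dx)
  sqrt(2 * (du_dx^2 + dv_dr^2 + hoop^2) + 4 * dxr^2)
}

# internal: (kind code, parameter vector) for the compiled solver
rheology_code <- function(model) {
  if (model$kind == "newtonian") {
    list(kind = 0L, par = c(model$mu, 0, 0, 1))
  } else {
    list(kind = 1L, par = c(model$mu_inf, model$mu_0, model$lambda, model$n))
  }
}
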