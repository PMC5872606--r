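#' Degree of stenosis from radii
#'
#' The stenosis degree is the fractional reduction of lumen cross-sectional
#' area at the throat, `eta = 1 - (Rt/R)^2`.
#'
#' @param R Vessel radius (m).
#' @param Rt Throat radius (m), `0 < Rt <= R`.
#' @return Dimensionless degree in `[0, 1)`.
#' @seealso [throat_radius_from_degree()]
#' @export
#' @examples
#' stenosis_degree(0.005, 0.0025) # 75% area reduction
stenosis_degree <- function(R, Rt) {
  if (any(R <= 0)) stop("invalid geometry: vessel radius must be positive")
  if (any(Rt <= 0) || any(Rt > R))
    stop("invalid geometry: throat radius must satisfy 0 < Rt <= R")
  1 - (Rt / R)^2
}

#' Throat radius realizing a given stenosis degree
#'
#' Inverts the area-ratio definition of the degree: `Rt = R * sqrt(1 - eta)`.
#'
#' @param R Vessel radius (m).
#' @param eta Stenosis degree in `[0, 1)`.
#' @return Throat radius (m); round-trips with [stenosis_degree()].
#' @export
throat_radius_from_degree <- function(R, eta) {
  if (any(R <= 0)) stop("invalid geometry: vessel radius must be positive")
  if (any(eta < 0) || any(eta >= 1))
    stop("invalid degree: eta must lie in [0, 1)")
  R * sqrt(1 - eta)
}

#' Parameterized cosine-stenosed tube geometry
#'
#' An axisymmetric tube of radius `R` carrying a single smooth axisymmetric
#' constriction of length `Ls` centred at `x = 0`. The wall follows
#' `r_w(x) = R - ((R - Rt)/2) * (1 + cos(2*pi*x/Ls))` for `|x| <= Ls/2` and
#' equals `R` outside: a cosine bump that reaches the throat radius `Rt`
#' at the centre and joins the straight wall with continuous slope.
#'
#' Exactly one of `eta` or `Rt` must be given (defaulting to `eta = 0`,
#' the unobstructed vessel).
#'
#' @param R Vessel radius (m). Default 5 mm.
#' @param eta Stenosis degree in `[0, 1)`.
#' @param Rt Throat radius (m).
#' @param Ls Stenosis length (m). Default `4 * R`.
#' @param x_inlet,x_outlet Axial domain bounds (m). Defaults `-6R` and `30R`:
#'   the outlet sits far downstream of the longest recirculation so the
#'   zero-gradient outflow condition does not truncate it; reporting windows
#'   are narrower than the computational domain.
#' @return An object of class `stenosis_geometry`.
#' @export
#' @examples
#' geom <- stenosis_geometry(R = 0.005, eta = 0.75)
#' wall_radius(geom, c(-0.02, 0, 0.005, 0.01))
stenosis_geometry <- function(R = 0.005, eta = NULL, Rt = NULL, Ls = 4 * R,
                              x_inlet = -6 * R, x_outlet = 30 * R) {
  if (R <= 0) stop("invalid geometry: vessel radius must be positive")
  if (is.null(eta) && is.null(Rt)) eta <- 0
  if (!is.null(eta) && !is.null(Rt))
    stop("give either 'eta' or 'Rt', not both")
  if (is.null(Rt)) Rt <- throat_radius_from_degree(R, eta)
  eta <- stenosis_degree(R, Rt)
  if (Ls <= 0) stop("invalid geometry: stenosis length must be positive")
  if (!(x_inlet < -Ls / 2) || !(x_outlet > Ls / 2))
    stop("invalid geometry: domain must contain the stenosis, x_inlet < -Ls/2 < Ls/2 < x_outlet")
  structure(list(R = R, Rt = Rt, eta = eta, Ls = Ls,
                 x_inlet = x_inlet, x_outlet = x_outlet),
            class = "stenosis_geometry")
}

#' @export
print.stenosis_geometry <- function(x, ...) {
  cat(sprintf("Axisymmetric stenosed tube: R = %.3g mm, Rt = %.3g mm (eta = %.3g)\n",
              1e3 * x$R, 1e3 * x$Rt, x$eta))
  cat(sprintf("  stenosis length Ls = %.3g mm, domain x in [%.3g, %.3g] mm\n",
              1e3 * x$Ls, 1e3 * x$x_inlet, 1e3 * x$x_outlet))
  invisible(x)
}

#' Wall radius of the stenosed tube
#'
#' @param geom A [stenosis_geometry()] object.
#' @param x Axial positions (m), inside `[x_inlet, x_outlet]`.
#' @return Wall radius at `x` (m).
#' @export
wall_radius <- function(geom, x) {
  stopifnot(inherits(geom, "stenosis_geometry"))
  if (any(x < geom$x_inlet - 1e-12) || any(x > geom$x_outlet + 1e-12))
    stop("out of domain: x outside [x_inlet, x_outlet]")
  r <- rep(geom$R, length(x))
  inb <- abs(x) < geom$Ls / 2
  r[inb] <- geom$R - 0.5 * (geom$R - geom$Rt) *
    (1 + cos(2 * pi * x[inb] / geom$Ls))
  r
}

# strictly-increasing axial face coordinates with smooth clustering around the
# stenosis: local target spacing is h_min inside |x| <= Ls, growing smoothly to
# factor * h_min beyond |x| >= Ls + ramp
axial_faces <- function(geom, n_axial, factor = 4, ramp = geom$Ls) {
  if (factor < 1) stop("configuration error: axial clustering factor must be >= 1")
  xg <- seq(geom$x_inlet, geom$x_outlet, length.out = 8192)
  s <- pmin(pmax((abs(xg) - geom$Ls) / ramp, 0), 1)
  s <- s * s * (3 - 2 * s)                    # smoothstep
  dens <- 1 / (1 + (factor - 1) * s)          # node density ~ 1/spacing
  cum <- cumsum(c(0, (dens[-1] + dens[-length(dens)]) / 2 * diff(xg)))
  cum <- cum / cum[length(cum)]
  xf <- approx(cum, xg, xout = seq(0, 1, length.out = n_axial + 1))$y
  xf[1] <- geom$x_inlet; xf[n_axial + 1] <- geom$x_outlet
  xf
}

# geometric radial face fractions in [0, 1], clustered toward the wall so the
# wall-adjacent spacing is wall_cell_fraction / n_radial
radial_fractions <- function(n_radial, wall_cell_fraction = 0.25) {
  if (wall_cell_fraction <= 0 || wall_cell_fraction > 1)
    stop("configuration error: wall_cell_fraction must be in (0, 1]")
  if (wall_cell_fraction == 1) return(seq(0, 1, length.out = n_radial + 1))
  target <- wall_cell_fraction / n_radial
  last_spacing <- function(g) {
    cc <- (1 - g) / (1 - g^n_radial)
    cc * g^(n_radial - 1)
  }
  g <- uniroot(function(g) last_spacing(g) - target,
               c(1e-4, 1 - 1e-10), tol = 1e-14)$root
  d <- g^(0:(n_radial - 1))
  cumsum(c(0, d)) / sum(d)
}

#' Boundary-fitted structured grid for a stenosed tube
#'
#' Builds a structured quadrilateral mesh in the axial-radial plane: a fixed
#' set of radial face fractions is scaled by the local wall radius in each
#' axial column, so east/west faces are vertical and the top faces lie exactly
#' on the stenosis wall. Radial spacing contracts geometrically toward the
#' wall and axial spacing contracts smoothly toward the stenosis; all metric
#' quantities (areas, volumes) carry the `2*pi*r` axisymmetric weight.
#'
#' @param geom A [stenosis_geometry()] object.
#' @param n_axial,n_radial Cell counts (at least 40 and 10). Defaults 160 and
#'   40.
#' @param axial_factor Ratio of far-field to stenosis-region axial spacing
#'   (>= 1, default 4).
#' @param wall_cell_fraction Wall-adjacent radial spacing as a fraction of the
#'   uniform spacing `1/n_radial` (default 0.25).
#' @return An object of class `axisymmetric_grid`.
#' @export
axisymmetric_grid <- function(geom, n_axial = 160, n_radial = 40,
                              axial_factor = 4, wall_cell_fraction = 0.25) {
  stopifnot(inherits(geom, "stenosis_geometry"))
  if (n_axial < 40 || n_radial < 10)
    stop("configuration error: need n_axial >= 40 and n_radial >= 10")
  xf <- axial_faces(geom, n_axial, factor = axial_factor)
  rfrac <- radial_fractions(n_radial, wall_cell_fraction)
  rwf <- wall_radius(geom, xf)
  ni <- n_axial; nj <- n_radial

  # vertex radii: (ni+1) x (nj+1)
  RV <- outer(rwf, rfrac)
  XV <- matrix(xf, ni + 1, nj + 1)
  # quad cells, vertices counter-clockwise: (i,j), (i+1,j), (i+1,j+1), (i,j+1)
  x1 <- XV[-(ni + 1), -(nj + 1)]; r1 <- RV[-(ni + 1), -(nj + 1)]
  x2 <- XV[-1, -(nj + 1)];        r2 <- RV[-1, -(nj + 1)]
  x3 <- XV[-1, -1];               r3 <- RV[-1, -1]
  x4 <- XV[-(ni + 1), -1];        r4 <- RV[-(ni + 1), -1]
  c1 <- x1 * r2 - x2 * r1; c2 <- x2 * r3 - x3 * r2
  c3 <- x3 * r4 - x4 * r3; c4 <- x4 * r1 - x1 * r4
  A <- 0.5 * (c1 + c2 + c3 + c4)
  XC <- (( x1 + x2) * c1 + (x2 + x3) * c2 + (x3 + x4) * c3 + (x4 + x1) * c4) / (6 * A)
  RC <- (( r1 + r2) * c1 + (r2 + r3) * c2 + (r3 + r4) * c3 + (r4 + r1) * c4) / (6 * A)
  VOL <- 2 * pi * A * RC
  if (any(VOL <= 0)) stop("configuration error: grid produced non-positive cell volumes")

  # wall face geometry (top boundary), one record per axial column
  wx1 <- xf[-(ni + 1)]; wx2 <- xf[-1]
  wr1 <- rwf[-(ni + 1)]; wr2 <- rwf[-1]
  wlen <- sqrt((wx2 - wx1)^2 + (wr2 - wr1)^2)
  tx <- (wx2 - wx1) / wlen; tr <- (wr2 - wr1) / wlen  # tangent, +x oriented
  nx <- -tr; nr <- tx                                  # outward normal (+r side)
  wfx <- (wx1 + wx2) / 2; wfr <- (wr1 + wr2) / 2
  d1 <- abs((XC[, nj] - wfx) * nx + (RC[, nj] - wfr) * nr)
  d2 <- abs((XC[, nj - 1] - wfx) * nx + (RC[, nj - 1] - wfr) * nr)

  structure(list(
    geometry = geom, n_axial = ni, n_radial = nj,
    x_faces = xf, r_fraction_faces = rfrac, wall_radius_faces = rwf,
    xc = XC, rc = RC, vol = VOL,
    wall = list(x = wfx, r = wfr, length = wlen, area = 2 * pi * wfr * wlen,
                tx = tx, tr = tr, nx = nx, nr = nr, d1 = d1, d2 = d2),
    axial_factor = axial_factor, wall_cell_fraction = wall_cell_fraction
  ), class = "axisymmetric_grid")
}

#' @export
print.axisymmetric_grid <- function(x, ...) {
  cat(sprintf("Boundary-fitted axisymmetric grid: %d x %d cells (axial x radial)\n",
              x$n_axial, x$n_radial))
  cat(sprintf("  meshed volume %.6g mm^3; wall-adjacent spacing %.3g of uniform\n",
              1e9 * sum(x$vol), x$wall_cell_fraction))
  print(x$geometry)
  invisible(x)
}
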