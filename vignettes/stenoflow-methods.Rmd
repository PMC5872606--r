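---
title: "Methods: steady hemodynamics of axisymmetric stenoses"
author: "stenoflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: steady hemodynamics of axisymmetric stenoses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The physical model

`stenoflow` computes steady laminar blood flow through an idealized
axisymmetric arterial stenosis. The vessel is a straight tube of radius $R$
whose wall is pinched by a single cosine-shaped constriction of length $L_s$
centred at $x = 0$:

$$ r_w(x) = R - \tfrac{R - R_t}{2}\left(1 + \cos\frac{2\pi x}{L_s}\right),
   \qquad |x| \le L_s/2, $$

and $r_w = R$ outside. The *degree of stenosis* is the fractional area
blockage at the throat, $\eta = 1 - (R_t/R)^2$. The cosine form is the
standard smooth idealization: it meets the straight wall with continuous
slope, so the geometry introduces no corner singularities, and a single
parameter $\eta$ spans the clinically interesting range. Only the exact wall
formula is a modelling choice here — any smooth bump with the same throat
radius behaves similarly — and it is stated explicitly so results are
reproducible.

The flow obeys the steady incompressible Navier–Stokes equations in
axisymmetric cylindrical coordinates $(x, r)$ with a generalized-Newtonian
stress $\boldsymbol\tau = \mu(\dot\gamma)\,(\nabla \mathbf U + \nabla
\mathbf U^{\mathsf T})$. Two constitutive laws are provided:

* **Newtonian**, $\mu = 0.00345$ Pa·s by default. This is the plasma
  viscosity: it is the unique constant viscosity consistent with a
  diameter-based Reynolds number of 300 at the reference conditions below.
* **Carreau**, $\mu(\dot\gamma) = \mu_\infty + (\mu_0 - \mu_\infty)\,
  (1 + (\lambda\dot\gamma)^2)^{(n-1)/2}$ with the standard whole-blood
  parameters $\mu_\infty = 0.00345$ Pa·s, $\mu_0 = 0.056$ Pa·s,
  $\lambda = 3.313$ s, $n = 0.3568$. The law is regular at
  $\dot\gamma = 0$ (it tends to $\mu_0$), so no shear-rate floor is needed.

The scalar shear rate is the second-invariant measure $\dot\gamma =
\sqrt{2\,\mathbf D : \mathbf D}$ of the axisymmetric rate-of-strain tensor,
including the hoop component $v/r$ (evaluated as $\partial v/\partial r$ on
the axis). It reduces exactly to $|\partial u/\partial r|$ in simple shear,
which fixes the normalization against the stress definition above.

**Reference conditions.** All bundled cases use $R = 5$ mm, $L_s = 4R$, a
constant inlet flow rate $Q = 0.465$ L/min (mean velocity
$U_m = 0.0986$ m/s) and density $\rho = 1050$ kg/m³, giving
$\mathrm{Re} = \rho U_m D / \mu_\infty \approx 300$. Five degrees
$\eta \in \{0, 0.25, 0.5, 0.625, 0.75\}$ times two rheologies form the
ten-case suite of `reference_cases()`.

## Discretization and the SIMPLE iteration

The solver is a colocated finite-volume SIMPLE scheme on a boundary-fitted
structured grid:

* **Grid.** A fixed set of radial face fractions is scaled by the local wall
  radius per axial column. East/west faces are therefore vertical, top faces
  lie exactly on $r_w(x)$, and all areas and volumes carry the $2\pi r$
  axisymmetric weight. Radial spacing contracts geometrically toward the
  wall (wall-adjacent cell = 1/4 of the uniform spacing by default) and
  axial spacing contracts smoothly toward the stenosis (far-field spacing
  4x the stenosis-region spacing). The domain runs from $x = -6R$ to
  $x = +30R$: the severe-stenosis recirculation reattaches near
  $10$–$15R$, so the outlet must sit far downstream of it; reporting is
  windowed to $[-3R, 9R]$ afterwards.
* **Convection** is second-order upwind applied as a deferred correction on
  an implicit first-order upwind stencil (a central deferred-correction
  scheme is selectable). The first 50 outer iterations run pure upwind for
  robustness; convergence may only be declared once the high-order
  correction is active.
* **Diffusion** uses the over-relaxed decomposition on non-orthogonal faces:
  the orthogonal part implicit, cross-diffusion and the transpose
  (variable-viscosity) stress explicit from Green–Gauss cell gradients. The
  hoop viscous term $-2\mu v/r^2$ is implicit in the radial momentum
  equation. On axisymmetric cells the face-area vectors do not sum to zero
  ($\oint n_r\,dA = V/\tilde r$), so Green–Gauss gradients are formed from
  $(\phi_f - \phi_P)$, which keeps them exact for constant fields.
* **Wall fluxes** use a one-sided quadratic fit through the two
  wall-adjacent cell rows, exact for a parabolic profile; this keeps the
  no-slip boundary second-order accurate, and the same two-point formula is
  used when the wall shear stress is extracted.
* **Pressure–velocity coupling** is SIMPLE with Rhie–Chow momentum-weighted
  face fluxes. Momentum systems are under-relaxed implicitly (0.7) and
  smoothed with alternating line-TDMA sweeps; the pressure-correction
  system, a symmetric M-matrix, is solved by IC(0)-preconditioned conjugate
  gradients with one cell pinned as pressure reference. Pressure updates are
  relaxed by 0.3. These factors are conventional SIMPLE settings; all ten
  reference cases converge with them, so no case-specific tuning is applied.
* **Boundary conditions.** The inlet (at $-6R$) imposes the fully developed
  profile of the active rheology, computed by the semi-analytic oracle
  below and rescaled so the *discrete* inlet flux equals $\rho Q$ exactly
  (a uniform plug inlet is available; it merely needs a longer development
  length). The axis is a symmetry line — its faces have identically zero
  area in the $2\pi r$ metric, so the condition is enforced by
  construction. The outlet is zero-gradient with the outflow scaled each
  iteration to conserve mass globally. After the solve the pressure gauge
  is shifted so the wall pressure vanishes at $x = 9R$.
* **Convergence** requires the normalized mass and both momentum residuals
  to fall below $10^{-6}$. The iteration is fully deterministic: identical
  configurations reproduce the residual history bit for bit. Non-converged
  solves raise a classed error carrying the residual history. A
  pseudo-transient diagonal is available as a robustness aid but is off by
  default and never substitutes for iteration convergence.

## Semi-analytic oracles

For fully developed pipe flow of any generalized-Newtonian fluid the shear
stress profile is exact: $\tau(r) = |dp/dx|\,r/2$. `developed_pipe_flow()`
inverts $\mu(\dot\gamma)\dot\gamma = \tau(r)$ for $\dot\gamma(r)$ by
bracketed root-finding — the product is strictly increasing for the Carreau
law with $n \le 1$, so the root is unique and bracketed by
$\tau/\mu_0$ and $\tau/\mu_\infty$ — integrates inward for $u(r)$, and
finds the pressure gradient matching $Q$ (via the exact identity
$Q = \pi\int_0^R s^2\dot\gamma(s)\,ds$) to a relative closure of $10^{-8}$.
Gauss–Legendre quadrature with 240 nodes and shear-rate inversions at
$10^{-10}$ relative tolerance make the oracle far more accurate than the
finite-volume solution it checks. For a Newtonian model it reproduces the
Poiseuille closed form to machine precision.

These oracles are used three ways: as the inlet profile, as the independent
reference for the unobstructed-tube checks (including the independent
validation conditions $R = 3.1$ mm, $Q = 5.98\times10^{-5}$ m³/s,
$\rho = 1000$ kg/m³), and as the closed forms behind the
pressure-drop/diameter sensitivity audit ($\delta\Delta p/\Delta p =
-4\,\delta D/D$ at fixed $Q$).

## Hemodynamic metrics

* **Wall shear stress**: per wall face, $\tau_w = \mu_w$ times the
  wall-normal gradient of the tangential velocity from the one-sided
  quadratic fit; $\mu_w$ is evaluated at the wall shear rate. Profiles are
  reported against axial position (not arc length), signed by the
  $+x$-oriented tangent.
* **Separation vortex length**: the distance between the separation and
  reattachment points, located as sign changes of the signed wall shear
  downstream of the throat with sub-cell linear interpolation, divided by
  $R$. It is zero exactly when no sign change exists; with several bubbles
  the longest is reported and the count flagged. (Measuring from the
  separation point rather than the throat is the standard recirculation
  convention and yields zero naturally for attached flow.)
* **Wall pressure**: wall values by two-point extrapolation from the two
  wall-adjacent cell rows, windowed to $[-3R, 9R]$ with interpolated
  endpoints and gauged to zero at $9R$; $\Delta p$ is the difference across
  the window. Peak detection is the plain maximum over wall faces — no
  smoothing.

## Default resolution and what the tests show

The default grid is $160\times40$ cells. The doubled-grid audit
(`grid_convergence_study()`, also run by the test suite) shows the three
summary metrics change by well under 1% between $160\times40$ and
$320\times80$ for both the unobstructed and the severe Carreau case, so the
default sits comfortably in the converged range for the reported quantities;
the unobstructed closed-form checks agree with Poiseuille to ~0.1%. A
refinement study on the unobstructed Newtonian case shows the expected
second-order decay of the velocity error. Users reproducing profile-level
detail (e.g. the WSS curve shape on the shoulder) may prefer the doubled
grid; the summary metrics do not require it.

The case suite *is* the data-generating stage of this package: there is no
external data, and all inputs are the printed physical parameters above.
What passing tests show is therefore internal consistency — agreement with
exact solutions where they exist, grid convergence, conservation, ordering
properties — for an idealized rigid, axisymmetric, steady model. They do not
show fidelity to real arteries: pulsatility, wall compliance, eccentric or
irregular lumina, vessel curvature and turbulence transition are all outside
the model class (deliberately: the point of the standard tube is parameter
transparency, not patient specificity).

## Known behaviour and limitations

* The severe case ($\eta = 0.75$) produces a Carreau recirculation of about
  $9.5R$ and wall shear peaks of about 7.4–7.7 Pa just upstream of the
  throat for both models; the Newtonian bubble is longer (~14R), as expected
  from the lower effective viscosity at the low shear rates inside the
  recirculation.
* The fold increase of the pressure drop over $[-3R, 9R]$ relative to the
  unobstructed vessel differs strongly between rheologies: about 7.8 for
  the Carreau model but about 12 for the Newtonian one. The reason is
  structural, not numerical: the stenotic pressure drop is dominated by
  inertial (expansion-loss) contributions of similar magnitude under both
  laws, while the Newtonian baseline is the exact Poiseuille drop at plasma
  viscosity (6.53 Pa) — substantially smaller than the Carreau baseline
  (9.8 Pa). Any Newtonian fold-increase near 8 would therefore require a
  baseline about 1.5x larger than the Poiseuille value, which this solver
  reproduces to 0.1%. The same tension appears in the wall-shear
  amplification: the Carreau peak is ~19x its own fully developed value
  (0.41 Pa), the Newtonian one ~27x of 0.272 Pa; a quoted "~15x of about
  0.5 Pa" normal value is consistent with neither exact baseline, so
  ratio-type comparisons should quote the rheology and the baseline
  explicitly.
* Steady axisymmetric solutions at $\mathrm{Re} = 300$ with long
  recirculations sit close to the onset of unsteadiness; the SIMPLE
  iteration converges for all bundled cases, but substantially higher
  Reynolds numbers or degrees would require the pseudo-transient option or
  a genuinely unsteady formulation, which is out of scope.

## Reproducing the bundled analyses

```{r example}
library(stenoflow)

# one case end to end
fit <- stenosis_flow(stenosis_geometry(eta = 0.75), rheology = carreau())
summary(fit)
plot(fit)

# the ten-case comparison and the grid study
suite <- run_suite(reference_cases(), out_dir = "stenoflow_suite")
suite$summary
grid_convergence_study(reference_cases(etas = 0.75,
                                       rheologies = "carreau")[[1]])

# developed-flow oracle checks
validate_solver()
```
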