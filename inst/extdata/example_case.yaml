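# Severe-stenosis reference case: 75% area reduction, Carreau blood model,
# Re = 300 by vessel diameter and plasma viscosity.
R_mm: 5
eta: 0.75
Ls_over_R: 4
x_inlet_over_R: -6
x_outlet_over_R: 30
model: carreau
rheology:
  mu_inf: 0.00345
  mu_0: 0.056
  lambda: 3.313
  n: 0.3568
Q_L_min: 0.465
rho: 1050
inlet: fully_developed
n_axial: 160
n_radial: 40
numerics:
  relax_u: 0.7
  relax_p: 0.3
  tol_mass: 1.0e-6
  tol_mom: 1.0e-6
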