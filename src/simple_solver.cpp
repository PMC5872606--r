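// Colocated finite-volume SIMPLE solver for steady incompressible
// axisymmetric (x, r) flow with a generalized-Newtonian viscosity.
//
// Grid: boundary-fitted structured mesh; column ie has vertical faces at
// x = xf[ie]; radial vertex fractions rfrac[] are scaled by the local wall
// radius rwf[ie], so east/west faces are straight vertical segments and
// north/south faces follow the wall slope. All face areas and cell volumes
// carry the 2*pi*r axisymmetric weight.
//
// Discretization: second-order upwind convection by deferred correction on a
// first-order upwind implicit stencil; over-relaxed non-orthogonal diffusion
// with explicit cross-diffusion; Green-Gauss cell gradients; Rhie-Chow
// momentum-weighted face fluxes; one-sided quadratic wall flux (second order
// at the no-slip boundary); hoop viscous term implicit in the radial
// momentum equation. Momentum systems are relaxed implicitly and smoothed by
// alternating line-TDMA sweeps; the pressure-correction system (symmetric
// M-matrix) is solved by IC(0)-preconditioned conjugate gradients.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

static const double PI_ = 3.14159265358979323846;

static inline double viscfun(int kind, const double* rp, double g) {
  if (kind == 0) return rp[0];               // newtonian: rp[0] = mu
  // carreau: rp = {mu_inf, mu_0, lambda, n}
  const double lg = rp[2] * g;
  return rp[0] + (rp[1] - rp[0]) * std::pow(1.0 + lg * lg, 0.5 * (rp[3] - 1.0));
}

// [[Rcpp::export]]
List simple_solve_cpp(NumericVector xf, NumericVector rfrac, NumericVector rwf,
                      NumericMatrix XC, NumericMatrix RC, NumericMatrix VOLm,
                      double rho, int rheo_kind, NumericVector rheo_par,
                      NumericVector u_inlet_in, double Q, List ctrl)
{
  const int ni = xf.size() - 1;
  const int nj = rfrac.size() - 1;
  const int nc = ni * nj;

  const double relax_u  = as<double>(ctrl["relax_u"]);
  const double relax_p  = as<double>(ctrl["relax_p"]);
  const double relax_mu = as<double>(ctrl["relax_mu"]);
  const double tol_mass = as<double>(ctrl["tol_mass"]);
  const double tol_mom  = as<double>(ctrl["tol_mom"]);
  const int    max_iter = as<int>(ctrl["max_iter"]);
  const int    min_iter = as<int>(ctrl["min_iter"]);
  const int    fou_iters = as<int>(ctrl["fou_iters"]);
  const int    scheme   = as<int>(ctrl["scheme"]); // 0 fou, 1 sou, 2 central deferred
  const int    mom_sweeps = as<int>(ctrl["mom_sweeps"]);
  const double lin_tol_p = as<double>(ctrl["lin_tol_p"]);
  const int    lin_iter_p = as<int>(ctrl["lin_iter_p"]);
  const double pseudo_dt = as<double>(ctrl["pseudo_dt"]);
  const int    verbose  = as<int>(ctrl["verbose"]);

  const double* rp = REAL(rheo_par);

  // ---- geometry ---------------------------------------------------------
  std::vector<double> vol(nc), xc(nc), rc(nc);
  for (int j = 0; j < nj; ++j)
    for (int i = 0; i < ni; ++i) {
      vol[i + j * ni] = VOLm(i, j);
      xc [i + j * ni] = XC(i, j);
      rc [i + j * ni] = RC(i, j);
    }
  auto id = [ni](int i, int j) { return i + j * ni; };
  auto fe = [ni](int ie, int j) { return ie + j * (ni + 1); }; // east faces
  auto fn = [ni](int i, int jn) { return i + jn * ni; };       // north faces

  // east (vertical) faces: ie = 0..ni, j = 0..nj-1
  const int nfe = (ni + 1) * nj;
  std::vector<double> eA(nfe), eFr(nfe);
  for (int ie = 0; ie <= ni; ++ie)
    for (int j = 0; j < nj; ++j) {
      double r1 = rfrac[j] * rwf[ie], r2 = rfrac[j + 1] * rwf[ie];
      eA [fe(ie, j)] = PI_ * (r2 * r2 - r1 * r1);   // 2*pi*rbar*dr
      eFr[fe(ie, j)] = 0.5 * (r1 + r2);
    }
  // north (sloped) faces: i = 0..ni-1, jn = 0..nj
  const int nfn = ni * (nj + 1);
  std::vector<double> nSx(nfn), nSr(nfn), nFx(nfn), nFr(nfn);
  for (int i = 0; i < ni; ++i)
    for (int jn = 0; jn <= nj; ++jn) {
      double x1 = xf[i], x2 = xf[i + 1];
      double r1 = rfrac[jn] * rwf[i], r2 = rfrac[jn] * rwf[i + 1];
      double rb = 0.5 * (r1 + r2);
      nSx[fn(i, jn)] = -2.0 * PI_ * rb * (r2 - r1);
      nSr[fn(i, jn)] =  2.0 * PI_ * rb * (x2 - x1);
      nFx[fn(i, jn)] = 0.5 * (x1 + x2);
      nFr[fn(i, jn)] = rb;
    }

  // interior east-face metrics (ie = 1..ni-1)
  std::vector<double> eLam(nfe, 0.5), eDx(nfe, 0), eDr(nfe, 0), eEf(nfe, 0),
                      eTx(nfe, 0), eTr(nfe, 0);
  for (int ie = 1; ie < ni; ++ie)
    for (int j = 0; j < nj; ++j) {
      int P = id(ie - 1, j), N = id(ie, j), f = fe(ie, j);
      double dx = xc[N] - xc[P], dr = rc[N] - rc[P];
      double fx = xf[ie], fr = eFr[f];
      double dP = std::hypot(fx - xc[P], fr - rc[P]);
      double dN = std::hypot(fx - xc[N], fr - rc[N]);
      eLam[f] = dN / (dP + dN);
      eDx[f] = dx; eDr[f] = dr;
      double A = eA[f];
      double sd = A * dx; // S = (A, 0)
      eEf[f] = A * A / sd;
      eTx[f] = A - eEf[f] * dx;
      eTr[f] =   - eEf[f] * dr;
    }
  // interior north-face metrics (jn = 1..nj-1)
  std::vector<double> nLam(nfn, 0.5), nDx(nfn, 0), nDr(nfn, 0), nEf(nfn, 0),
                      nTx(nfn, 0), nTr(nfn, 0);
  for (int i = 0; i < ni; ++i)
    for (int jn = 1; jn < nj; ++jn) {
      int P = id(i, jn - 1), N = id(i, jn), f = fn(i, jn);
      double dx = xc[N] - xc[P], dr = rc[N] - rc[P];
      double dP = std::hypot(nFx[f] - xc[P], nFr[f] - rc[P]);
      double dN = std::hypot(nFx[f] - xc[N], nFr[f] - rc[N]);
      nLam[f] = dN / (dP + dN);
      nDx[f] = dx; nDr[f] = dr;
      double Sx = nSx[f], Sr = nSr[f];
      double sd = Sx * dx + Sr * dr;
      double s2 = Sx * Sx + Sr * Sr;
      nEf[f] = s2 / sd;
      nTx[f] = Sx - nEf[f] * dx;
      nTr[f] = Sr - nEf[f] * dr;
    }

  // Net outward face-area vector per cell. With the 2*pi*r weights the
  // radial components do not cancel (closed-surface identity in cylindrical
  // coordinates: sum S_r = V / r_tilde), so Green-Gauss gradients must be
  // formed from (phi_f - phi_P) to be exact for constant fields.
  std::vector<double> Bx(nc, 0.0), Br(nc, 0.0);
  for (int j = 0; j < nj; ++j)
    for (int i = 0; i < ni; ++i) {
      int c = i + j * ni;
      Bx[c] = eA[(i + 1) + j * (ni + 1)] - eA[i + j * (ni + 1)]
            + nSx[i + (j + 1) * ni] - nSx[i + j * ni];
      Br[c] = nSr[i + (j + 1) * ni] - nSr[i + j * ni];
    }

  // inlet boundary metrics (cells (0, j)); outward S = (-A, 0)
  std::vector<double> inEf(nj), inTx(nj), inTr(nj);
  for (int j = 0; j < nj; ++j) {
    int P = id(0, j), f = fe(0, j);
    double A = eA[f];
    double dbx = xf[0] - xc[P], dbr = eFr[f] - rc[P];
    double sd = -A * dbx;
    inEf[j] = A * A / sd;
    inTx[j] = -A - inEf[j] * dbx;
    inTr[j] =     - inEf[j] * dbr;
  }
  // wall boundary metrics (cells (i, nj-1)); quadratic normal-gradient flux
  std::vector<double> wS(ni), wNx(ni), wNr(ni), wD1(ni), wD2(ni),
                      wC1(ni), wC2(ni);
  for (int i = 0; i < ni; ++i) {
    int f = fn(i, nj);
    double Sx = nSx[f], Sr = nSr[f];
    double S = std::hypot(Sx, Sr);
    wS[i] = S; wNx[i] = Sx / S; wNr[i] = Sr / S;
    int P1 = id(i, nj - 1), P2 = id(i, nj - 2);
    double d1 = std::abs((xc[P1] - nFx[f]) * wNx[i] + (rc[P1] - nFr[f]) * wNr[i]);
    double d2 = std::abs((xc[P2] - nFx[f]) * wNx[i] + (rc[P2] - nFr[f]) * wNr[i]);
    wD1[i] = d1; wD2[i] = d2;
    // one-sided quadratic derivative at the wall through (0,0),(d1,u1),(d2,u2)
    wC1[i] = d2 * d2 / (d1 * d2 * (d2 - d1));
    wC2[i] = -d1 * d1 / (d1 * d2 * (d2 - d1));
  }

  // ---- fields ------------------------------------------------------------
  std::vector<double> u(nc), v(nc, 0.0), p(nc, 0.0), mu(nc), gam(nc, 0.0);
  std::vector<double> gux(nc, 0), gur(nc, 0), gvx(nc, 0), gvr(nc, 0),
                      gpx(nc, 0), gpr(nc, 0), gcx(nc, 0), gcr(nc, 0);
  std::vector<double> aP(nc), aW(nc), aE(nc), aS(nc), aN(nc),
                      bu(nc), bv(nc), aPu(nc), aPv(nc), dcell(nc), pc(nc, 0.0);
  std::vector<double> me(nfe, 0.0), mn(nfn, 0.0);

  const double R0 = rwf[0];
  const double Um = Q / (PI_ * R0 * R0);

  // inlet profile scaled so the discrete inlet flux equals rho*Q exactly
  std::vector<double> u_in(nj);
  {
    double qd = 0.0;
    for (int j = 0; j < nj; ++j) qd += u_inlet_in[j] * eA[fe(0, j)];
    double sc = Q / qd;
    for (int j = 0; j < nj; ++j) u_in[j] = u_inlet_in[j] * sc;
  }

  // initial guess: inlet profile stretched column-wise by the area ratio
  for (int i = 0; i < ni; ++i) {
    double rw_i = 0.5 * (rwf[i] + rwf[i + 1]);
    double sc = (R0 * R0) / (rw_i * rw_i);
    for (int j = 0; j < nj; ++j) u[id(i, j)] = u_in[j] * sc;
  }
  double gam0 = 4.0 * Um / R0;
  for (int c = 0; c < nc; ++c) mu[c] = viscfun(rheo_kind, rp, gam0);

  // initial face fluxes (no pressure contribution; p = 0)
  for (int ie = 1; ie < ni; ++ie)
    for (int j = 0; j < nj; ++j) {
      int f = fe(ie, j), P = id(ie - 1, j), N = id(ie, j);
      double uf = eLam[f] * u[P] + (1 - eLam[f]) * u[N];
      me[f] = rho * uf * eA[f];
    }
  for (int j = 0; j < nj; ++j) {
    me[fe(0, j)]  = rho * u_in[j] * eA[fe(0, j)];
    me[fe(ni, j)] = rho * u[id(ni - 1, j)] * eA[fe(ni, j)];
  }
  {
    double s = 0.0;
    for (int j = 0; j < nj; ++j) s += me[fe(ni, j)];
    double sc = rho * Q / s;
    for (int j = 0; j < nj; ++j) me[fe(ni, j)] *= sc;
  }
  for (int i = 0; i < ni; ++i)
    for (int jn = 1; jn < nj; ++jn) {
      int f = fn(i, jn), P = id(i, jn - 1), N = id(i, jn);
      double uf = nLam[f] * u[P] + (1 - nLam[f]) * u[N];
      double vf = nLam[f] * v[P] + (1 - nLam[f]) * v[N];
      mn[f] = rho * (uf * nSx[f] + vf * nSr[f]);
    }

  // ---- helpers -----------------------------------------------------------
  // Green-Gauss gradient of a cell field; boundary treatment flag:
  //   0: Dirichlet inlet value from bval (u uses u_in, v uses 0),
  //      zero at wall, zero-gradient at outlet  (velocity components)
  //   1: extrapolated boundary values for pressure (uses gx, gy as lag)
  //   2: zero-gradient everywhere (pressure correction)
  auto gradient = [&](const std::vector<double>& f, std::vector<double>& gx,
                      std::vector<double>& gy, int btype,
                      const std::vector<double>* bval) {
    std::vector<double> sx(nc, 0.0), sy(nc, 0.0);
    for (int ie = 1; ie < ni; ++ie)
      for (int j = 0; j < nj; ++j) {
        int ff = fe(ie, j), P = id(ie - 1, j), N = id(ie, j);
        double fv = eLam[ff] * f[P] + (1 - eLam[ff]) * f[N];
        double Sx = eA[ff];
        sx[P] += fv * Sx; sx[N] -= fv * Sx;
      }
    for (int i = 0; i < ni; ++i)
      for (int jn = 1; jn < nj; ++jn) {
        int ff = fn(i, jn), P = id(i, jn - 1), N = id(i, jn);
        double fv = nLam[ff] * f[P] + (1 - nLam[ff]) * f[N];
        sx[P] += fv * nSx[ff]; sx[N] -= fv * nSx[ff];
        sy[P] += fv * nSr[ff]; sy[N] -= fv * nSr[ff];
      }
    for (int j = 0; j < nj; ++j) {       // inlet / outlet
      int P0 = id(0, j), P1 = id(ni - 1, j);
      double A0 = eA[fe(0, j)], A1 = eA[fe(ni, j)];
      double fb0, fb1;
      if (btype == 0) { fb0 = bval ? (*bval)[j] : 0.0; fb1 = f[P1]; }
      else if (btype == 1) {
        fb0 = f[P0] + gx[P0] * (xf[0] - xc[P0]) + gy[P0] * (eFr[fe(0, j)] - rc[P0]);
        fb1 = f[P1] + gx[P1] * (xf[ni] - xc[P1]) + gy[P1] * (eFr[fe(ni, j)] - rc[P1]);
      } else { fb0 = f[P0]; fb1 = f[P1]; }
      sx[P0] += fb0 * (-A0);
      sx[P1] += fb1 * ( A1);
    }
    for (int i = 0; i < ni; ++i) {       // wall (axis face has zero area)
      int P = id(i, nj - 1), ff = fn(i, nj);
      double fb;
      if (btype == 0) fb = 0.0;
      else if (btype == 1)
        fb = f[P] + gx[P] * (nFx[ff] - xc[P]) + gy[P] * (nFr[ff] - rc[P]);
      else fb = f[P];
      sx[P] += fb * nSx[ff]; sy[P] += fb * nSr[ff];
    }
    for (int c = 0; c < nc; ++c) {
      gx[c] = (sx[c] - f[c] * Bx[c]) / vol[c];
      gy[c] = (sy[c] - f[c] * Br[c]) / vol[c];
    }
  };

  // tridiagonal solve (Thomas); lo/up are sub/super diagonals
  std::vector<double> t_lo(std::max(ni, nj)), t_di(std::max(ni, nj)),
                      t_up(std::max(ni, nj)), t_rh(std::max(ni, nj)),
                      t_cp(std::max(ni, nj));
  auto thomas = [&](int n, std::vector<double>& lo, std::vector<double>& di,
                    std::vector<double>& up, std::vector<double>& rh) {
    t_cp[0] = up[0] / di[0];
    rh[0] = rh[0] / di[0];
    for (int k = 1; k < n; ++k) {
      double m = 1.0 / (di[k] - lo[k] * t_cp[k - 1]);
      t_cp[k] = up[k] * m;
      rh[k] = (rh[k] - lo[k] * rh[k - 1]) * m;
    }
    for (int k = n - 2; k >= 0; --k) rh[k] -= t_cp[k] * rh[k + 1];
  };

  auto sweep_jlines = [&](std::vector<double>& phi, const std::vector<double>& aPd,
                          const std::vector<double>& b, bool fwd) {
    for (int s = 0; s < ni; ++s) {
      int i = fwd ? s : ni - 1 - s;
      for (int j = 0; j < nj; ++j) {
        int c = id(i, j);
        t_lo[j] = -aS[c]; t_di[j] = aPd[c]; t_up[j] = -aN[c];
        double r = b[c];
        if (i > 0)      r += aW[c] * phi[id(i - 1, j)];
        if (i < ni - 1) r += aE[c] * phi[id(i + 1, j)];
        t_rh[j] = r;
      }
      thomas(nj, t_lo, t_di, t_up, t_rh);
      for (int j = 0; j < nj; ++j) phi[id(i, j)] = t_rh[j];
    }
  };
  auto sweep_ilines = [&](std::vector<double>& phi, const std::vector<double>& aPd,
                          const std::vector<double>& b, bool fwd) {
    for (int s = 0; s < nj; ++s) {
      int j = fwd ? s : nj - 1 - s;
      for (int i = 0; i < ni; ++i) {
        int c = id(i, j);
        t_lo[i] = -aW[c]; t_di[i] = aPd[c]; t_up[i] = -aE[c];
        double r = b[c];
        if (j > 0)      r += aS[c] * phi[id(i, j - 1)];
        if (j < nj - 1) r += aN[c] * phi[id(i, j + 1)];
        t_rh[i] = r;
      }
      thomas(ni, t_lo, t_di, t_up, t_rh);
      for (int i = 0; i < ni; ++i) phi[id(i, j)] = t_rh[i];
    }
  };

  // ---- outer SIMPLE loop -------------------------------------------------
  std::vector<double> hist;
  hist.reserve(3 * 2048);
  bool converged = false, breakdown = false;
  int it_done = 0;
  const double mom_ref = rho * Q * Um;
  std::vector<double> peC(nfe, 0.0), pnC(nfn, 0.0); // pressure-eq face coeffs
  std::vector<double> pdiag(nc), prhs(nc);
  std::vector<double> ld(nc), lw(nc), ls(nc);       // IC(0) factors
  std::vector<double> cg_r(nc), cg_z(nc), cg_p(nc), cg_q(nc);

  for (int it = 1; it <= max_iter; ++it) {
    // gradients
    gradient(u, gux, gur, 0, &u_in);
    gradient(v, gvx, gvr, 0, nullptr);
    gradient(p, gpx, gpr, 1, nullptr);
    gradient(p, gpx, gpr, 1, nullptr); // second pass refines boundary extrapolation

    // shear rate and viscosity (relaxed fixed-point update)
    for (int c = 0; c < nc; ++c) {
      double Dxx = gux[c], Drr = gvr[c], Dtt = v[c] / rc[c];
      double Dxr = 0.5 * (gur[c] + gvx[c]);
      double g = std::sqrt(2.0 * (Dxx * Dxx + Drr * Drr + Dtt * Dtt) +
                           4.0 * Dxr * Dxr);
      gam[c] = g;
      double mnew = viscfun(rheo_kind, rp, g);
      mu[c] += relax_mu * (mnew - mu[c]);
    }

    // ---- momentum assembly ----
    std::fill(aP.begin(), aP.end(), 0.0);
    std::fill(aW.begin(), aW.end(), 0.0);
    std::fill(aE.begin(), aE.end(), 0.0);
    std::fill(aS.begin(), aS.end(), 0.0);
    std::fill(aN.begin(), aN.end(), 0.0);
    std::fill(bu.begin(), bu.end(), 0.0);
    std::fill(bv.begin(), bv.end(), 0.0);
    const bool hi_order = (scheme > 0) && (it > fou_iters);

    for (int ie = 1; ie < ni; ++ie)
      for (int j = 0; j < nj; ++j) {
        int f = fe(ie, j), P = id(ie - 1, j), N = id(ie, j);
        double lam = eLam[f];
        double muf = lam * mu[P] + (1 - lam) * mu[N];
        double D = muf * eEf[f];
        double m = me[f];
        double mPos = std::max(m, 0.0), mNeg = std::max(-m, 0.0);
        aE[P] += D + mNeg;  aP[P] += D + mPos;
        aW[N] += D + mPos;  aP[N] += D + mNeg;
        if (hi_order) {
          int U = (m >= 0.0) ? P : N;
          double fx = xf[ie], fr = eFr[f];
          double du, dv;
          if (scheme == 1) {
            du = gux[U] * (fx - xc[U]) + gur[U] * (fr - rc[U]);
            dv = gvx[U] * (fx - xc[U]) + gvr[U] * (fr - rc[U]);
          } else { // central by deferred correction
            du = (lam * u[P] + (1 - lam) * u[N]) - u[U];
            dv = (lam * v[P] + (1 - lam) * v[N]) - v[U];
          }
          bu[P] -= m * du; bu[N] += m * du;
          bv[P] -= m * dv; bv[N] += m * dv;
        }
        // explicit cross-diffusion + transpose stress
        double guxf = lam * gux[P] + (1 - lam) * gux[N];
        double gurf = lam * gur[P] + (1 - lam) * gur[N];
        double gvxf = lam * gvx[P] + (1 - lam) * gvx[N];
        double gvrf = lam * gvr[P] + (1 - lam) * gvr[N];
        double su = muf * (guxf * eTx[f] + gurf * eTr[f])
                  + muf * (guxf * eA[f]); // (gradU^T S)_x, S = (A, 0)
        double sv = muf * (gvxf * eTx[f] + gvrf * eTr[f])
                  + muf * (gurf * eA[f]); // (gradU^T S)_r
        bu[P] += su; bu[N] -= su;
        bv[P] += sv; bv[N] -= sv;
      }

    for (int i = 0; i < ni; ++i)
      for (int jn = 1; jn < nj; ++jn) {
        int f = fn(i, jn), P = id(i, jn - 1), N = id(i, jn);
        double lam = nLam[f];
        double muf = lam * mu[P] + (1 - lam) * mu[N];
        double D = muf * nEf[f];
        double m = mn[f];
        double mPos = std::max(m, 0.0), mNeg = std::max(-m, 0.0);
        aN[P] += D + mNeg;  aP[P] += D + mPos;
        aS[N] += D + mPos;  aP[N] += D + mNeg;
        if (hi_order) {
          int U = (m >= 0.0) ? P : N;
          double du, dv;
          if (scheme == 1) {
            du = gux[U] * (nFx[f] - xc[U]) + gur[U] * (nFr[f] - rc[U]);
            dv = gvx[U] * (nFx[f] - xc[U]) + gvr[U] * (nFr[f] - rc[U]);
          } else {
            du = (lam * u[P] + (1 - lam) * u[N]) - u[U];
            dv = (lam * v[P] + (1 - lam) * v[N]) - v[U];
          }
          bu[P] -= m * du; bu[N] += m * du;
          bv[P] -= m * dv; bv[N] += m * dv;
        }
        double guxf = lam * gux[P] + (1 - lam) * gux[N];
        double gurf = lam * gur[P] + (1 - lam) * gur[N];
        double gvxf = lam * gvx[P] + (1 - lam) * gvx[N];
        double gvrf = lam * gvr[P] + (1 - lam) * gvr[N];
        double su = muf * (guxf * nTx[f] + gurf * nTr[f])
                  + muf * (guxf * nSx[f] + gvxf * nSr[f]);
        double sv = muf * (gvxf * nTx[f] + gvrf * nTr[f])
                  + muf * (gurf * nSx[f] + gvrf * nSr[f]);
        bu[P] += su; bu[N] -= su;
        bv[P] += sv; bv[N] -= sv;
      }

    // inlet: Dirichlet velocity, fixed inflow
    for (int j = 0; j < nj; ++j) {
      int P = id(0, j);
      double m = -me[fe(0, j)];              // outward flux (negative)
      double D = mu[P] * inEf[j];
      aP[P] += D;                            // + max(m,0) = 0 for inflow
      bu[P] += D * u_in[j] - m * u_in[j];
      // cross-diffusion with Dirichlet face value folded in via gradients
      double su = mu[P] * (gux[P] * inTx[j] + gur[P] * inTr[j])
                + mu[P] * (gux[P] * (-eA[fe(0, j)]));
      double sv = mu[P] * (gvx[P] * inTx[j] + gvr[P] * inTr[j])
                + mu[P] * (gur[P] * (-eA[fe(0, j)]));
      bu[P] += su; bv[P] += sv;
    }
    // outlet: zero-gradient, convected out implicitly
    for (int j = 0; j < nj; ++j) {
      int P = id(ni - 1, j);
      double m = me[fe(ni, j)];
      aP[P] += std::max(m, 0.0);
      bu[P] -= std::min(m, 0.0) * u[P];      // guard against weak backflow
      bv[P] -= std::min(m, 0.0) * v[P];
    }
    // wall: no-slip, one-sided quadratic normal-gradient viscous flux
    for (int i = 0; i < ni; ++i) {
      int P1 = id(i, nj - 1), P2 = id(i, nj - 2);
      // wall tangent (along +x): t = (n_r, -n_x)
      double ut1 = u[P1] * wNr[i] - v[P1] * wNx[i];
      double ut2 = u[P2] * wNr[i] - v[P2] * wNx[i];
      double gw = std::abs((wD2[i] * wD2[i] * ut1 - wD1[i] * wD1[i] * ut2) /
                           (wD1[i] * wD2[i] * (wD2[i] - wD1[i])));
      double muw = viscfun(rheo_kind, rp, gw);
      double c1 = muw * wS[i] * wC1[i];
      double c2 = muw * wS[i] * (-wC2[i]);   // positive coupling to P2
      aP[P1] += c1;
      aS[P1] += c2;
      // transpose stress at the wall face (gradients lagged)
      double su = muw * (gux[P1] * nSx[fn(i, nj)] + gvx[P1] * nSr[fn(i, nj)]);
      double sv = muw * (gur[P1] * nSx[fn(i, nj)] + gvr[P1] * nSr[fn(i, nj)]);
      bu[P1] += su; bv[P1] += sv;
    }

    // hoop viscous term, pressure force, pseudo-transient
    for (int c = 0; c < nc; ++c) {
      double hoop = 2.0 * mu[c] * vol[c] / (rc[c] * rc[c]);
      aPu[c] = aP[c];
      aPv[c] = aP[c] + hoop;
      if (pseudo_dt > 0.0) {
        double at = rho * vol[c] / pseudo_dt;
        aPu[c] += at; aPv[c] += at;
        bu[c] += at * u[c]; bv[c] += at * v[c];
      }
      bu[c] -= gpx[c] * vol[c];
      bv[c] -= gpr[c] * vol[c];
    }

    // unrelaxed momentum residuals
    double res_u = 0.0, res_v = 0.0;
    for (int j = 0; j < nj; ++j)
      for (int i = 0; i < ni; ++i) {
        int c = id(i, j);
        double su = bu[c] - aPu[c] * u[c], sv = bv[c] - aPv[c] * v[c];
        if (i > 0)      { su += aW[c] * u[id(i - 1, j)]; sv += aW[c] * v[id(i - 1, j)]; }
        if (i < ni - 1) { su += aE[c] * u[id(i + 1, j)]; sv += aE[c] * v[id(i + 1, j)]; }
        if (j > 0)      { su += aS[c] * u[id(i, j - 1)]; sv += aS[c] * v[id(i, j - 1)]; }
        if (j < nj - 1) { su += aN[c] * u[id(i, j + 1)]; sv += aN[c] * v[id(i, j + 1)]; }
        res_u += std::abs(su); res_v += std::abs(sv);
      }
    res_u /= mom_ref; res_v /= mom_ref;

    // implicit under-relaxation
    for (int c = 0; c < nc; ++c) {
      double au0 = aPu[c], av0 = aPv[c];
      aPu[c] = au0 / relax_u;
      aPv[c] = av0 / relax_u;
      bu[c] += (1.0 - relax_u) / relax_u * au0 * u[c];
      bv[c] += (1.0 - relax_u) / relax_u * av0 * v[c];
      dcell[c] = 0.5 * (vol[c] / aPu[c] + vol[c] / aPv[c]);
    }

    // momentum smoothing sweeps
    for (int s = 0; s < mom_sweeps; ++s) {
      bool fwd = (s % 2 == 0);
      sweep_jlines(u, aPu, bu, fwd);
      sweep_ilines(u, aPu, bu, fwd);
      sweep_jlines(v, aPv, bv, fwd);
      sweep_ilines(v, aPv, bv, fwd);
    }

    // ---- Rhie-Chow face fluxes ----
    for (int ie = 1; ie < ni; ++ie)
      for (int j = 0; j < nj; ++j) {
        int f = fe(ie, j), P = id(ie - 1, j), N = id(ie, j);
        double lam = eLam[f];
        double uf = lam * u[P] + (1 - lam) * u[N];
        double df = lam * dcell[P] + (1 - lam) * dcell[N];
        double gpf_d = (lam * gpx[P] + (1 - lam) * gpx[N]) * eDx[f] +
                       (lam * gpr[P] + (1 - lam) * gpr[N]) * eDr[f];
        peC[f] = rho * df * eEf[f];
        me[f] = rho * uf * eA[f] - peC[f] * ((p[N] - p[P]) - gpf_d);
      }
    for (int i = 0; i < ni; ++i)
      for (int jn = 1; jn < nj; ++jn) {
        int f = fn(i, jn), P = id(i, jn - 1), N = id(i, jn);
        double lam = nLam[f];
        double uf = lam * u[P] + (1 - lam) * u[N];
        double vf = lam * v[P] + (1 - lam) * v[N];
        double df = lam * dcell[P] + (1 - lam) * dcell[N];
        double gpf_d = (lam * gpx[P] + (1 - lam) * gpx[N]) * nDx[f] +
                       (lam * gpr[P] + (1 - lam) * gpr[N]) * nDr[f];
        pnC[f] = rho * df * nEf[f];
        mn[f] = rho * (uf * nSx[f] + vf * nSr[f]) - pnC[f] * ((p[N] - p[P]) - gpf_d);
      }
    // outlet flux: zero-gradient, scaled for exact global mass conservation
    {
      double s = 0.0;
      for (int j = 0; j < nj; ++j) s += rho * u[id(ni - 1, j)] * eA[fe(ni, j)];
      if (s > 0.1 * rho * Q) {
        double sc = rho * Q / s;
        for (int j = 0; j < nj; ++j)
          me[fe(ni, j)] = sc * rho * u[id(ni - 1, j)] * eA[fe(ni, j)];
      } else {
        double at = 0.0;
        for (int j = 0; j < nj; ++j) at += eA[fe(ni, j)];
        for (int j = 0; j < nj; ++j) me[fe(ni, j)] = rho * Q * eA[fe(ni, j)] / at;
      }
    }

    // mass imbalance
    double res_m = 0.0;
    for (int j = 0; j < nj; ++j)
      for (int i = 0; i < ni; ++i) {
        double div = me[fe(i + 1, j)] - me[fe(i, j)] + mn[fn(i, j + 1)] - mn[fn(i, j)];
        prhs[id(i, j)] = -div;
        res_m += std::abs(div);
      }
    res_m /= (rho * Q);

    hist.push_back(res_m); hist.push_back(res_u); hist.push_back(res_v);
    it_done = it;
    if (!std::isfinite(res_m) || !std::isfinite(res_u) || !std::isfinite(res_v)) {
      breakdown = true; break;
    }
    if (verbose && (it % verbose == 0))
      Rcpp::Rcout << "iter " << it << "  mass " << res_m
                  << "  u " << res_u << "  v " << res_v << std::endl;
    if (it >= min_iter && (scheme == 0 || it > fou_iters + 20) &&
        res_m < tol_mass && res_u < tol_mom && res_v < tol_mom) {
      converged = true; break;
    }

    // ---- pressure correction: IC(0)-CG ----
    for (int j = 0; j < nj; ++j)
      for (int i = 0; i < ni; ++i) {
        int c = id(i, j);
        double d = 0.0;
        if (i > 0)      d += peC[fe(i, j)];
        if (i < ni - 1) d += peC[fe(i + 1, j)];
        if (j > 0)      d += pnC[fn(i, j)];
        if (j < nj - 1) d += pnC[fn(i, j + 1)];
        pdiag[c] = d;
      }
    pdiag[id(ni - 1, 0)] *= 1.0e8;           // pin the reference cell
    // IC(0) factorization (exists for symmetric M-matrices)
    for (int j = 0; j < nj; ++j)
      for (int i = 0; i < ni; ++i) {
        int c = id(i, j);
        double lwv = 0.0, lsv = 0.0;
        if (i > 0) lwv = -peC[fe(i, j)] / ld[c - 1];
        if (j > 0) lsv = -pnC[fn(i, j)] / ld[c - ni];
        double s = pdiag[c] - lwv * lwv - lsv * lsv;
        if (s <= 0.0) s = pdiag[c];
        ld[c] = std::sqrt(s);
        lw[c] = lwv; ls[c] = lsv;
      }
    auto precond = [&](const std::vector<double>& r, std::vector<double>& z) {
      for (int j = 0; j < nj; ++j)
        for (int i = 0; i < ni; ++i) {
          int c = id(i, j);
          double s = r[c];
          if (i > 0) s -= lw[c] * cg_q[c - 1];
          if (j > 0) s -= ls[c] * cg_q[c - ni];
          cg_q[c] = s / ld[c];
        }
      for (int j = nj - 1; j >= 0; --j)
        for (int i = ni - 1; i >= 0; --i) {
          int c = id(i, j);
          double s = cg_q[c];
          if (i < ni - 1) s -= lw[c + 1] * z[c + 1];
          if (j < nj - 1) s -= ls[c + ni] * z[c + ni];
          z[c] = s / ld[c];
        }
    };
    auto amul = [&](const std::vector<double>& x, std::vector<double>& y) {
      for (int j = 0; j < nj; ++j)
        for (int i = 0; i < ni; ++i) {
          int c = id(i, j);
          double s = pdiag[c] * x[c];
          if (i > 0)      s -= peC[fe(i, j)]     * x[c - 1];
          if (i < ni - 1) s -= peC[fe(i + 1, j)] * x[c + 1];
          if (j > 0)      s -= pnC[fn(i, j)]     * x[c - ni];
          if (j < nj - 1) s -= pnC[fn(i, j + 1)] * x[c + ni];
          y[c] = s;
        }
    };
    std::fill(pc.begin(), pc.end(), 0.0);
    double bn = 0.0;
    for (int c = 0; c < nc; ++c) { cg_r[c] = prhs[c]; bn += prhs[c] * prhs[c]; }
    bn = std::sqrt(bn);
    if (bn > 0.0) {
      precond(cg_r, cg_z);
      double rz = 0.0;
      for (int c = 0; c < nc; ++c) { cg_p[c] = cg_z[c]; rz += cg_r[c] * cg_z[c]; }
      for (int k = 0; k < lin_iter_p; ++k) {
        amul(cg_p, cg_q);
        double pq = 0.0;
        for (int c = 0; c < nc; ++c) pq += cg_p[c] * cg_q[c];
        double alpha = rz / pq;
        double rn = 0.0;
        for (int c = 0; c < nc; ++c) {
          pc[c]  += alpha * cg_p[c];
          cg_r[c] -= alpha * cg_q[c];
          rn += cg_r[c] * cg_r[c];
        }
        if (std::sqrt(rn) < lin_tol_p * bn) break;
        precond(cg_r, cg_z);
        double rz1 = 0.0;
        for (int c = 0; c < nc; ++c) rz1 += cg_r[c] * cg_z[c];
        double beta = rz1 / rz;
        rz = rz1;
        for (int c = 0; c < nc; ++c) cg_p[c] = cg_z[c] + beta * cg_p[c];
      }
    }

    // corrections
    gradient(pc, gcx, gcr, 2, nullptr);
    for (int c = 0; c < nc; ++c) {
      u[c] -= vol[c] / aPu[c] * gcx[c];
      v[c] -= vol[c] / aPv[c] * gcr[c];
      p[c] += relax_p * pc[c];
    }
    for (int ie = 1; ie < ni; ++ie)
      for (int j = 0; j < nj; ++j) {
        int f = fe(ie, j);
        me[f] -= peC[f] * (pc[id(ie, j)] - pc[id(ie - 1, j)]);
      }
    for (int i = 0; i < ni; ++i)
      for (int jn = 1; jn < nj; ++jn) {
        int f = fn(i, jn);
        mn[f] -= pnC[f] * (pc[id(i, jn)] - pc[id(i, jn - 1)]);
      }
  }

  // final consistent shear-rate / viscosity evaluation
  gradient(u, gux, gur, 0, &u_in);
  gradient(v, gvx, gvr, 0, nullptr);
  for (int c = 0; c < nc; ++c) {
    double Dxx = gux[c], Drr = gvr[c], Dtt = v[c] / rc[c];
    double Dxr = 0.5 * (gur[c] + gvx[c]);
    gam[c] = std::sqrt(2.0 * (Dxx * Dxx + Drr * Drr + Dtt * Dtt) + 4.0 * Dxr * Dxr);
    mu[c] = viscfun(rheo_kind, rp, gam[c]);
  }

  // outputs
  NumericMatrix U(ni, nj), V(ni, nj), P(ni, nj), MU(ni, nj), GAM(ni, nj);
  for (int j = 0; j < nj; ++j)
    for (int i = 0; i < ni; ++i) {
      U(i, j) = u[id(i, j)]; V(i, j) = v[id(i, j)]; P(i, j) = p[id(i, j)];
      MU(i, j) = mu[id(i, j)]; GAM(i, j) = gam[id(i, j)];
    }
  NumericVector Qx(ni + 1);
  for (int ie = 0; ie <= ni; ++ie) {
    double s = 0.0;
    for (int j = 0; j < nj; ++j) s += me[fe(ie, j)];
    Qx[ie] = s / rho;
  }
  int nh = it_done;
  NumericMatrix H(nh, 3);
  for (int k = 0; k < nh; ++k) {
    H(k, 0) = hist[3 * k]; H(k, 1) = hist[3 * k + 1]; H(k, 2) = hist[3 * k + 2];
  }
  colnames(H) = CharacterVector::create("mass", "u_mom", "v_mom");

  return List::create(_["u"] = U, _["v"] = V, _["p"] = P, _["mu_eff"] = MU,
                      _["gamma_dot"] = GAM, _["flux_x"] = Qx,
                      _["residuals"] = H, _["converged"] = converged,
                      _["breakdown"] = breakdown, _["iterations"] = it_done,
                      _["u_inlet"] = NumericVector(u_in.begin(), u_in.end()));
}
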