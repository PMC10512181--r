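// TriSeg wall mechanics core: spherical-cap kinematics, fiber stress,
// tension balance at the shared junction, and the closed-loop circulation
// right-hand side.  Wall order throughout: 0 = LW, 1 = SW, 2 = RW.
//
// Kinematic and tension relations follow the three-segment (TriSeg)
// formulation: each wall is a spherical cap attached to a common junction
// circle of radius ym, with axial midwall displacement xm.  The four
// unknowns (xm_LW, xm_SW, xm_RW, ym) are solved at every evaluation by a
// damped Newton iteration on [sum Tx, sum Ty, LV volume, RV volume].

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double KPA_PER_MMHG = 0.133322;

struct HeartPars {
  double Vw[3], Amref[3], kpas[3], kact[3];
  double Lref, Lc0, Lse, vmax, gam;
  double peri_s, peri_Vh0;
  bool use_peri;
};

struct WallState {
  double xm, Am, Cm, Vm, z, eps, Ls, sigp, siga, sig, Tm, Tx, Ty, sinA, cosA;
};

static HeartPars parse_heart(const List& heart) {
  HeartPars hp;
  NumericVector Vw = heart["Vw"], Amref = heart["Am_ref"],
                kpas = heart["kpas"], kact = heart["kact"];
  for (int i = 0; i < 3; ++i) {
    hp.Vw[i] = Vw[i]; hp.Amref[i] = Amref[i];
    hp.kpas[i] = kpas[i]; hp.kact[i] = kact[i];
  }
  hp.Lref = as<double>(heart["L_ref"]);
  hp.Lc0  = as<double>(heart["L_c0"]);
  hp.Lse  = as<double>(heart["L_se_iso"]);
  hp.vmax = as<double>(heart["v_max"]);
  hp.gam  = as<double>(heart["gamma"]);
  hp.peri_s   = as<double>(heart["peri_s"]);
  hp.peri_Vh0 = as<double>(heart["peri_Vh0"]);
  hp.use_peri = as<bool>(heart["use_pericardium"]);
  return hp;
}

// lc_mode: 0 = contractile lengths given in Lc[],
//          1 = isometric quasi-steady Lc = Ls - Lse,iso (calibration use)
static void wall_config(const HeartPars& hp, const double u[4],
                        const double Lc[3], int lc_mode, double Y,
                        WallState ws[3]) {
  const double ym = u[3];
  for (int i = 0; i < 3; ++i) {
    const double xm = u[i];
    const double d  = xm * xm + ym * ym;
    const double Am = M_PI * d;
    const double Cm = 2.0 * xm / d;
    const double Vm = (M_PI / 6.0) * xm * (xm * xm + 3.0 * ym * ym);
    const double z  = 3.0 * Cm * hp.Vw[i] / (2.0 * Am);
    const double z2 = z * z;
    const double eps = 0.5 * std::log(Am / hp.Amref[i]) - z2 / 12.0 -
                       0.019 * z2 * z2;
    const double Ls = hp.Lref * std::exp(eps);
    const double lc = (lc_mode == 1) ? (Ls - hp.Lse) : Lc[i];
    const double dl = Ls - hp.Lc0;
    const double sigp = (dl > 0.0) ? std::pow(dl, hp.gam) : 0.0;
    const double siga = std::max(lc - hp.Lc0, 0.0) * ((Ls - lc) / hp.Lse) * Y;
    const double sig  = hp.kpas[i] * sigp + hp.kact[i] * siga;
    const double Tm   = sig * hp.Vw[i] / (2.0 * Am) *
                        (1.0 + z2 / 3.0 + z2 * z2 / 5.0);
    const double sinA = 2.0 * xm * ym / d;
    const double cosA = (ym * ym - xm * xm) / d;
    ws[i].xm = xm;  ws[i].Am = Am;  ws[i].Cm = Cm;  ws[i].Vm = Vm;
    ws[i].z = z;    ws[i].eps = eps; ws[i].Ls = Ls;
    ws[i].sigp = sigp; ws[i].siga = siga; ws[i].sig = sig;
    ws[i].Tm = Tm;  ws[i].Tx = Tm * sinA; ws[i].Ty = Tm * cosA;
    ws[i].sinA = sinA; ws[i].cosA = cosA;
  }
}

static void residuals(const HeartPars& hp, const double u[4],
                      double VLV, double VRV, const double Lc[3],
                      int lc_mode, double Y, double r[4], WallState ws[3]) {
  wall_config(hp, u, Lc, lc_mode, Y, ws);
  r[0] = ws[0].Tx + ws[1].Tx + ws[2].Tx;
  r[1] = ws[0].Ty + ws[1].Ty + ws[2].Ty;
  r[2] = (-ws[0].Vm + ws[1].Vm) - (VLV + 0.5 * hp.Vw[0] + 0.5 * hp.Vw[1]);
  r[3] = ( ws[2].Vm - ws[1].Vm) - (VRV + 0.5 * hp.Vw[1] + 0.5 * hp.Vw[2]);
}

static double scaled_norm(const double r[4], const WallState ws[3],
                          double vol_scale) {
  double Tsc = std::fabs(ws[0].Tm) + std::fabs(ws[1].Tm) + std::fabs(ws[2].Tm);
  if (Tsc < 1e-8) Tsc = 1e-8;
  double nT = std::max(std::fabs(r[0]), std::fabs(r[1])) / Tsc;
  double nV = std::max(std::fabs(r[2]), std::fabs(r[3])) / vol_scale;
  return std::max(nT, nV);
}

// solve 4x4 linear system in place; returns false if singular
static bool solve4(double A[4][4], double b[4]) {
  int piv[4] = {0, 1, 2, 3};
  for (int k = 0; k < 4; ++k) {
    int imax = k; double amax = std::fabs(A[k][k]);
    for (int i = k + 1; i < 4; ++i)
      if (std::fabs(A[i][k]) > amax) { amax = std::fabs(A[i][k]); imax = i; }
    if (amax < 1e-300) return false;
    if (imax != k) {
      for (int j = 0; j < 4; ++j) std::swap(A[k][j], A[imax][j]);
      std::swap(b[k], b[imax]); std::swap(piv[k], piv[imax]);
    }
    for (int i = k + 1; i < 4; ++i) {
      double f = A[i][k] / A[k][k];
      for (int j = k; j < 4; ++j) A[i][j] -= f * A[k][j];
      b[i] -= f * b[k];
    }
  }
  for (int i = 3; i >= 0; --i) {
    double s = b[i];
    for (int j = i + 1; j < 4; ++j) s -= A[i][j] * b[j];
    b[i] = s / A[i][i];
  }
  return true;
}

// monotone cubic solve: (pi/6) x (x^2 + 3 ym^2) = Vm
static double solve_cap_x(double Vm, double ym) {
  double x = Vm / ((M_PI / 6.0) * 3.0 * ym * ym);
  for (int it = 0; it < 60; ++it) {
    double f  = (M_PI / 6.0) * x * (x * x + 3.0 * ym * ym) - Vm;
    double df = (M_PI / 6.0) * (3.0 * x * x + 3.0 * ym * ym);
    double dx = f / df;
    x -= dx;
    if (std::fabs(dx) < 1e-13 * (1.0 + std::fabs(x))) break;
  }
  return x;
}

// volume-consistent geometric initial guess
static void geometric_guess(const HeartPars& hp, double VLV, double VRV,
                            double u[4]) {
  double Vl = VLV + 0.5 * (hp.Vw[0] + hp.Vw[1]);
  double Vr = VRV + 0.5 * (hp.Vw[1] + hp.Vw[2]);
  double rm = std::cbrt(3.0 * Vl / (4.0 * M_PI));
  double ym = 0.92 * rm;
  double VmSW = 0.15 * Vl;
  u[3] = ym;
  u[0] = solve_cap_x(VmSW - Vl, ym);
  u[1] = solve_cap_x(VmSW, ym);
  u[2] = solve_cap_x(VmSW + Vr, ym);
}

static bool newton_solve(const HeartPars& hp, double VLV, double VRV,
                         const double Lc[3], int lc_mode, double Y,
                         double u[4], double tol, int maxit,
                         int& iters, double& final_norm, WallState ws[3]) {
  double r[4];
  const double vol_scale = VLV + VRV + hp.Vw[0] + hp.Vw[1] + hp.Vw[2];
  residuals(hp, u, VLV, VRV, Lc, lc_mode, Y, r, ws);
  double nrm = scaled_norm(r, ws, vol_scale);
  iters = 0;
  for (int it = 0; it < maxit; ++it) {
    if (nrm < tol) { final_norm = nrm; return true; }
    // forward-difference Jacobian
    double J[4][4], rp[4];
    WallState wtmp[3];
    for (int j = 0; j < 4; ++j) {
      double h = 1e-7 * std::max(std::fabs(u[j]), 1e-2);
      double usave = u[j];
      u[j] = usave + h;
      residuals(hp, u, VLV, VRV, Lc, lc_mode, Y, rp, wtmp);
      u[j] = usave;
      for (int i = 0; i < 4; ++i) J[i][j] = (rp[i] - r[i]) / h;
    }
    double step[4] = {r[0], r[1], r[2], r[3]};
    if (!solve4(J, step)) return false;
    // damped update, keep ym positive
    double lambda = 1.0;
    double unew[4];
    for (int bt = 0; bt < 12; ++bt) {
      for (int i = 0; i < 4; ++i) unew[i] = u[i] - lambda * step[i];
      if (unew[3] <= 1e-4) { lambda *= 0.5; continue; }
      residuals(hp, unew, VLV, VRV, Lc, lc_mode, Y, rp, wtmp);
      double nnew = scaled_norm(rp, wtmp, vol_scale);
      if (nnew < nrm || nnew < tol) {
        for (int i = 0; i < 4; ++i) { u[i] = unew[i]; r[i] = rp[i]; }
        for (int i = 0; i < 3; ++i) ws[i] = wtmp[i];
        nrm = nnew;
        break;
      }
      lambda *= 0.5;
      if (bt == 11) {  // accept anyway to escape flat regions
        for (int i = 0; i < 4; ++i) { u[i] = unew[i]; r[i] = rp[i]; }
        for (int i = 0; i < 3; ++i) ws[i] = wtmp[i];
        nrm = nnew;
      }
    }
    ++iters;
  }
  final_norm = nrm;
  return nrm < tol;
}

// Reduced 2-unknown solve: unknowns (Vm_SW, ym); the cap volumes of LW and
// RW follow exactly from the chamber-volume constraints, and each xm is
// recovered from its cap volume by inverting the monotone cubic.  Only the
// two tension residuals remain.  More robust than the full 4-variable
// Newton at extreme stiffness; identical solution.
static bool newton_solve_reduced(const HeartPars& hp, double VLV, double VRV,
                                 const double Lc[3], int lc_mode, double Y,
                                 double u[4], double tol, int maxit,
                                 WallState ws[3]) {
  const double volL = VLV + 0.5 * (hp.Vw[0] + hp.Vw[1]);
  const double volR = VRV + 0.5 * (hp.Vw[1] + hp.Vw[2]);
  double v[2];  // Vm_SW, ym
  v[0] = (M_PI / 6.0) * u[1] * (u[1] * u[1] + 3.0 * u[3] * u[3]);
  v[1] = u[3];
  const double vol_scale = VLV + VRV + hp.Vw[0] + hp.Vw[1] + hp.Vw[2];

  double r[2];
  WallState wtmp[3];
  double uu[4];
  double Tsc = 0.0;
  // residual of the reduced system
  struct Eval {
    const HeartPars& hp; double volL, volR; const double* Lc; int lc_mode;
    double Y;
    bool operator()(const double v[2], double r[2], double uu[4],
                    WallState ws[3], double& Tsc) const {
      double ym = v[1];
      if (ym <= 1e-4) return false;
      uu[3] = ym;
      uu[0] = solve_cap_x(v[0] - volL, ym);
      uu[1] = solve_cap_x(v[0], ym);
      uu[2] = solve_cap_x(v[0] + volR, ym);
      wall_config(hp, uu, Lc, lc_mode, Y, ws);
      r[0] = ws[0].Tx + ws[1].Tx + ws[2].Tx;
      r[1] = ws[0].Ty + ws[1].Ty + ws[2].Ty;
      Tsc = std::fabs(ws[0].Tm) + std::fabs(ws[1].Tm) + std::fabs(ws[2].Tm);
      if (Tsc < 1e-8) Tsc = 1e-8;
      return true;
    }
  } eval{hp, volL, volR, Lc, lc_mode, Y};

  if (!eval(v, r, uu, ws, Tsc)) return false;
  double nrm = std::max(std::fabs(r[0]), std::fabs(r[1])) / Tsc;
  for (int it = 0; it < maxit; ++it) {
    if (nrm < tol) {
      for (int i = 0; i < 4; ++i) u[i] = uu[i];
      return true;
    }
    double J[2][2], rp[2];
    double hsteps[2] = {1e-7 * std::max(std::fabs(v[0]), vol_scale * 1e-3),
                        1e-7 * std::max(std::fabs(v[1]), 1e-2)};
    for (int j = 0; j < 2; ++j) {
      double vs = v[j];
      double vpert[2] = {v[0], v[1]};
      vpert[j] = vs + hsteps[j];
      double up[4]; WallState wp[3]; double Ts2;
      if (!eval(vpert, rp, up, wp, Ts2)) return false;
      J[0][j] = (rp[0] - r[0]) / hsteps[j];
      J[1][j] = (rp[1] - r[1]) / hsteps[j];
    }
    double det = J[0][0] * J[1][1] - J[0][1] * J[1][0];
    if (std::fabs(det) < 1e-300) return false;
    double s0 = ( J[1][1] * r[0] - J[0][1] * r[1]) / det;
    double s1 = (-J[1][0] * r[0] + J[0][0] * r[1]) / det;
    double lambda = 1.0;
    for (int bt = 0; bt < 16; ++bt) {
      double vn[2] = {v[0] - lambda * s0, v[1] - lambda * s1};
      double un[4]; WallState wn[3]; double Tsn;
      if (vn[1] > 1e-4 && eval(vn, rp, un, wn, Tsn)) {
        double nnew = std::max(std::fabs(rp[0]), std::fabs(rp[1])) / Tsn;
        if (nnew < nrm || nnew < tol || bt == 15) {
          v[0] = vn[0]; v[1] = vn[1];
          r[0] = rp[0]; r[1] = rp[1];
          for (int i = 0; i < 4; ++i) uu[i] = un[i];
          for (int i = 0; i < 3; ++i) ws[i] = wn[i];
          nrm = nnew;
          break;
        }
      }
      lambda *= 0.5;
    }
  }
  if (nrm < tol) {
    for (int i = 0; i < 4; ++i) u[i] = uu[i];
    return true;
  }
  return false;
}

// full fallback chain: warm-started 4-var Newton, geometric restart, then
// the reduced 2-var solve from both starting points
static bool solve_with_fallback(const HeartPars& hp, double VLV, double VRV,
                                const double Lc[3], int lc_mode, double Y,
                                double u[4], double tol, int maxit,
                                int& iters, double& nrm, WallState ws[3]) {
  double u0[4] = {u[0], u[1], u[2], u[3]};
  if (newton_solve(hp, VLV, VRV, Lc, lc_mode, Y, u, tol, maxit, iters, nrm,
                   ws))
    return true;
  for (int i = 0; i < 4; ++i) u[i] = u0[i];
  const double vol_scale = VLV + VRV + hp.Vw[0] + hp.Vw[1] + hp.Vw[2];
  double r[4];
  if (newton_solve_reduced(hp, VLV, VRV, Lc, lc_mode, Y, u, tol, 100, ws)) {
    residuals(hp, u, VLV, VRV, Lc, lc_mode, Y, r, ws);
    nrm = scaled_norm(r, ws, vol_scale);
    return true;
  }
  geometric_guess(hp, VLV, VRV, u);
  if (newton_solve(hp, VLV, VRV, Lc, lc_mode, Y, u, tol, maxit, iters, nrm,
                   ws))
    return true;
  geometric_guess(hp, VLV, VRV, u);
  if (newton_solve_reduced(hp, VLV, VRV, Lc, lc_mode, Y, u, tol, 200, ws)) {
    residuals(hp, u, VLV, VRV, Lc, lc_mode, Y, r, ws);
    nrm = scaled_norm(r, ws, vol_scale);
    return true;
  }
  // perturbed geometric restarts (junction radius scaled)
  for (double f = 0.75; f <= 1.3; f += 0.25) {
    geometric_guess(hp, VLV, VRV, u);
    u[3] *= f;
    if (newton_solve_reduced(hp, VLV, VRV, Lc, lc_mode, Y, u, tol, 200,
                             ws)) {
      residuals(hp, u, VLV, VRV, Lc, lc_mode, Y, r, ws);
      nrm = scaled_norm(r, ws, vol_scale);
      return true;
    }
  }
  // stress-continuation homotopy: ramp the wall scaling factors up from a
  // soft configuration, warm-starting each stage
  {
    HeartPars soft = hp;
    geometric_guess(hp, VLV, VRV, u);
    bool ok = true;
    const double lams[4] = {0.1, 0.3, 0.6, 1.0};
    for (int s = 0; s < 4 && ok; ++s) {
      for (int i = 0; i < 3; ++i) {
        soft.kpas[i] = hp.kpas[i] * lams[s];
        soft.kact[i] = hp.kact[i] * lams[s];
      }
      ok = newton_solve_reduced(soft, VLV, VRV, Lc, lc_mode, Y, u, tol,
                                200, ws);
    }
    if (ok) {
      residuals(hp, u, VLV, VRV, Lc, lc_mode, Y, r, ws);
      nrm = scaled_norm(r, ws, vol_scale);
      if (nrm < tol) return true;
      if (newton_solve(hp, VLV, VRV, Lc, lc_mode, Y, u, tol, maxit, iters,
                       nrm, ws))
        return true;
    }
  }
  return false;
}

static double pericardial(const HeartPars& hp, double VLV, double VRV) {
  if (!hp.use_peri) return 0.0;
  double Vh = VLV + VRV;
  return std::exp(hp.peri_s * (Vh / hp.peri_Vh0 - 1.0)) - 1.0;
}

static List config_as_list(const HeartPars& hp, const double u[4],
                           const WallState ws[3], double VLV, double VRV,
                           bool converged, int iters, double resnorm) {
  const double ym = u[3];
  NumericVector xm(3), Am(3), Cm(3), Vm(3), z(3), Ls(3), sigp(3), siga(3),
      sig(3), Tm(3), Tx(3), Ty(3);
  for (int i = 0; i < 3; ++i) {
    xm[i] = ws[i].xm; Am[i] = ws[i].Am; Cm[i] = ws[i].Cm; Vm[i] = ws[i].Vm;
    z[i] = ws[i].z; Ls[i] = ws[i].Ls; sigp[i] = ws[i].sigp;
    siga[i] = ws[i].siga; sig[i] = ws[i].sig;
    Tm[i] = ws[i].Tm; Tx[i] = ws[i].Tx; Ty[i] = ws[i].Ty;
  }
  CharacterVector wn = CharacterVector::create("LW", "SW", "RW");
  xm.names() = wn; Am.names() = wn; Cm.names() = wn; Vm.names() = wn;
  z.names() = wn; Ls.names() = wn; sig.names() = wn; Tm.names() = wn;
  Tx.names() = wn; Ty.names() = wn; sigp.names() = wn; siga.names() = wn;
  double P_peri = pericardial(hp, VLV, VRV);
  double P_LV_tm = -2.0 * ws[0].Tx / ym / KPA_PER_MMHG;
  double P_RV_tm =  2.0 * ws[2].Tx / ym / KPA_PER_MMHG;
  return List::create(
      _["u"] = NumericVector::create(u[0], u[1], u[2], u[3]),
      _["xm"] = xm, _["ym"] = ym, _["Am"] = Am, _["Cm"] = Cm, _["Vm"] = Vm,
      _["z"] = z, _["Ls"] = Ls, _["sig_pas"] = sigp, _["sig_act"] = siga,
      _["sigma"] = sig, _["Tm"] = Tm, _["Tx"] = Tx, _["Ty"] = Ty,
      _["P_LV_trans"] = P_LV_tm, _["P_RV_trans"] = P_RV_tm,
      _["P_peri"] = P_peri,
      _["P_LV"] = P_LV_tm + P_peri, _["P_RV"] = P_RV_tm + P_peri,
      _["V_LV"] = VLV, _["V_RV"] = VRV,
      _["converged"] = converged, _["iterations"] = iters,
      _["residual_norm"] = resnorm);
}

// [[Rcpp::export]]
NumericVector ts_guess_cpp(double VLV, double VRV, List heart) {
  HeartPars hp = parse_heart(heart);
  double u[4];
  geometric_guess(hp, VLV, VRV, u);
  return NumericVector::create(u[0], u[1], u[2], u[3]);
}

// [[Rcpp::export]]
List ts_solve_cpp(double VLV, double VRV, NumericVector Lc, double Y,
                  List heart, NumericVector guess, int lc_mode = 0,
                  double tol = 1e-9, int maxit = 50) {
  HeartPars hp = parse_heart(heart);
  double u[4], lc[3] = {Lc[0], Lc[1], Lc[2]};
  for (int i = 0; i < 4; ++i) u[i] = guess[i];
  WallState ws[3];
  int iters; double nrm;
  bool ok = solve_with_fallback(hp, VLV, VRV, lc, lc_mode, Y, u, tol,
                                maxit, iters, nrm, ws);
  return config_as_list(hp, u, ws, VLV, VRV, ok, iters, nrm);
}

// [[Rcpp::export]]
NumericVector ts_residual_cpp(NumericVector u_in, double VLV, double VRV,
                              NumericVector Lc, double Y, List heart,
                              int lc_mode = 0) {
  HeartPars hp = parse_heart(heart);
  double u[4] = {u_in[0], u_in[1], u_in[2], u_in[3]};
  double lc[3] = {Lc[0], Lc[1], Lc[2]};
  double r[4]; WallState ws[3];
  residuals(hp, u, VLV, VRV, lc, lc_mode, Y, r, ws);
  return NumericVector::create(_["Tx"] = r[0], _["Ty"] = r[1],
                               _["V_LV"] = r[2], _["V_RV"] = r[3]);
}

// time reduced to the current cycle, [0, Tcyc)
static double cycle_time(double t, double Tcyc) {
  return t - std::floor(t / Tcyc) * Tcyc;
}

// Activation waveform: rising half-cosine over [0, TS], falling half-cosine
// over [TS, TS+TR], zero for the rest of the cycle.
static double activation_fun(double t, double TS, double TR) {
  if (t < 0.0) return 0.0;
  if (t <= TS) return 0.5 * (1.0 - std::cos(M_PI * t / TS));
  if (t <= TS + TR) return 0.5 * (1.0 + std::cos(M_PI * (t - TS) / TR));
  return 0.0;
}

// [[Rcpp::export]]
NumericVector ts_activation_cpp(NumericVector t, double TS, double TR,
                                double Tcyc) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = activation_fun(cycle_time(t[i], Tcyc), TS, TR);
  return out;
}

// Closed-loop RHS.  State y = (V_LV, V_SA, V_SV, V_RV, V_PA, V_PV,
// Lc_LW, Lc_SW, Lc_RW).  circ holds compliances/resistances/unstressed
// volumes and the activation timing.
// [[Rcpp::export]]
List ts_rhs_cpp(double t, NumericVector y, List heart, List circ,
                NumericVector guess, double tol = 1e-9, int maxit = 50) {
  HeartPars hp = parse_heart(heart);
  double C_SA = as<double>(circ["C_SA"]), C_SV = as<double>(circ["C_SV"]);
  double C_PA = as<double>(circ["C_PA"]), C_PV = as<double>(circ["C_PV"]);
  double Vu_SA = as<double>(circ["Vu_SA"]), Vu_SV = as<double>(circ["Vu_SV"]);
  double Vu_PA = as<double>(circ["Vu_PA"]), Vu_PV = as<double>(circ["Vu_PV"]);
  double R_sys = as<double>(circ["R_sys"]), R_pul = as<double>(circ["R_pul"]);
  double Rt_SA = as<double>(circ["Rt_SA"]), Rt_PA = as<double>(circ["Rt_PA"]);
  double Rm = as<double>(circ["R_mv"]), Rtc = as<double>(circ["R_tv"]);
  double Tcyc = as<double>(circ["T"]);
  double TS = as<double>(circ["T_S"]), TR = as<double>(circ["T_R"]);

  double VLV = y[0], VSA = y[1], VSV = y[2], VRV = y[3], VPA = y[4],
         VPV = y[5];
  double lc[3] = {y[6], y[7], y[8]};
  double Y = activation_fun(cycle_time(t, Tcyc), TS, TR);

  double u[4] = {guess[0], guess[1], guess[2], guess[3]};
  WallState ws[3];
  int iters; double nrm;
  bool ok = solve_with_fallback(hp, VLV, VRV, lc, 0, Y, u, tol, maxit,
                                iters, nrm, ws);
  if (!ok)
    stop("TriSeg wall solve failed at t=%g (residual %g)", t, nrm);

  double P_peri = pericardial(hp, VLV, VRV);
  double P_LV = -2.0 * ws[0].Tx / u[3] / KPA_PER_MMHG + P_peri;
  double P_RV =  2.0 * ws[2].Tx / u[3] / KPA_PER_MMHG + P_peri;

  double P_SA_el = (VSA - Vu_SA) / C_SA;
  double P_SV    = (VSV - Vu_SV) / C_SV;
  double P_PA_el = (VPA - Vu_PA) / C_PA;
  double P_PV    = (VPV - Vu_PV) / C_PV;

  double q_m  = std::max(P_PV - P_LV, 0.0) / Rm;     // mitral
  double q_a  = std::max(P_LV - P_SA_el, 0.0) / Rt_SA;  // aortic ejection
  double q_sys = (P_SA_el - P_SV) / R_sys;
  double q_t  = std::max(P_SV - P_RV, 0.0) / Rtc;    // tricuspid
  double q_p  = std::max(P_RV - P_PA_el, 0.0) / Rt_PA;  // pulmonary ejection
  double q_pul = (P_PA_el - P_PV) / R_pul;

  NumericVector dy(9);
  dy[0] = q_m - q_a;
  dy[1] = q_a - q_sys;
  dy[2] = q_sys - q_t;
  dy[3] = q_t - q_p;
  dy[4] = q_p - q_pul;
  dy[5] = q_pul - q_m;
  for (int i = 0; i < 3; ++i)
    dy[6 + i] = ((ws[i].Ls - lc[i]) / hp.Lse - 1.0) * hp.vmax;

  // reported arterial pressures include the viscoelastic component
  double P_SA = P_SA_el + Rt_SA * (q_a - q_sys);
  double P_PA = P_PA_el + Rt_PA * (q_p - q_pul);

  NumericVector aux = NumericVector::create(
      _["P_LV"] = P_LV, _["P_RV"] = P_RV, _["P_SA"] = P_SA, _["P_SV"] = P_SV,
      _["P_PA"] = P_PA, _["P_PV"] = P_PV, _["P_peri"] = P_peri,
      _["q_m"] = q_m, _["q_a"] = q_a, _["q_sys"] = q_sys, _["q_t"] = q_t,
      _["q_p"] = q_p, _["q_pul"] = q_pul,
      _["Cm_SW"] = ws[1].Cm, _["Am_SW"] = ws[1].Am,
      _["xm_LW"] = u[0], _["xm_SW"] = u[1], _["xm_RW"] = u[2],
      _["ym"] = u[3],
      _["Ls_LW"] = ws[0].Ls, _["Ls_SW"] = ws[1].Ls, _["Ls_RW"] = ws[2].Ls,
      _["Y"] = Y);
  return List::create(_["dy"] = dy, _["aux"] = aux,
                      _["u"] = NumericVector::create(u[0], u[1], u[2], u[3]));
}
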