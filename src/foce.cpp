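// FOCE-I likelihood kernel for the one-compartment infusion model.
//
// Per subject: find the conditional mode eta-hat of the 2-d random effect
// (log-scale perturbations of CL and V) by Newton iteration with a
// Gauss-Newton Hessian, then accumulate the Laplacian/FOCE approximation to
// -2 log of the marginal likelihood. The residual-error model is either
// Gaussian on log concentration ("exponential", exact eta-eps interaction),
// additive on the natural scale, or combined proportional+additive
// (interaction handled through the eta-dependence of the variance).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double LOG2PI = 1.8378770664093453;

// Concentration and derivatives w.r.t. (log cl, log v) at one time point,
// superposed over infusion dose events. s <= 0 doses contribute nothing.
static void conc_grad(double t,
                      const double* dose_time, const double* amt,
                      const double* dur, int ndose,
                      double cl, double v,
                      double& C, double& dC_dlcl, double& dC_dlv) {
  double ke = cl / v;
  C = 0.0;
  double dC_dke = 0.0;
  for (int d = 0; d < ndose; ++d) {
    double s = t - dose_time[d];
    if (s <= 0) continue;
    double D = dur[d];
    double r0 = amt[d] / D;
    double a = s < D ? s : D;
    double b = s > D ? s - D : 0.0;
    double ea = std::exp(-ke * a);
    double eb = std::exp(-ke * b);
    double h = (1.0 - ea) * eb;
    double dh = a * ea * eb - b * h;
    C += (r0 / cl) * h;
    dC_dke += (r0 / cl) * dh;
  }
  // d ke / d log cl = ke ; d ke / d log v = -ke ; prefactor 1/cl gives -C
  dC_dlcl = -C + ke * dC_dke;
  dC_dlv = -ke * dC_dke;
}

struct SubjData {
  std::vector<double> obs_time, dv, ldv;
  std::vector<double> dose_time, amt, dur;
  double tvcl, tvv;
};

// Fill residual-scale quantities at a given eta.
// errcode 0: exponential (log scale): r = log y - log C, g = dlogC/deta,
//            V = s2a (constant).
// errcode 1: additive: r = y - C, g = dC/deta, V = s2a.
// errcode 2: combined: r = y - C, g = dC/deta, V = s2a + s2p*C^2,
//            dV = 2*s2p*C*g.
struct ObsEval {
  std::vector<double> r, V, g1, g2, dV1, dV2, pred;
};

static bool eval_obs(const SubjData& sd, const double* eta, int errcode,
                     double s2a, double s2p, ObsEval& oe) {
  int n = sd.obs_time.size();
  oe.r.resize(n); oe.V.resize(n); oe.g1.resize(n); oe.g2.resize(n);
  oe.dV1.assign(n, 0.0); oe.dV2.assign(n, 0.0); oe.pred.resize(n);
  double cl = sd.tvcl * std::exp(eta[0]);
  double v = sd.tvv * std::exp(eta[1]);
  for (int j = 0; j < n; ++j) {
    double C, dlcl, dlv;
    conc_grad(sd.obs_time[j], sd.dose_time.data(), sd.amt.data(),
              sd.dur.data(), sd.dose_time.size(), cl, v, C, dlcl, dlv);
    oe.pred[j] = C;
    if (errcode == 0) {
      if (C <= 0) return false;           // log undefined: prediction 0
      oe.r[j] = sd.ldv[j] - std::log(C);
      oe.g1[j] = dlcl / C;
      oe.g2[j] = dlv / C;
      oe.V[j] = s2a;
    } else {
      oe.r[j] = sd.dv[j] - C;
      oe.g1[j] = dlcl;
      oe.g2[j] = dlv;
      if (errcode == 1) {
        oe.V[j] = s2a;
      } else {
        oe.V[j] = s2a + s2p * C * C;
        oe.dV1[j] = 2.0 * s2p * C * dlcl;
        oe.dV2[j] = 2.0 * s2p * C * dlv;
      }
    }
    if (oe.V[j] <= 0) return false;
  }
  return true;
}

// Penalized objective Q(eta) = sum_j [log V_j + r_j^2/V_j] + sum_k eta_k^2/omega2_k
// over free dims (omega2 > 0); fixed dims have eta = 0.
static double q_of_eta(const ObsEval& oe, const double* eta,
                       const double* oinv, const bool* freed) {
  double q = 0.0;
  for (size_t j = 0; j < oe.r.size(); ++j)
    q += std::log(oe.V[j]) + oe.r[j] * oe.r[j] / oe.V[j];
  for (int k = 0; k < 2; ++k)
    if (freed[k]) q += eta[k] * eta[k] * oinv[k];
  return q;
}

// Gradient of Q and Gauss-Newton half-Hessian A (so Hess(Q) ~= 2A).
static void grad_hess(const ObsEval& oe, const double* eta,
                      const double* oinv, const bool* freed,
                      double* grad, double A[2][2]) {
  grad[0] = grad[1] = 0.0;
  A[0][0] = A[0][1] = A[1][0] = A[1][1] = 0.0;
  for (size_t j = 0; j < oe.r.size(); ++j) {
    double r = oe.r[j], V = oe.V[j];
    double g[2] = { oe.g1[j], oe.g2[j] };
    double dV[2] = { oe.dV1[j], oe.dV2[j] };
    for (int k = 0; k < 2; ++k) {
      grad[k] += -2.0 * r * g[k] / V + dV[k] / V - r * r * dV[k] / (V * V);
      for (int l = 0; l < 2; ++l)
        A[k][l] += g[k] * g[l] / V + 0.5 * dV[k] * dV[l] / (V * V);
    }
  }
  for (int k = 0; k < 2; ++k) {
    if (freed[k]) {
      grad[k] += 2.0 * eta[k] * oinv[k];
      A[k][k] += oinv[k];
    } else {
      grad[k] = 0.0;                       // dimension fixed at zero
    }
  }
}

// Newton minimization of Q over the free eta dimensions.
// Returns true on convergence (max |grad| < tol).
static bool inner_newton(const SubjData& sd, int errcode, double s2a,
                         double s2p, const double* oinv, const bool* freed,
                         double tol, int maxit, double* eta, ObsEval& oe) {
  if (!freed[0]) eta[0] = 0.0;
  if (!freed[1]) eta[1] = 0.0;
  if (!eval_obs(sd, eta, errcode, s2a, s2p, oe)) {
    eta[0] = eta[1] = 0.0;
    if (!eval_obs(sd, eta, errcode, s2a, s2p, oe)) return false;
  }
  double q = q_of_eta(oe, eta, oinv, freed);
  double grad[2], A[2][2];
  for (int it = 0; it < maxit; ++it) {
    grad_hess(oe, eta, oinv, freed, grad, A);
    double gmax = std::max(std::fabs(grad[0]), std::fabs(grad[1]));
    if (gmax < tol) return true;
    // Solve (2A) step = grad on the free dims.
    double step[2] = { 0.0, 0.0 };
    if (freed[0] && freed[1]) {
      double det = A[0][0] * A[1][1] - A[0][1] * A[1][0];
      if (det <= 1e-300) return false;
      step[0] = (A[1][1] * grad[0] - A[0][1] * grad[1]) / (2.0 * det);
      step[1] = (A[0][0] * grad[1] - A[1][0] * grad[0]) / (2.0 * det);
    } else if (freed[0]) {
      step[0] = grad[0] / (2.0 * A[0][0]);
    } else if (freed[1]) {
      step[1] = grad[1] / (2.0 * A[1][1]);
    } else {
      return true;                        // nothing free
    }
    double lam = 1.0;
    bool moved = false;
    for (int h = 0; h < 30; ++h, lam *= 0.5) {
      double cand[2] = { eta[0] - lam * step[0], eta[1] - lam * step[1] };
      ObsEval oe2;
      if (!eval_obs(sd, cand, errcode, s2a, s2p, oe2)) continue;
      double q2 = q_of_eta(oe2, cand, oinv, freed);
      if (q2 <= q + 1e-12) {
        eta[0] = cand[0]; eta[1] = cand[1];
        oe = oe2; q = q2; moved = true;
        break;
      }
    }
    if (!moved) {
      double gm = std::max(std::fabs(grad[0]), std::fabs(grad[1]));
      return gm < 1e-4;                   // stalled near optimum
    }
  }
  double gm = std::max(std::fabs(grad[0]), std::fabs(grad[1]));
  return gm < 1e-4;
}

// Exact Hessian of Q at eta by central finite differences of the analytic
// gradient; used for the Laplacian log-determinant. Falls back to the
// Gauss-Newton matrix when the exact Hessian is not positive definite
// (e.g. on a likelihood ridge).
static void exact_hess(const SubjData& sd, int errcode, double s2a,
                       double s2p, const double* oinv, const bool* freed,
                       const double* eta, double A[2][2]) {
  double gn[2][2], grad[2];
  ObsEval oe;
  double H[2][2] = { {0, 0}, {0, 0} };
  const double h = 1e-4;
  bool ok = true;
  for (int k = 0; k < 2 && ok; ++k) {
    if (!freed[k]) continue;
    double gp[2], gm[2];
    double ep[2] = { eta[0], eta[1] }, em[2] = { eta[0], eta[1] };
    ep[k] += h; em[k] -= h;
    if (!eval_obs(sd, ep, errcode, s2a, s2p, oe)) { ok = false; break; }
    grad_hess(oe, ep, oinv, freed, gp, gn);
    if (!eval_obs(sd, em, errcode, s2a, s2p, oe)) { ok = false; break; }
    grad_hess(oe, em, oinv, freed, gm, gn);
    for (int l = 0; l < 2; ++l) H[k][l] = (gp[l] - gm[l]) / (2.0 * h);
  }
  if (ok) {
    // symmetrize; Hessian of the negative log joint is H/2
    double a00 = H[0][0] / 2.0, a11 = H[1][1] / 2.0;
    double a01 = (H[0][1] + H[1][0]) / 4.0;
    bool pd;
    if (freed[0] && freed[1])
      pd = a00 > 0 && a11 > 0 && a00 * a11 - a01 * a01 > 0;
    else if (freed[0]) pd = a00 > 0;
    else if (freed[1]) pd = a11 > 0;
    else pd = true;
    if (pd) {
      A[0][0] = a00; A[1][1] = a11; A[0][1] = A[1][0] = a01;
      return;
    }
  }
  // fallback: Gauss-Newton curvature at eta
  if (eval_obs(sd, eta, errcode, s2a, s2p, oe))
    grad_hess(oe, eta, oinv, freed, grad, A);
}

// [[Rcpp::export]]
List foce_kernel(List subjects, NumericVector tvcl, NumericVector tvv,
                 NumericVector omega2, int errcode, double s2a, double s2p,
                 NumericMatrix eta_start, bool detail = false,
                 double tol = 1e-8, int maxit = 100) {
  int n = subjects.size();
  if (tvcl.size() != n || tvv.size() != n)
    stop("tvcl/tvv length mismatch");
  bool freed[2] = { omega2[0] > 1e-10, omega2[1] > 1e-10 };
  double oinv[2] = { freed[0] ? 1.0 / omega2[0] : 0.0,
                     freed[1] ? 1.0 / omega2[1] : 0.0 };
  double logdet_omega = 0.0;
  int dfree = 0;
  for (int k = 0; k < 2; ++k)
    if (freed[k]) { logdet_omega += std::log(omega2[k]); ++dfree; }

  double ofv = 0.0;
  NumericMatrix eta_out(n, 2);
  LogicalVector ok(n);
  List det_list(detail ? n : 0);

  for (int i = 0; i < n; ++i) {
    List si = subjects[i];
    SubjData sd;
    sd.obs_time = as<std::vector<double> >(si["obs_time"]);
    sd.dv = as<std::vector<double> >(si["dv"]);
    sd.dose_time = as<std::vector<double> >(si["dose_time"]);
    sd.amt = as<std::vector<double> >(si["amt"]);
    sd.dur = as<std::vector<double> >(si["dur"]);
    sd.tvcl = tvcl[i];
    sd.tvv = tvv[i];
    int nobs = sd.obs_time.size();
    sd.ldv.resize(nobs);
    if (errcode == 0)
      for (int j = 0; j < nobs; ++j) {
        if (sd.dv[j] <= 0) stop("non-positive observation with log-scale error");
        sd.ldv[j] = std::log(sd.dv[j]);
      }

    double eta[2] = { eta_start(i, 0), eta_start(i, 1) };
    ObsEval oe;
    if (nobs == 0) {
      eta[0] = eta[1] = 0.0;
      ok[i] = true;
      eta_out(i, 0) = 0.0; eta_out(i, 1) = 0.0;
      if (detail)
        det_list[i] = List::create(_["eta"] = NumericVector::create(0.0, 0.0),
                                   _["ofv_i"] = 0.0,
                                   _["converged"] = true);
      continue;
    }
    ok[i] = inner_newton(sd, errcode, s2a, s2p, oinv, freed, tol, maxit,
                         eta, oe);
    eta_out(i, 0) = eta[0]; eta_out(i, 1) = eta[1];

    double grad[2], A[2][2];
    grad_hess(oe, eta, oinv, freed, grad, A);
    exact_hess(sd, errcode, s2a, s2p, oinv, freed, eta, A);
    double logdet_a;
    if (freed[0] && freed[1]) {
      double dt = A[0][0] * A[1][1] - A[0][1] * A[1][0];
      if (dt <= 0) { ok[i] = false; dt = 1e-300; }
      logdet_a = std::log(dt);
    } else if (freed[0]) {
      logdet_a = std::log(A[0][0]);
    } else if (freed[1]) {
      logdet_a = std::log(A[1][1]);
    } else {
      logdet_a = 0.0;
    }

    double ofv_i = 0.0;
    for (int j = 0; j < nobs; ++j)
      ofv_i += LOG2PI + std::log(oe.V[j]) + oe.r[j] * oe.r[j] / oe.V[j];
    for (int k = 0; k < 2; ++k)
      if (freed[k]) ofv_i += eta[k] * eta[k] * oinv[k];
    ofv_i += logdet_omega + logdet_a;
    ofv += ofv_i;

    if (detail) {
      NumericMatrix G(nobs, 2);
      NumericVector rr(nobs), vv(nobs), pp(nobs);
      for (int j = 0; j < nobs; ++j) {
        G(j, 0) = oe.g1[j]; G(j, 1) = oe.g2[j];
        rr[j] = oe.r[j]; vv[j] = oe.V[j]; pp[j] = oe.pred[j];
      }
      det_list[i] = List::create(
        _["eta"] = NumericVector::create(eta[0], eta[1]),
        _["ofv_i"] = ofv_i, _["resid"] = rr, _["G"] = G, _["V"] = vv,
        _["ipred"] = pp, _["converged"] = (bool)ok[i]);
    }
  }

  List out = List::create(_["ofv"] = ofv, _["eta"] = eta_out, _["ok"] = ok);
  if (detail) out["detail"] = det_list;
  return out;
}

// Concentrations for many (eta_cl, eta_v) draws of one subject at a set of
// times; used by the simulation-based diagnostics (NPDE) where R-level
// looping over replicates would dominate.
// [[Rcpp::export]]
NumericMatrix conc_matrix(NumericVector times, NumericVector dose_time,
                          NumericVector amt, NumericVector dur,
                          double tvcl, double tvv,
                          NumericVector eta_cl, NumericVector eta_v) {
  int nt = times.size(), K = eta_cl.size();
  NumericMatrix out(nt, K);
  for (int k = 0; k < K; ++k) {
    double cl = tvcl * std::exp(eta_cl[k]);
    double v = tvv * std::exp(eta_v[k]);
    for (int j = 0; j < nt; ++j) {
      double C, d1, d2;
      conc_grad(times[j], dose_time.begin(), amt.begin(), dur.begin(),
                dose_time.size(), cl, v, C, d1, d2);
      out(j, k) = C;
    }
  }
  return out;
}
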