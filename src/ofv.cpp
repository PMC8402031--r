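#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// One-compartment multiple-infusion prediction with analytic derivatives.
// For each observation time t the contribution of a dose starting at t0
// with zero-order rate R0 over duration D is, with u = min(t-t0, D),
// w = max(t-t0-D, 0) and ke = CL/Vd:
//   c   = (R0/CL) (1 - exp(-ke u)) exp(-ke w)
//   dc/dke = (R0/CL) exp(-ke w) [ u exp(-ke u) - w (1 - exp(-ke u)) ]
//   dc/dCL = -c/CL + dc/dke / Vd
//   dc/dVd = -dc/dke * ke / Vd
static void conc_grad(double CL, double Vd, double t,
                      const double* dt0, const double* drate,
                      const double* ddur, int ndose,
                      double& f, double& dfdcl, double& dfdvd) {
  const double ke = CL / Vd;
  f = 0.0; dfdcl = 0.0; dfdvd = 0.0;
  for (int d = 0; d < ndose; ++d) {
    const double rel = t - dt0[d];
    if (rel < 0.0) continue;
    const double u = rel < ddur[d] ? rel : ddur[d];
    const double w = rel - u;
    const double eu = std::exp(-ke * u);
    const double ew = std::exp(-ke * w);
    const double base = drate[d] / CL;
    const double c = base * (1.0 - eu) * ew;
    const double dcdke = base * ew * (u * eu - w * (1.0 - eu));
    f += c;
    dfdcl += -c / CL + dcdke / Vd;
    dfdvd += -dcdke * ke / Vd;
  }
}

// Conditional (empirical Bayes) mode of the two random effects for one
// subject, by damped Newton with a Gauss-Newton Hessian, followed by the
// Laplace/FOCE-I contribution to -2 log marginal likelihood.
//
// g(eta) = sum_j [ r_j^2/v_j + log v_j ] + sum_active eta_k^2/omega_k^2
// with r = y - f, v = sigma_add^2 + (sigma_prop f)^2 evaluated at eta
// (interaction). Contribution:
//   ofv_i = sum_j [ log 2pi + log v + r^2/v ] + eta'Om^-1 eta + log|Om_a|
//           + log det( J'V^-1 J + Om_a^-1 )
// where only active dimensions (omega > 0) enter the last three terms.
struct SubjData {
  const double* t; const double* y; const double* tvcl; const double* tvvd;
  int nobs;
  const double* dt0; const double* drate; const double* ddur; int ndose;
};

static void predict_eta(const SubjData& S, double e1, double e2,
                        double* f, double* g1, double* g2) {
  const double a1 = std::exp(e1), a2 = std::exp(e2);
  for (int j = 0; j < S.nobs; ++j) {
    const double CL = S.tvcl[j] * a1;
    const double Vd = S.tvvd[j] * a2;
    double fj, dcl, dvd;
    conc_grad(CL, Vd, S.t[j], S.dt0, S.drate, S.ddur, S.ndose, fj, dcl, dvd);
    f[j] = fj;
    g1[j] = dcl * CL;   // df/deta1
    g2[j] = dvd * Vd;   // df/deta2
  }
}

static double inner_g(const SubjData& S, const double* f,
                      double e1, double e2,
                      double w1inv2, double w2inv2, bool a1, bool a2,
                      double s2add, double s2prop) {
  double g = 0.0;
  for (int j = 0; j < S.nobs; ++j) {
    const double v = s2add + s2prop * f[j] * f[j];
    const double r = S.y[j] - f[j];
    g += r * r / v + std::log(v);
  }
  if (a1) g += e1 * e1 * w1inv2;
  if (a2) g += e2 * e2 * w2inv2;
  return g;
}

// Gauss-Hermite nodes/weights (weight function exp(-x^2)).
static const double GH5_X[] = {0.0, 0.958572464613819, -0.958572464613819,
                               2.020182870456086, -2.020182870456086};
static const double GH5_W[] = {0.945308720482942, 0.393619323152241,
                               0.393619323152241, 0.019953242059046,
                               0.019953242059046};
static const double GH7_X[] = {0.0, 0.816287882858965, -0.816287882858965,
                               1.673551628767471, -1.673551628767471,
                               2.651961356835233, -2.651961356835233};
static const double GH7_W[] = {0.810264617556807, 0.425607252610128,
                               0.425607252610128, 0.054515582819127,
                               0.054515582819127, 0.000971781245100,
                               0.000971781245100};

// -2 log joint density at eta (times 1/2 gives h used by the quadrature)
static double neg2_log_joint(const SubjData& S, const double* f,
                             double e1, double e2,
                             double w1inv2, double w2inv2,
                             bool a1, bool a2, double lognorm_eta,
                             double s2add, double s2prop) {
  const double LOG2PI = std::log(2.0 * M_PI);
  double out = 0.0;
  for (int j = 0; j < S.nobs; ++j) {
    double v = s2add + s2prop * f[j] * f[j];
    if (v < 1e-12) v = 1e-12;
    const double r = S.y[j] - f[j];
    out += LOG2PI + std::log(v) + r * r / v;
  }
  if (a1) out += e1 * e1 * w1inv2;
  if (a2) out += e2 * e2 * w2inv2;
  out += lognorm_eta; // q log 2pi + log|Omega| over active dims
  return out;
}

// [[Rcpp::export]]
List cpp_ofv(IntegerVector obs_ptr, NumericVector obs_t, NumericVector obs_y,
             NumericVector tvcl, NumericVector tvvd,
             IntegerVector dose_ptr, NumericVector dose_t,
             NumericVector dose_rate, NumericVector dose_dur,
             double omega_cl, double omega_vd,
             double sigma_add, double sigma_prop,
             NumericMatrix eta_start, int nq = 1) {
  const int S = obs_ptr.size() - 1;
  const double s2add = sigma_add * sigma_add;
  const double s2prop = sigma_prop * sigma_prop;
  const bool act1 = omega_cl > 0.0, act2 = omega_vd > 0.0;
  const double w1inv2 = act1 ? 1.0 / (omega_cl * omega_cl) : 0.0;
  const double w2inv2 = act2 ? 1.0 / (omega_vd * omega_vd) : 0.0;
  const double LOG2PI = std::log(2.0 * M_PI);
  const double VFLOOR = 1e-12;

  NumericMatrix eta(2, S);
  NumericVector ipred(obs_t.size());
  double ofv = 0.0;
  std::vector<double> f(64), g1(64), g2(64);

  for (int i = 0; i < S; ++i) {
    SubjData D;
    const int o0 = obs_ptr[i], o1 = obs_ptr[i + 1];
    D.t = &obs_t[o0]; D.y = &obs_y[o0];
    D.tvcl = &tvcl[o0]; D.tvvd = &tvvd[o0];
    D.nobs = o1 - o0;
    const int d0 = dose_ptr[i], d1 = dose_ptr[i + 1];
    D.dt0 = &dose_t[d0]; D.drate = &dose_rate[d0]; D.ddur = &dose_dur[d0];
    D.ndose = d1 - d0;
    if ((int)f.size() < D.nobs) { f.resize(D.nobs); g1.resize(D.nobs); g2.resize(D.nobs); }

    double e1 = act1 ? eta_start(0, i) : 0.0;
    double e2 = act2 ? eta_start(1, i) : 0.0;
    if (!std::isfinite(e1) || std::fabs(e1) > 8.0) e1 = 0.0;
    if (!std::isfinite(e2) || std::fabs(e2) > 8.0) e2 = 0.0;

    predict_eta(D, e1, e2, f.data(), g1.data(), g2.data());
    double gcur = inner_g(D, f.data(), e1, e2, w1inv2, w2inv2, act1, act2,
                          s2add, s2prop);

    if (act1 || act2) {
      for (int iter = 0; iter < 60; ++iter) {
        // gradient and Gauss-Newton Hessian of g at (e1, e2)
        double G1 = 0, G2 = 0, H11 = 0, H12 = 0, H22 = 0;
        for (int j = 0; j < D.nobs; ++j) {
          double v = s2add + s2prop * f[j] * f[j];
          if (v < VFLOOR) v = VFLOOR;
          const double r = D.y[j] - f[j];
          const double dv1 = 2.0 * s2prop * f[j] * g1[j];
          const double dv2 = 2.0 * s2prop * f[j] * g2[j];
          const double common = (1.0 / v - r * r / (v * v));
          G1 += -2.0 * r / v * g1[j] + common * dv1;
          G2 += -2.0 * r / v * g2[j] + common * dv2;
          H11 += 2.0 * g1[j] * g1[j] / v;
          H12 += 2.0 * g1[j] * g2[j] / v;
          H22 += 2.0 * g2[j] * g2[j] / v;
        }
        if (act1) { G1 += 2.0 * e1 * w1inv2; H11 += 2.0 * w1inv2; } else { G1 = 0; }
        if (act2) { G2 += 2.0 * e2 * w2inv2; H22 += 2.0 * w2inv2; } else { G2 = 0; }

        // Newton step on active dims (2x2 / 1x1 solve with ridge fallback)
        double s1 = 0, s2 = 0;
        if (act1 && act2) {
          double det = H11 * H22 - H12 * H12;
          if (det < 1e-12) { H11 += 1e-6; H22 += 1e-6; det = H11 * H22 - H12 * H12; }
          s1 = -(H22 * G1 - H12 * G2) / det;
          s2 = -(H11 * G2 - H12 * G1) / det;
        } else if (act1) {
          s1 = -G1 / H11;
        } else {
          s2 = -G2 / H22;
        }
        const double gnorm = std::fabs(G1) + std::fabs(G2);
        if (gnorm < 1e-8 * (1.0 + std::fabs(gcur))) break;
        // cap step length
        const double smax = std::max(std::fabs(s1), std::fabs(s2));
        if (smax > 2.0) { s1 *= 2.0 / smax; s2 *= 2.0 / smax; }

        double step = 1.0, gnew = 0.0, n1 = e1, n2 = e2;
        bool improved = false;
        for (int ls = 0; ls < 25; ++ls) {
          n1 = e1 + step * s1; n2 = e2 + step * s2;
          if (std::fabs(n1) > 10.0) n1 = n1 > 0 ? 10.0 : -10.0;
          if (std::fabs(n2) > 10.0) n2 = n2 > 0 ? 10.0 : -10.0;
          predict_eta(D, n1, n2, f.data(), g1.data(), g2.data());
          gnew = inner_g(D, f.data(), n1, n2, w1inv2, w2inv2, act1, act2,
                         s2add, s2prop);
          if (std::isfinite(gnew) && gnew <= gcur + 1e-12) { improved = true; break; }
          step *= 0.5;
        }
        if (!improved) { // restore state at (e1, e2) and stop
          predict_eta(D, e1, e2, f.data(), g1.data(), g2.data());
          break;
        }
        const double moved = std::fabs(n1 - e1) + std::fabs(n2 - e2);
        e1 = n1; e2 = n2; gcur = gnew;
        if (moved < 1e-10) break;
      }
    }

    // Laplace (nq = 1) or adaptive Gauss-Hermite (nq = 5 or 7)
    // contribution at the conditional mode
    double sumlik = 0.0, A11 = 0.0, A12 = 0.0, A22 = 0.0;
    for (int j = 0; j < D.nobs; ++j) {
      double v = s2add + s2prop * f[j] * f[j];
      if (v < VFLOOR) v = VFLOOR;
      const double r = D.y[j] - f[j];
      sumlik += LOG2PI + std::log(v) + r * r / v;
      A11 += g1[j] * g1[j] / v;
      A12 += g1[j] * g2[j] / v;
      A22 += g2[j] * g2[j] / v;
      ipred[o0 + j] = f[j];
    }
    const int q = (act1 ? 1 : 0) + (act2 ? 1 : 0);
    double ofv_i;
    if (q == 0) {
      ofv_i = sumlik;
    } else if (nq <= 1) {
      ofv_i = sumlik;
      if (act1 && act2) {
        const double G11 = A11 + w1inv2, G12 = A12, G22 = A22 + w2inv2;
        double det = G11 * G22 - G12 * G12;
        if (det < 1e-300) det = 1e-300;
        ofv_i += e1 * e1 * w1inv2 + e2 * e2 * w2inv2
          + std::log(omega_cl * omega_cl) + std::log(omega_vd * omega_vd)
          + std::log(det);
      } else if (act1) {
        ofv_i += e1 * e1 * w1inv2 + std::log(omega_cl * omega_cl)
          + std::log(A11 + w1inv2);
      } else {
        ofv_i += e2 * e2 * w2inv2 + std::log(omega_vd * omega_vd)
          + std::log(A22 + w2inv2);
      }
    } else {
      const double* gx = (nq >= 7) ? GH7_X : GH5_X;
      const double* gw = (nq >= 7) ? GH7_W : GH5_W;
      const int nn = (nq >= 7) ? 7 : 5;
      double lognorm_eta = q * LOG2PI;
      if (act1) lognorm_eta += std::log(omega_cl * omega_cl);
      if (act2) lognorm_eta += std::log(omega_vd * omega_vd);
      std::vector<double> terms;
      terms.reserve(q == 2 ? nn * nn : nn);
      double logdetG;
      if (q == 2) {
        const double G11 = A11 + w1inv2, G12 = A12, G22 = A22 + w2inv2;
        double det = G11 * G22 - G12 * G12;
        if (det < 1e-300) det = 1e-300;
        logdetG = std::log(det);
        const double s11 = G22 / det, s12 = -G12 / det, s22 = G11 / det;
        const double c11 = std::sqrt(s11);
        const double c21 = s12 / c11;
        const double c22 = std::sqrt(std::max(s22 - c21 * c21, 1e-300));
        for (int a = 0; a < nn; ++a) for (int b = 0; b < nn; ++b) {
          const double z1 = gx[a], z2 = gx[b];
          const double e1n = e1 + M_SQRT2 * c11 * z1;
          const double e2n = e2 + M_SQRT2 * (c21 * z1 + c22 * z2);
          predict_eta(D, e1n, e2n, f.data(), g1.data(), g2.data());
          const double h = 0.5 * neg2_log_joint(
            D, f.data(), e1n, e2n, w1inv2, w2inv2, act1, act2,
            lognorm_eta, s2add, s2prop);
          terms.push_back(std::log(gw[a] * gw[b]) + z1 * z1 + z2 * z2 - h);
        }
      } else {
        const double G = act1 ? (A11 + w1inv2) : (A22 + w2inv2);
        logdetG = std::log(std::max(G, 1e-300));
        const double c = 1.0 / std::sqrt(std::max(G, 1e-300));
        for (int a = 0; a < nn; ++a) {
          const double z = gx[a];
          const double e1n = act1 ? e1 + M_SQRT2 * c * z : 0.0;
          const double e2n = act2 ? e2 + M_SQRT2 * c * z : 0.0;
          predict_eta(D, e1n, e2n, f.data(), g1.data(), g2.data());
          const double h = 0.5 * neg2_log_joint(
            D, f.data(), e1n, e2n, w1inv2, w2inv2, act1, act2,
            lognorm_eta, s2add, s2prop);
          terms.push_back(std::log(gw[a]) + z * z - h);
        }
      }
      double m = terms[0];
      for (double t : terms) if (t > m) m = t;
      double s = 0.0;
      for (double t : terms) s += std::exp(t - m);
      ofv_i = -q * std::log(2.0) + logdetG - 2.0 * (m + std::log(s));
    }
    eta(0, i) = e1; eta(1, i) = e2;
    ofv += ofv_i;
  }

  return List::create(_["ofv"] = ofv, _["eta"] = eta, _["ipred"] = ipred);
}

// Noise-free predictions for a whole dataset given per-observation
// individual CL and Vd (used by the simulation-based diagnostics).
// [[Rcpp::export]]
NumericVector cpp_pred(IntegerVector obs_ptr, NumericVector obs_t,
                       NumericVector cl, NumericVector vd,
                       IntegerVector dose_ptr, NumericVector dose_t,
                       NumericVector dose_rate, NumericVector dose_dur) {
  const int S = obs_ptr.size() - 1;
  NumericVector f(obs_t.size());
  for (int i = 0; i < S; ++i) {
    const int o0 = obs_ptr[i], o1 = obs_ptr[i + 1];
    const int d0 = dose_ptr[i], d1 = dose_ptr[i + 1];
    for (int j = o0; j < o1; ++j) {
      double fj, dcl, dvd;
      conc_grad(cl[j], vd[j], obs_t[j], &dose_t[d0], &dose_rate[d0],
                &dose_dur[d0], d1 - d0, fj, dcl, dvd);
      f[j] = fj;
    }
  }
  return f;
}
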