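// Core numerics for the dual-decision observer model.
//
// All stimulus strengths are on the normalized scale s = (dir*coh - bias)/sigma,
// so internal noise is 1 throughout. Internal responses r ~ N(s, 1).
// The target-decision criterion is theta = -|r_lead| / w_choice (always <= 0:
// the task rule makes the prior point rightward).
#ifndef PRIORCONF_CORE_H
#define PRIORCONF_CORE_H

#include <Rcpp.h>
#include <cmath>
#include <vector>

namespace pc {

const double INV_SQRT2   = 0.707106781186547524;
const double INV_SQRT2PI = 0.398942280401432678;
const double PROB_EPS    = 1e-9;   // clamp for the Bayes combination
const double LIK_FLOOR   = 1e-300; // floor before log()

inline double phi_pdf(double x) { return INV_SQRT2PI * std::exp(-0.5 * x * x); }
inline double Phi(double x)     { return 0.5 * std::erfc(-x * INV_SQRT2); }

// Inverse standard-normal CDF: Acklam's rational approximation
// (relative error ~1e-9, far below the quadrature error).
inline double qnorm_fast(double p) {
  if (p <= 0.0) return -INFINITY;
  if (p >= 1.0) return  INFINITY;
  static const double a[6] = { -3.969683028665376e+01,  2.209460984245205e+02,
                               -2.759285104469687e+02,  1.383577518672690e+02,
                               -3.066479806614716e+01,  2.506628277459239e+00 };
  static const double b[5] = { -5.447609879822406e+01,  1.615858368580409e+02,
                               -1.556989798598866e+02,  6.680131188771972e+01,
                               -1.328068155288572e+01 };
  static const double c[6] = { -7.784894002430293e-03, -3.223964580411365e-01,
                               -2.400758277161838e+00, -2.549732539343734e+00,
                                4.374664141464968e+00,  2.938163982698783e+00 };
  static const double d[4] = {  7.784695709041462e-03,  3.224671290700398e-01,
                                2.445134137142996e+00,  3.754408661907416e+00 };
  const double p_low = 0.02425, p_high = 1.0 - p_low;
  double x;
  if (p < p_low) {
    double q = std::sqrt(-2.0 * std::log(p));
    x = (((((c[0]*q + c[1])*q + c[2])*q + c[3])*q + c[4])*q + c[5]) /
        ((((d[0]*q + d[1])*q + d[2])*q + d[3])*q + 1.0);
  } else if (p <= p_high) {
    double q = p - 0.5, r = q * q;
    x = (((((a[0]*r + a[1])*r + a[2])*r + a[3])*r + a[4])*r + a[5])*q /
        (((((b[0]*r + b[1])*r + b[2])*r + b[3])*r + b[4])*r + 1.0);
  } else {
    double q = std::sqrt(-2.0 * std::log(1.0 - p));
    x = -(((((c[0]*q + c[1])*q + c[2])*q + c[3])*q + c[4])*q + c[5]) /
         ((((d[0]*q + d[1])*q + d[2])*q + d[3])*q + 1.0);
  }
  return x;
}

// Gauss-Legendre nodes/weights on [-1, 1], Newton iteration on P_n.
inline void gauss_legendre(int n, std::vector<double>& x, std::vector<double>& w) {
  x.assign(n, 0.0); w.assign(n, 0.0);
  int m = (n + 1) / 2;
  for (int i = 0; i < m; ++i) {
    double z = std::cos(M_PI * (i + 0.75) / (n + 0.5)), z1, pp;
    do {
      double p1 = 1.0, p2 = 0.0;
      for (int j = 0; j < n; ++j) {
        double p3 = p2; p2 = p1;
        p1 = ((2.0 * j + 1.0) * z * p2 - j * p3) / (j + 1.0);
      }
      pp = n * (z * p1 - p2) / (z * z - 1.0);
      z1 = z; z = z1 - p1 / pp;
    } while (std::fabs(z - z1) > 1e-14);
    x[i] = -z; x[n - 1 - i] = z;
    w[i] = 2.0 / ((1.0 - z * z) * pp * pp); w[n - 1 - i] = w[i];
  }
}

// Eq. for the Bayes combination of a rightward prior and likelihood
// (posterior probability correct for a rightward choice).
inline double bayes_conf_right(double p_prior, double p_like) {
  if (p_prior < PROB_EPS) p_prior = PROB_EPS;
  if (p_prior > 1.0 - PROB_EPS) p_prior = 1.0 - PROB_EPS;
  if (p_like  < PROB_EPS) p_like  = PROB_EPS;
  if (p_like  > 1.0 - PROB_EPS) p_like  = 1.0 - PROB_EPS;
  double num = p_prior * p_like;
  return num / ((1.0 - p_prior) * (1.0 - p_like) + num);
}

// Truncated-Gaussian report density on [0.5, 1].
inline double report_density(double c, double mu, double sd) {
  double z  = (c - mu) / sd;
  double zu = (1.0 - mu) / sd, zl = (0.5 - mu) / sd;
  double mass = Phi(zu) - Phi(zl);
  if (mass < 1e-14) mass = 1e-14;
  return phi_pdf(z) / (sd * mass);
}

// Per-dataset precomputation for the marginalized likelihood.
// The latent magnitude u = |r_lead| given the observed lead choice has
// density proportional to phi(u - m) on u > 0, with m = d_lead * s_lead.
// Nodes are Gauss-Legendre on (0, u_max]; weights are self-normalized.
struct ObsData {
  int n;
  std::vector<double> s_lead, s_target;  // signed normalized strengths
  std::vector<int>    d_lead, d_target;  // observed choices, +1 / -1
  std::vector<double> conf;              // reports on [0.5, 1]
  std::vector<double> m_lead;            // level-mean |s| of lead stimulus
  std::vector<double> rbar_target;       // signed level-mean target strength
  std::vector<int>    part;              // participant index (0-based)

  int n_u;
  std::vector<double> u_nodes;           // shared magnitude nodes
  std::vector<double> tnw;               // n x n_u normalized weights

  void precompute(int n_u_, double u_max) {
    n_u = n_u_;
    std::vector<double> gx, gw;
    gauss_legendre(n_u, gx, gw);
    u_nodes.resize(n_u);
    std::vector<double> base_w(n_u);
    double half = 0.5 * u_max;
    for (int i = 0; i < n_u; ++i) {
      u_nodes[i] = half * (gx[i] + 1.0);
      base_w[i]  = half * gw[i];
    }
    tnw.assign((size_t)n * n_u, 0.0);
    for (int t = 0; t < n; ++t) {
      double m = d_lead[t] * s_lead[t];
      double tot = 0.0;
      for (int i = 0; i < n_u; ++i) {
        double wgt = base_w[i] * phi_pdf(u_nodes[i] - m);
        tnw[(size_t)t * n_u + i] = wgt;
        tot += wgt;
      }
      if (tot < 1e-300) tot = 1e-300;
      for (int i = 0; i < n_u; ++i) tnw[(size_t)t * n_u + i] /= tot;
    }
  }
};

// Marginal probability of a rightward target choice for one trial
// (Eqs. 3-4 marginalization over the truncated-normal lead response).
inline double p_right_trial(const ObsData& D, int t, double w_choice,
                            bool flat_prior, bool simplified) {
  if (flat_prior) return Phi(D.s_target[t]);
  if (simplified) return Phi(D.s_target[t] + D.m_lead[t] / w_choice);
  const double* wrow = &D.tnw[(size_t)t * D.n_u];
  double p = 0.0;
  for (int i = 0; i < D.n_u; ++i)
    p += wrow[i] * Phi(D.s_target[t] + D.u_nodes[i] / w_choice);
  return p;
}

inline double choice_ll_trial(const ObsData& D, int t, double w_choice,
                              bool flat_prior, bool simplified) {
  double p = p_right_trial(D, t, w_choice, flat_prior, simplified);
  if (D.d_target[t] < 0) p = 1.0 - p;
  if (p < 1e-12) p = 1e-12;
  if (p > 1.0 - 1e-12) p = 1.0 - 1e-12;
  return std::log(p);
}

// Confidence-report log-density for one trial.
//
// Full version: integrates over (|r_lead|, r_target) jointly consistent
// with the observed choices; the inner integral over r_target uses
// equal-probability (quantile) Gauss-Legendre nodes on the side of the
// criterion selected by the observed target choice.
// Simplified version: plugs in level-mean internal signals on the
// true-direction side (the hierarchical-model simplification).
inline double conf_ll_trial(const ObsData& D, int t,
                            double w_choice, double w_conf, double b,
                            double sd_report, bool flat_prior, bool simplified,
                            int n_v, const std::vector<double>& v_nodes,
                            const std::vector<double>& v_w) {
  double c = D.conf[t];
  int d2 = D.d_target[t];
  double s_t = D.s_target[t];

  if (simplified) {
    double p_prior = flat_prior ? 0.5 : Phi(D.m_lead[t] / (b * w_conf));
    double p_like  = Phi(D.rbar_target[t] / b);
    double cr = bayes_conf_right(p_prior, p_like);
    double mu = (d2 > 0) ? cr : 1.0 - cr;
    if (mu < 0.5) mu = 0.5;
    if (mu > 1.0) mu = 1.0;
    double dens = report_density(c, mu, sd_report);
    return std::log(dens > LIK_FLOOR ? dens : LIK_FLOOR);
  }

  if (flat_prior) {
    // 1-D: r_target truncated at 0 by the observed choice, prior fixed 0.5.
    double Pr = (d2 > 0) ? 1.0 - Phi(-s_t) : Phi(-s_t);
    if (Pr < 1e-14) Pr = 1e-14;
    double p_lo = (d2 > 0) ? Phi(-s_t) : 0.0;
    double g = 0.0;
    for (int k = 0; k < n_v; ++k) {
      double pp = p_lo + v_nodes[k] * Pr;
      double r  = s_t + qnorm_fast(pp);
      double cr = bayes_conf_right(0.5, Phi(r / b));
      double mu = (d2 > 0) ? cr : 1.0 - cr;
      if (mu < 0.5) mu = 0.5;
      if (mu > 1.0) mu = 1.0;
      g += v_w[k] * report_density(c, mu, sd_report);
    }
    return std::log(g > LIK_FLOOR ? g : LIK_FLOOR);
  }

  const double* wrow = &D.tnw[(size_t)t * D.n_u];
  double num = 0.0, den = 0.0;
  for (int i = 0; i < D.n_u; ++i) {
    double tw = wrow[i];
    if (tw < 1e-12) continue;
    double u = D.u_nodes[i];
    double theta = -u / w_choice;
    double z = theta - s_t;
    double Pr, p_lo;
    if (d2 > 0) { p_lo = Phi(z); Pr = 1.0 - p_lo; }
    else        { p_lo = 0.0;    Pr = Phi(z); }
    if (Pr < 1e-14) continue;
    double p_prior = Phi(u / (b * w_conf));
    double g = 0.0;
    for (int k = 0; k < n_v; ++k) {
      double pp = p_lo + v_nodes[k] * Pr;
      double r  = s_t + qnorm_fast(pp);
      double cr = bayes_conf_right(p_prior, Phi(r / b));
      double mu = (d2 > 0) ? cr : 1.0 - cr;
      if (mu < 0.5) mu = 0.5;
      if (mu > 1.0) mu = 1.0;
      g += v_w[k] * report_density(c, mu, sd_report);
    }
    num += tw * Pr * g;
    den += tw * Pr;
  }
  double lik = (den > 0.0) ? num / den : 0.0;
  return std::log(lik > LIK_FLOOR ? lik : LIK_FLOOR);
}

inline void gl01(int n, std::vector<double>& x, std::vector<double>& w) {
  std::vector<double> gx, gw;
  gauss_legendre(n, gx, gw);
  x.resize(n); w.resize(n);
  for (int i = 0; i < n; ++i) { x[i] = 0.5 * (gx[i] + 1.0); w[i] = 0.5 * gw[i]; }
}

} // namespace pc

#endif
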