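// Adaptive MCMC samplers for the observer model.
//
// Individual fits: joint adaptive random-walk Metropolis on log-scale
// parameters, component scales learned from the running chain variance
// during warmup (target acceptance 0.30).
//
// Hierarchical fits: Metropolis-within-Gibbs with a centered
// parameterization. Participant-level log-parameters theta_jk ~
// N(mu_k, tau_k); mu_k has a conjugate Gibbs update, tau_k and the shared
// report-noise SD are updated by 1-D adaptive Metropolis steps.
// The choice likelihood is the full marginalization (Gauss-Legendre over
// the truncated-normal lead response); the confidence likelihood uses the
// level-mean simplification, as in the hierarchical model definition.
#include "priorconf_core.h"
using namespace Rcpp;

namespace {

pc::ObsData build_obsdata(List data, int n_u, double u_max) {
  pc::ObsData D;
  NumericVector s_lead = data["s_lead"], s_target = data["s_target"],
                conf = data["conf"], m_lead = data["m_lead"],
                rbar_target = data["rbar_target"];
  IntegerVector d_lead = data["d_lead"], d_target = data["d_target"],
                part = data["part"];
  D.n = s_lead.size();
  D.s_lead.assign(s_lead.begin(), s_lead.end());
  D.s_target.assign(s_target.begin(), s_target.end());
  D.conf.assign(conf.begin(), conf.end());
  D.m_lead.assign(m_lead.begin(), m_lead.end());
  D.rbar_target.assign(rbar_target.begin(), rbar_target.end());
  D.d_lead.assign(d_lead.begin(), d_lead.end());
  D.d_target.assign(d_target.begin(), d_target.end());
  D.part.assign(part.begin(), part.end());
  D.precompute(n_u, u_max);
  return D;
}

struct Pars { double wc, wf, b, sd; bool flat; };

// model: 0 flexible, 1 flat_prior, 2 optimal, 3 equal
int n_free(int model) { return model == 0 ? 4 : (model == 3 ? 3 : 2); }

Pars unpack(int model, const std::vector<double>& p) {
  Pars q; q.flat = false;
  switch (model) {
    case 0: q.wc = std::exp(p[0]); q.wf = std::exp(p[1]);
            q.b = std::exp(p[2]); q.sd = std::exp(p[3]); break;
    case 1: q.flat = true; q.wc = q.wf = 1.0;
            q.b = std::exp(p[0]); q.sd = std::exp(p[1]); break;
    case 2: q.wc = q.wf = 1.0;
            q.b = std::exp(p[0]); q.sd = std::exp(p[1]); break;
    default: q.wc = q.wf = std::exp(p[0]);
             q.b = std::exp(p[1]); q.sd = std::exp(p[2]); break;
  }
  return q;
}

// Weakly informative priors, centered on the optimal observer:
// lognormal(0, 1) on weighting and bias parameters; half-normal(sd_scale)
// on the report-noise SD (Jacobian included; constants dropped).
double log_prior(int model, const std::vector<double>& p, double sd_scale) {
  int np = n_free(model);
  double lp = 0.0;
  for (int i = 0; i < np - 1; ++i) lp += -0.5 * p[i] * p[i];
  double lsd = p[np - 1], sd = std::exp(lsd);
  lp += -0.5 * (sd / sd_scale) * (sd / sd_scale) + lsd;
  return lp;
}

double data_loglik(const pc::ObsData& D, const Pars& q, bool conf_simplified,
                   int n_v, const std::vector<double>& vx,
                   const std::vector<double>& vw) {
  double ll = 0.0;
  for (int t = 0; t < D.n; ++t) {
    ll += pc::choice_ll_trial(D, t, q.wc, q.flat, false);
    ll += pc::conf_ll_trial(D, t, q.wc, q.wf, q.b, q.sd, q.flat,
                            conf_simplified, n_v, vx, vw);
  }
  return ll;
}

} // namespace

// [[Rcpp::export]]
List cpp_mcmc_individual(List data, int model, NumericVector init,
                         int n_warmup, int n_iter, bool conf_simplified,
                         int n_u, int n_v, double u_max, double sd_scale) {
  pc::ObsData D = build_obsdata(data, n_u, u_max);
  std::vector<double> vx, vw;
  pc::gl01(n_v, vx, vw);
  int np = n_free(model);
  if ((int)init.size() != np) stop("init has wrong length");
  std::vector<double> p(init.begin(), init.end());
  Pars q = unpack(model, p);
  double lpost = data_loglik(D, q, conf_simplified, n_v, vx, vw) +
                 log_prior(model, p, sd_scale);

  // full-covariance adaptation (running mean/covariance of the chain,
  // proposal Cholesky refreshed during warmup; global scale tuned to 0.30)
  std::vector<double> mean(np, 0.0), cov((size_t)np * np, 0.0),
      L((size_t)np * np, 0.0);
  for (int i = 0; i < np; ++i) L[(size_t)i * np + i] = 0.10;
  double lg = 0.0;
  bool cov_ready = false;
  int n_total = n_warmup + n_iter, n_acc = 0, t_adapt = 0;
  NumericMatrix draws(n_iter, np);
  NumericVector lp_out(n_iter);
  std::vector<double> prop(np), z(np);

  for (int it = 0; it < n_total; ++it) {
    double step = std::exp(lg);
    for (int i = 0; i < np; ++i) z[i] = R::norm_rand();
    for (int i = 0; i < np; ++i) {
      double dx = 0.0;
      for (int k = 0; k <= i; ++k) dx += L[(size_t)i * np + k] * z[k];
      prop[i] = p[i] + step * dx;
    }
    Pars qp = unpack(model, prop);
    double lpost_p = data_loglik(D, qp, conf_simplified, n_v, vx, vw) +
                     log_prior(model, prop, sd_scale);
    double a = std::min(1.0, std::exp(lpost_p - lpost));
    if (R::unif_rand() < a) { p = prop; lpost = lpost_p; if (it >= n_warmup) ++n_acc; }
    if (it < n_warmup) {
      ++t_adapt;
      lg += (a - 0.30) / std::pow((double)t_adapt, 0.6);
      for (int i = 0; i < np; ++i) {          // running mean / covariance
        double d = p[i] - mean[i];
        mean[i] += d / t_adapt;
        for (int k = 0; k <= i; ++k)
          cov[(size_t)i * np + k] += d * (p[k] - mean[k]);
      }
      if (t_adapt > 100 && t_adapt % 25 == 0) {
        // scaled covariance (2.38^2/d) with jitter, then Cholesky
        std::vector<double> C((size_t)np * np, 0.0);
        double fac = 5.6644 / np / (t_adapt - 1);
        bool ok = true;
        for (int i = 0; i < np; ++i)
          for (int k = 0; k <= i; ++k) {
            C[(size_t)i * np + k] = fac * cov[(size_t)i * np + k];
            if (i == k) C[(size_t)i * np + i] += 1e-6;
          }
        for (int i = 0; i < np && ok; ++i) {   // in-place Cholesky
          for (int k = 0; k <= i; ++k) {
            double s = C[(size_t)i * np + k];
            for (int m2 = 0; m2 < k; ++m2)
              s -= C[(size_t)i * np + m2] * C[(size_t)k * np + m2];
            if (i == k) {
              if (s <= 0) { ok = false; break; }
              C[(size_t)i * np + i] = std::sqrt(s);
            } else {
              C[(size_t)i * np + k] = s / C[(size_t)k * np + k];
            }
          }
        }
        if (ok) {
          L = C;
          if (!cov_ready) { lg = 0.0; cov_ready = true; }
        }
      }
    } else {
      int k = it - n_warmup;
      for (int i = 0; i < np; ++i) draws(k, i) = p[i];
      lp_out[k] = lpost;
    }
  }
  return List::create(_["draws"] = draws, _["lp"] = lp_out,
                      _["accept"] = (double)n_acc / n_iter);
}

// Posterior log-density evaluator used by the R-level MAP initializer.
// [[Rcpp::export]]
double cpp_logpost_individual(List data, int model, NumericVector pars,
                              bool conf_simplified, int n_u, int n_v,
                              double u_max, double sd_scale) {
  pc::ObsData D = build_obsdata(data, n_u, u_max);
  std::vector<double> vx, vw;
  pc::gl01(n_v, vx, vw);
  std::vector<double> p(pars.begin(), pars.end());
  Pars q = unpack(model, p);
  return data_loglik(D, q, conf_simplified, n_v, vx, vw) +
         log_prior(model, p, sd_scale);
}

namespace {

// Hierarchical parameter layout: K per-participant log-parameters.
// flexible: (log w_choice, log w_conf, log b); equal: (log w, log b);
// optimal / flat_prior: (log b).
int hier_K(int model) { return model == 0 ? 3 : (model == 3 ? 2 : 1); }

Pars hier_unpack(int model, const double* th, double sd) {
  Pars q; q.flat = (model == 1); q.sd = sd;
  switch (model) {
    case 0: q.wc = std::exp(th[0]); q.wf = std::exp(th[1]); q.b = std::exp(th[2]); break;
    case 3: q.wc = q.wf = std::exp(th[0]); q.b = std::exp(th[1]); break;
    default: q.wc = q.wf = 1.0; q.b = std::exp(th[0]); break;
  }
  return q;
}

double part_choice_ll(const pc::ObsData& D, const std::vector<int>& idx,
                      const Pars& q) {
  double ll = 0.0;
  for (int t : idx) ll += pc::choice_ll_trial(D, t, q.wc, q.flat, false);
  return ll;
}

double part_conf_ll(const pc::ObsData& D, const std::vector<int>& idx,
                    const Pars& q, int n_v, const std::vector<double>& vx,
                    const std::vector<double>& vw) {
  double ll = 0.0;
  for (int t : idx)
    ll += pc::conf_ll_trial(D, t, q.wc, q.wf, q.b, q.sd, q.flat, true,
                            n_v, vx, vw);
  return ll;
}

} // namespace

// [[Rcpp::export]]
List cpp_mcmc_hier(List data, int model, int J, NumericMatrix init_theta,
                   NumericVector init_mu, NumericVector init_tau,
                   double init_lsd, int n_warmup, int n_iter, int thin,
                   int n_u, double u_max, double sd_scale, double tau_scale,
                   double mu_prior_sd) {
  pc::ObsData D = build_obsdata(data, n_u, u_max);
  std::vector<double> vx, vw;
  int n_v = 8;  // simplified confidence likelihood is node-free; kept for API
  pc::gl01(n_v, vx, vw);
  int K = hier_K(model);
  if (init_theta.nrow() != J || init_theta.ncol() != K) stop("bad init_theta");

  std::vector<std::vector<int>> idx(J);
  for (int t = 0; t < D.n; ++t) {
    int j = D.part[t];
    if (j < 0 || j >= J) stop("participant index out of range");
    idx[j].push_back(t);
  }

  std::vector<double> theta((size_t)J * K), mu(K), tau(K);
  for (int j = 0; j < J; ++j)
    for (int k = 0; k < K; ++k) theta[(size_t)j * K + k] = init_theta(j, k);
  for (int k = 0; k < K; ++k) { mu[k] = init_mu[k]; tau[k] = init_tau[k]; }
  double lsd = init_lsd, sd = std::exp(lsd);

  std::vector<double> ll_choice(J), ll_conf(J);
  for (int j = 0; j < J; ++j) {
    Pars q = hier_unpack(model, &theta[(size_t)j * K], sd);
    ll_choice[j] = part_choice_ll(D, idx[j], q);
    ll_conf[j]   = part_conf_ll(D, idx[j], q, n_v, vx, vw);
  }

  // adaptation state
  std::vector<double> lg_part(J, std::log(0.25 / std::sqrt((double)K)));
  std::vector<double> lg_tau(K, std::log(0.5)), acc_count(3, 0.0);
  double lg_sd = std::log(0.2);
  int n_total = n_warmup + n_iter;
  int n_save = n_iter / thin;
  NumericMatrix group_draws(n_save, 2 * K + 1);
  NumericMatrix theta_draws(n_save, J * K);
  std::vector<double> prop(K);
  int save_row = 0;
  long part_prop = 0, part_acc = 0;

  for (int it = 0; it < n_total; ++it) {
    double rm = 1.0 / std::pow((double)(it + 1), 0.6);
    // --- participant blocks ---
    for (int j = 0; j < J; ++j) {
      double* th = &theta[(size_t)j * K];
      double step = std::exp(lg_part[j]);
      double lp0 = 0.0, lp1 = 0.0;
      for (int k = 0; k < K; ++k) {
        prop[k] = th[k] + step * R::norm_rand();
        lp0 += R::dnorm(th[k],  mu[k], tau[k], 1);
        lp1 += R::dnorm(prop[k], mu[k], tau[k], 1);
      }
      Pars qp = hier_unpack(model, prop.data(), sd);
      double lc = part_choice_ll(D, idx[j], qp);
      double lf = part_conf_ll(D, idx[j], qp, n_v, vx, vw);
      double a = std::min(1.0, std::exp(lc + lf + lp1 - ll_choice[j] - ll_conf[j] - lp0));
      ++part_prop;
      if (R::unif_rand() < a) {
        for (int k = 0; k < K; ++k) th[k] = prop[k];
        ll_choice[j] = lc; ll_conf[j] = lf; ++part_acc;
      }
      if (it < n_warmup) lg_part[j] += (a - 0.30) * rm;
    }
    // --- group means: conjugate Gibbs ---
    for (int k = 0; k < K; ++k) {
      double prec = (double)J / (tau[k] * tau[k]) + 1.0 / (mu_prior_sd * mu_prior_sd);
      double s = 0.0;
      for (int j = 0; j < J; ++j) s += theta[(size_t)j * K + k];
      double m = (s / (tau[k] * tau[k])) / prec;
      mu[k] = m + R::norm_rand() / std::sqrt(prec);
    }
    // --- group SDs: adaptive MH on log tau, half-normal(tau_scale) prior ---
    for (int k = 0; k < K; ++k) {
      double lt = std::log(tau[k]);
      double lt_p = lt + std::exp(lg_tau[k]) * R::norm_rand();
      double tp = std::exp(lt_p);
      double d0 = 0.0, d1 = 0.0;
      for (int j = 0; j < J; ++j) {
        double x = theta[(size_t)j * K + k];
        d0 += R::dnorm(x, mu[k], tau[k], 1);
        d1 += R::dnorm(x, mu[k], tp, 1);
      }
      d0 += -0.5 * (tau[k] / tau_scale) * (tau[k] / tau_scale) + lt;
      d1 += -0.5 * (tp / tau_scale) * (tp / tau_scale) + lt_p;
      double a = std::min(1.0, std::exp(d1 - d0));
      if (R::unif_rand() < a) tau[k] = tp;
      if (it < n_warmup) lg_tau[k] += (a - 0.44) * rm;
    }
    // --- shared report-noise SD ---
    {
      double lsd_p = lsd + std::exp(lg_sd) * R::norm_rand();
      double sd_p = std::exp(lsd_p);
      double new_total = 0.0;
      std::vector<double> lc_new(J);
      for (int j = 0; j < J; ++j) {
        Pars q = hier_unpack(model, &theta[(size_t)j * K], sd_p);
        lc_new[j] = part_conf_ll(D, idx[j], q, n_v, vx, vw);
        new_total += lc_new[j];
      }
      double old_total = 0.0;
      for (int j = 0; j < J; ++j) old_total += ll_conf[j];
      double pr0 = -0.5 * (sd / sd_scale) * (sd / sd_scale) + lsd;
      double pr1 = -0.5 * (sd_p / sd_scale) * (sd_p / sd_scale) + lsd_p;
      double a = std::min(1.0, std::exp(new_total + pr1 - old_total - pr0));
      if (R::unif_rand() < a) {
        lsd = lsd_p; sd = sd_p;
        for (int j = 0; j < J; ++j) ll_conf[j] = lc_new[j];
      }
      if (it < n_warmup) lg_sd += (a - 0.44) * rm;
    }
    // --- save ---
    if (it >= n_warmup && (it - n_warmup) % thin == 0 && save_row < n_save) {
      for (int k = 0; k < K; ++k) {
        group_draws(save_row, k) = mu[k];
        group_draws(save_row, K + k) = tau[k];
      }
      group_draws(save_row, 2 * K) = sd;
      for (int j = 0; j < J; ++j)
        for (int k = 0; k < K; ++k)
          theta_draws(save_row, j * K + k) = theta[(size_t)j * K + k];
      ++save_row;
    }
  }
  return List::create(_["group"] = group_draws, _["theta"] = theta_draws,
                      _["accept_part"] = (double)part_acc / (double)part_prop,
                      _["K"] = K);
}

// Pointwise log predictive density for held-out participants: for each
// posterior draw, new-participant parameters are drawn from the fitted
// group distribution (group-predictive integration), then per-trial
// likelihoods are averaged across draws on the log scale.
// [[Rcpp::export]]
NumericVector cpp_heldout_lpd(List data, int model, NumericMatrix group_draws,
                              int J_new, int n_u, double u_max) {
  pc::ObsData D = build_obsdata(data, n_u, u_max);
  std::vector<double> vx, vw;
  int n_v = 8;
  pc::gl01(n_v, vx, vw);
  int K = hier_K(model);
  int S = group_draws.nrow();
  if (group_draws.ncol() != 2 * K + 1) stop("bad group_draws");

  std::vector<std::vector<int>> idx(J_new);
  for (int t = 0; t < D.n; ++t) idx[D.part[t]].push_back(t);

  std::vector<double> mx(D.n, -INFINITY), sm(D.n, 0.0);
  std::vector<double> th(K);
  for (int s = 0; s < S; ++s) {
    double sd = group_draws(s, 2 * K);
    for (int j = 0; j < J_new; ++j) {
      for (int k = 0; k < K; ++k)
        th[k] = group_draws(s, k) + group_draws(s, K + k) * R::norm_rand();
      Pars q = hier_unpack(model, th.data(), sd);
      for (int t : idx[j]) {
        double ll = pc::choice_ll_trial(D, t, q.wc, q.flat, false) +
                    pc::conf_ll_trial(D, t, q.wc, q.wf, q.b, q.sd, q.flat,
                                      true, n_v, vx, vw);
        if (ll > mx[t]) {             // online log-sum-exp
          sm[t] = sm[t] * std::exp(mx[t] - ll) + 1.0;
          mx[t] = ll;
        } else {
          sm[t] += std::exp(ll - mx[t]);
        }
      }
    }
  }
  NumericVector lpd(D.n);
  for (int t = 0; t < D.n; ++t) lpd[t] = mx[t] + std::log(sm[t]) - std::log((double)S);
  return lpd;
}
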