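#include "priorconf_core.h"
using namespace Rcpp;

// Marginal probability of a rightward target choice (Eqs. of the observer
// model): composite Simpson quadrature over the latent magnitude
// u = |r_lead| on (0, upper], with the truncated-normal weight given the
// observed lead choice; weights self-normalized.
// [[Rcpp::export]]
NumericVector cpp_p_right_simpson(NumericVector s_lead, NumericVector s_target,
                                  IntegerVector lead_choice, double w_choice,
                                  int n_nodes, double upper) {
  if (n_nodes < 3 || n_nodes % 2 == 0) stop("n_nodes must be odd and >= 3");
  int n = s_lead.size();
  NumericVector out(n);
  double h = upper / (n_nodes - 1);
  std::vector<double> simp(n_nodes);
  for (int i = 0; i < n_nodes; ++i)
    simp[i] = (i == 0 || i == n_nodes - 1) ? 1.0 : (i % 2 == 1 ? 4.0 : 2.0);
  for (int t = 0; t < n; ++t) {
    double m = lead_choice[t] * s_lead[t];
    double num = 0.0, den = 0.0;
    for (int i = 0; i < n_nodes; ++i) {
      double u = i * h;
      double w = simp[i] * pc::phi_pdf(u - m);
      num += w * pc::Phi(s_target[t] + u / w_choice);
      den += w;
    }
    out[t] = num / den;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_simulate_trials(IntegerVector lead_dir, NumericVector lead_coh,
                         NumericVector target_coh,
                         double sigma, double bias,
                         double w_choice, double w_conf, double b,
                         double lapse, double metacog_sd, int metacog_family,
                         double report_sd) {
  // metacog_family: 0 none, 1 gaussian (additive on r), 2 lognormal
  // (multiplicative on |r|).
  int n = lead_dir.size();
  NumericVector r_lead(n), r_target(n), conf_model(n), conf_report(n);
  IntegerVector lead_choice(n), target_choice(n), target_dir(n);
  LogicalVector lead_correct(n), target_correct(n);
  for (int t = 0; t < n; ++t) {
    double s_l = (lead_dir[t] * lead_coh[t] - bias) / sigma;
    double rl = R::rnorm(s_l, 1.0);
    int cl = (rl > 0.0) ? 1 : (rl < 0.0 ? -1 : (R::unif_rand() < 0.5 ? 1 : -1));
    if (lapse > 0.0 && R::unif_rand() < lapse)
      cl = (R::unif_rand() < 0.5) ? 1 : -1;
    bool corr1 = (cl == lead_dir[t]);
    int td = corr1 ? 1 : -1;
    double s_t = (td * target_coh[t] - bias) / sigma;
    double rt = R::rnorm(s_t, 1.0);
    double theta = -std::fabs(rl) / w_choice;
    int ct = (rt > theta) ? 1 : -1;
    if (lapse > 0.0 && R::unif_rand() < lapse)
      ct = (R::unif_rand() < 0.5) ? 1 : -1;
    bool corr2 = (ct == td);

    double rl_c = rl, rt_c = rt;
    if (metacog_family == 1 && metacog_sd > 0.0) {
      rl_c += R::rnorm(0.0, metacog_sd);
      rt_c += R::rnorm(0.0, metacog_sd);
    } else if (metacog_family == 2 && metacog_sd > 0.0) {
      rl_c = ((rl_c >= 0) ? 1.0 : -1.0) * std::fabs(rl_c) * std::exp(R::rnorm(0.0, metacog_sd));
      rt_c = ((rt_c >= 0) ? 1.0 : -1.0) * std::fabs(rt_c) * std::exp(R::rnorm(0.0, metacog_sd));
    }
    double p_prior = pc::Phi(std::fabs(rl_c) / (b * w_conf));
    double p_like  = pc::Phi(rt_c / b);
    double cr = pc::bayes_conf_right(p_prior, p_like);
    double cm = (ct > 0) ? cr : 1.0 - cr;
    double mu = cm;
    if (mu < 0.5) mu = 0.5;
    if (mu > 1.0) mu = 1.0;
    double rep = mu;
    if (report_sd > 0.0) {
      // truncated-Gaussian report noise on [0.5, 1] via inverse CDF
      double pl = pc::Phi((0.5 - mu) / report_sd);
      double pu = pc::Phi((1.0 - mu) / report_sd);
      double uu = pl + R::unif_rand() * (pu - pl);
      rep = mu + report_sd * pc::qnorm_fast(uu);
      if (rep < 0.5) rep = 0.5;
      if (rep > 1.0) rep = 1.0;
    }
    r_lead[t] = rl; r_target[t] = rt;
    lead_choice[t] = cl; target_choice[t] = ct; target_dir[t] = td;
    lead_correct[t] = corr1; target_correct[t] = corr2;
    conf_model[t] = cm; conf_report[t] = rep;
  }
  return List::create(_["r_lead"] = r_lead, _["lead_choice"] = lead_choice,
                      _["lead_correct"] = lead_correct,
                      _["target_dir"] = target_dir, _["r_target"] = r_target,
                      _["target_choice"] = target_choice,
                      _["target_correct"] = target_correct,
                      _["conf_model"] = conf_model,
                      _["conf_report"] = conf_report);
}

static pc::ObsData build_obsdata(List data, int n_u, double u_max) {
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

// Per-trial choice and confidence log-likelihood components for a single
// parameter set. Used by the R wrappers, the MAP optimizer and the tests.
// [[Rcpp::export]]
List cpp_dataset_loglik(List data, double w_choice, double w_conf, double b,
                        double sd_report, bool flat_prior, bool simplified,
                        int n_u, int n_v, double u_max) {
  pc::ObsData D = build_obsdata(data, n_u, u_max);
  std::vector<double> vx, vw;
  pc::gl01(n_v, vx, vw);
  NumericVector ll_choice(D.n), ll_conf(D.n);
  for (int t = 0; t < D.n; ++t) {
    ll_choice[t] = pc::choice_ll_trial(D, t, w_choice, flat_prior, simplified);
    ll_conf[t]   = pc::conf_ll_trial(D, t, w_choice, w_conf, b, sd_report,
                                     flat_prior, simplified, n_v, vx, vw);
  }
  return List::create(_["choice"] = ll_choice, _["conf"] = ll_conf);
}
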