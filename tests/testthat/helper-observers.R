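# Shared fixture builders; everything is generated in code at test time.

# Minimal trial rows for likelihood-level tests.
make_trial_tbl <- function(s_lead, s_target, lead_choice = 1L,
                           target_choice = 1L, conf = 0.8,
                           target_dir = sign(s_target),
                           participant = "P") {
  k <- max(length(s_lead), length(s_target), length(lead_choice),
           length(target_choice), length(conf))
  tibble::tibble(
    participant = participant,
    s_lead = rep_len(s_lead, k), s_target = rep_len(s_target, k),
    lead_level = "M", target_level = "M",
    target_dir = as.integer(rep_len(target_dir, k)),
    lead_choice = as.integer(rep_len(lead_choice, k)),
    target_choice = as.integer(rep_len(target_choice, k)),
    conf_report = rep_len(conf, k),
    lead_dir = 1L, lead_coh = 0.1, target_coh = 0.1)
}

# Small calibrated cohort used by several fitting tests.
make_cohort_trials <- function(n_participants, n_blocks = 10, sessions = 1,
                               group = list(w_choice = 2.17, w_conf = 1.27,
                                            b = 2.18),
                               sd_log = 0.3, seed = 1) {
  cohort <- priorconf:::draw_cohort_params(n_participants, group = group,
                                           sd_log = sd_log)
  ds <- generate_dataset(cohort,
                         design = experiment_design(sessions = sessions,
                                                    n_blocks = n_blocks),
                         seed = seed)
  calib <- calibrate_participants(ds$main, ds$control)
  list(trials = normalize_dataset(ds$main, calib), calib = calib,
       cohort = cohort, dataset = ds)
}

# Monte-Carlo oracle for the marginal rightward-choice probability:
# draws |r_lead| from the truncated normal implied by the lead choice via
# inverse-CDF sampling and averages the exact inner Phi.
mc_p_right <- function(s_lead, s_target, lead_choice, w_choice, n_draws) {
  m <- lead_choice * s_lead
  u <- qnorm(runif(n_draws) * (1 - pnorm(-m)) + pnorm(-m)) + m
  mean(pnorm(s_target + u / w_choice))
}
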