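#' Normalize stimulus strength into internal-noise units
#'
#' Transforms a signed coherence into the observer's internal evidence
#' scale, `s = (direction * coherence - bias) / sigma`. After this
#' transformation internal noise is 1 in all downstream computations.
#'
#' @param stim A [stimulus_spec()], or a numeric vector of directions if
#'   `coherence` is supplied.
#' @param coherence Coherence values (used when `stim` is a direction
#'   vector).
#' @param sigma Internal noise (stimulus units), > 0.
#' @param bias Decision bias (stimulus units).
#' @return Normalized strength(s) `s`.
#' @examples
#' normalize_stimulus(stimulus_spec(1, 0.15), sigma = 0.1)  # 1.5
#' @export
normalize_stimulus <- function(stim, coherence = NULL, sigma, bias = 0) {
  if (sigma <= 0) stop("sigma must be > 0")
  if (inherits(stim, "stimulus_spec")) {
    direction <- stim$direction
    coherence <- stim$coherence
  } else {
    direction <- stim
    if (is.null(coherence)) stop("coherence required when stim is a direction vector")
  }
  (direction * coherence - bias) / sigma
}

#' Confidence in the lead decision
#'
#' Posterior probability that the lead choice (the sign of `r_lead`) is
#' correct, under unit internal noise and a flat prior: `Phi(|r_lead|)`.
#' Always at least 0.5.
#'
#' @param r_lead Internal lead response(s), normalized units.
#' @return Probability in `[0.5, 1)`.
#' @export
lead_confidence <- function(r_lead) {
  stopifnot(all(is.finite(r_lead)))
  pnorm(abs(r_lead))
}

#' Criterion shift induced by the lead response
#'
#' The target-decision criterion is shifted proportionally to the weighted
#' prior: `theta = -|r_lead| / w_choice`. The shift is never positive
#' because the task rule makes the prior point rightward; the target choice
#' is "right" iff `r_target > theta`.
#'
#' @param r_lead Internal lead response(s).
#' @param w_choice Prior weighting in the decision, > 0.
#' @return Criterion value(s) `theta <= 0`.
#' @export
shifted_criterion <- function(r_lead, w_choice) {
  if (any(w_choice <= 0)) stop("w_choice must be > 0")
  -abs(r_lead) / w_choice
}

#' Marginal probability of a rightward target choice
#'
#' Integrates the probability that the internal target response exceeds the
#' shifted criterion against the truncated-normal density of the lead
#' response implied by the observed lead choice (truncation to
#' `r_lead > 0` after a rightward lead choice, `r_lead < 0` after a
#' leftward one). Composite Simpson quadrature over `|r_lead|` on
#' `(0, upper]` with self-normalized weights; the default 201 nodes agree
#' with a refined rule to well below 1e-6 for normalized strengths up to
#' about 4.
#'
#' @param s_lead,s_target Signed normalized strengths (recycled).
#' @param lead_choice Observed lead choice(s), -1 or +1.
#' @param w_choice Prior weighting in the decision, > 0.
#' @param n_nodes Odd number of quadrature nodes (>= 201 by default).
#' @param upper Upper integration limit for `|r_lead|`.
#' @return Probability of a rightward target choice, in (0, 1).
#' @export
p_right_target <- function(s_lead, s_target, lead_choice, w_choice,
                           n_nodes = 201, upper = 8) {
  if (w_choice <= 0) stop("w_choice must be > 0")
  if (!all(lead_choice %in% c(-1, 1))) stop("lead_choice must be -1 or +1")
  k <- max(length(s_lead), length(s_target), length(lead_choice))
  s_lead <- rep_len(s_lead, k); s_target <- rep_len(s_target, k)
  lead_choice <- rep_len(as.integer(lead_choice), k)
  cpp_p_right_simpson(s_lead, s_target, lead_choice, w_choice, n_nodes, upper)
}

#' Weighted prior entering the confidence computation
#'
#' The rightward prior used in confidence equals the lead decision
#' confidence with the prior variance misestimated by `b * w_conf`:
#' `Phi(|r_lead| / (b * w_conf))`.
#'
#' @param r_lead Internal lead response(s).
#' @param b Confidence bias, > 0.
#' @param w_conf Prior weighting in confidence, > 0.
#' @return Probability in `[0.5, 1)`.
#' @export
confidence_prior <- function(r_lead, b, w_conf) {
  if (any(b <= 0)) stop("b must be > 0")
  if (any(w_conf <= 0)) stop("w_conf must be > 0")
  pnorm(abs(r_lead) / (b * w_conf))
}

#' Likelihood of the target response under a rightward stimulus
#'
#' `Phi(r_target / b)`: the perceived probability of the internal target
#' response given a rightward target stimulus, with the likelihood variance
#' misestimated by the confidence bias `b`.
#'
#' @param r_target Internal target response(s).
#' @param b Confidence bias, > 0.
#' @return Probability in (0, 1).
#' @export
confidence_likelihood <- function(r_target, b) {
  if (any(b <= 0)) stop("b must be > 0")
  pnorm(r_target / b)
}

#' Bayes combination of prior and likelihood for a rightward choice
#'
#' `conf_right = p_prior * p_like / ((1 - p_prior) (1 - p_like) +
#' p_prior * p_like)`. Confidence in a leftward choice is one minus this
#' value. Inputs at exactly 0 or 1 are clamped to `[1e-9, 1 - 1e-9]` with a
#' warning.
#'
#' @param p_prior Rightward prior probability(ies).
#' @param p_like Rightward likelihood value(s).
#' @return Posterior confidence in a rightward choice.
#' @export
posterior_confidence_right <- function(p_prior, p_like) {
  eps <- .pc_prob_eps
  if (any(p_prior <= 0 | p_prior >= 1) || any(p_like <= 0 | p_like >= 1)) {
    warning("probabilities at 0 or 1 clamped to [",
            format(eps), ", 1 - ", format(eps), "]")
    p_prior <- clamp(p_prior, eps, 1 - eps)
    p_like <- clamp(p_like, eps, 1 - eps)
  }
  num <- p_prior * p_like
  num / ((1 - p_prior) * (1 - p_like) + num)
}

#' Simulate dual-decision trials from the observer model
#'
#' Each trial: the lead stimulus generates an internal response
#' `r_lead ~ N(s_lead, 1)`; the lead choice is its sign (ties broken by a
#' fair coin). The task rule sets the target direction: rightward iff the
#' lead choice was correct. The target response is drawn, the target choice
#' compares it to the shifted criterion, and confidence is the Bayes
#' combination of the weighted prior and likelihood (computed on
#' metacognitively noised responses if requested). Lapses replace each
#' choice by a coin flip with probability `lapse`. Model confidence in the
#' chosen option is clipped to `[0.5, 1]` for the report scale (the
#' pre-clip value is retained in `conf_model`) and truncated-Gaussian
#' report noise is added.
#'
#' @param params An [observer_params()].
#' @param lead_dir Vector of lead directions (-1/+1).
#' @param lead_coh Vector of lead coherences.
#' @param target_coh Vector of target coherences (magnitudes; the direction
#'   follows from the task rule).
#' @param seed Optional integer seed.
#' @return A tibble with one row per trial: internal responses, choices,
#'   accuracies, target direction, `conf_model` (pre-clip confidence in the
#'   chosen target response) and `conf_report` on `[0.5, 1]`.
#' @examples
#' p <- observer_params()
#' simulate_trials(p, lead_dir = c(1, -1), lead_coh = 0.15,
#'                 target_coh = 0.15, seed = 1)
#' @export
simulate_trials <- function(params, lead_dir, lead_coh, target_coh,
                            seed = NULL) {
  stopifnot(inherits(params, "observer_params"))
  if (!all(lead_dir %in% c(-1, 1))) stop("lead_dir must be -1 or +1")
  n <- max(length(lead_dir), length(lead_coh), length(target_coh))
  lead_dir <- rep_len(as.integer(lead_dir), n)
  lead_coh <- rep_len(lead_coh, n)
  target_coh <- rep_len(target_coh, n)
  fam <- match(params$metacog_noise_family, c("none", "gaussian", "lognormal")) - 1L
  sim <- with_seed_if(seed,
    cpp_simulate_trials(lead_dir, lead_coh, target_coh,
                        params$sigma, params$bias, params$w_choice,
                        params$w_conf, params$b, params$lapse,
                        params$metacog_noise_sd, fam, params$report_noise_sd))
  tibble::tibble(
    lead_dir = lead_dir, lead_coh = lead_coh,
    target_dir = sim$target_dir, target_coh = target_coh,
    r_lead = sim$r_lead, r_target = sim$r_target,
    lead_choice = sim$lead_choice, target_choice = sim$target_choice,
    lead_correct = sim$lead_correct, target_correct = sim$target_correct,
    conf_model = sim$conf_model, conf_report = sim$conf_report)
}

#' @rdname simulate_trials
#' @param lead_stim A [stimulus_spec()] for the lead stimulus.
#' @param target_coh_single Target coherence for the single trial.
#' @export
simulate_trial <- function(params, lead_stim, target_coh_single, seed = NULL) {
  stopifnot(inherits(lead_stim, "stimulus_spec"))
  simulate_trials(params, lead_stim$direction, lead_stim$coherence,
                  target_coh_single, seed = seed)
}
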