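#' Trial-wise choice log-likelihood
#'
#' Log-probability of each observed target choice under the observer model.
#' The full version marginalizes the lead response over the truncated
#' normal implied by the observed lead choice; the simplified version
#' substitutes the level-mean internal signal (the hierarchical-model
#' simplification). For the `flat_prior` variant the probability is
#' exactly `Phi(+/- s_target)`.
#'
#' @param trials Trial tibble with normalized strengths (`s_lead`,
#'   `s_target`) and observed choices.
#' @param params Named list or vector with `w_choice` (ignored for
#'   `flat_prior`).
#' @param spec A [model_spec()] (default flexible).
#' @param simplified Use the level-mean simplification?
#' @param n_u Number of Gauss-Legendre nodes for the marginalization.
#' @return Numeric vector of per-trial log-probabilities.
#' @export
choice_loglik <- function(trials, params, spec = model_spec("flexible"),
                          simplified = FALSE, n_u = 32) {
  d <- pc_model_data(trials)
  ll <- cpp_dataset_loglik(d, w_choice = params[["w_choice"]] %||% 1,
                           w_conf = 1, b = 1, sd_report = 0.1,
                           flat_prior = spec$name == "flat_prior",
                           simplified = simplified,
                           n_u = n_u, n_v = 4, u_max = 8)
  ll$choice
}

#' Trial-wise confidence-report log-likelihood
#'
#' Log-density of each observed confidence report. Model confidence is the
#' Bayes combination of the weighted prior and likelihood; the observation
#' model is a truncated Gaussian on `[0.5, 1]` around (clipped) model
#' confidence with SD `sd_report`. The full version integrates over the
#' internal responses consistent with the observed choices; the simplified
#' version plugs in level-mean signals on the true-direction side, which
#' systematically underestimates confidence.
#'
#' @inheritParams choice_loglik
#' @param params Named list/vector with `w_choice`, `w_conf`, `b`,
#'   `sd_report` (free parameters irrelevant to the variant are ignored).
#' @param n_v Inner quadrature nodes for the target-response integral.
#' @return Numeric vector of per-trial log-densities.
#' @export
confidence_loglik <- function(trials, params, spec = model_spec("flexible"),
                              simplified = FALSE, n_u = 24, n_v = 16) {
  if ((params[["sd_report"]] %||% 0) <= 0)
    stop("sd_report must be > 0 (zero-width report noise)")
  d <- pc_model_data(trials)
  p <- resolve_params(params, spec)
  ll <- cpp_dataset_loglik(d, p$w_choice, p$w_conf, p$b, p$sd_report,
                           flat_prior = spec$name == "flat_prior",
                           simplified = simplified,
                           n_u = n_u, n_v = n_v, u_max = 8)
  ll$conf
}

#' Total dataset log-likelihood (choices + confidence)
#'
#' @inheritParams confidence_loglik
#' @return List with per-trial `choice` and `conf` log-likelihood vectors
#'   and their `total`.
#' @export
dataset_loglik <- function(trials, params, spec = model_spec("flexible"),
                           simplified = FALSE, n_u = 24, n_v = 16) {
  d <- pc_model_data(trials)
  p <- resolve_params(params, spec)
  ll <- cpp_dataset_loglik(d, p$w_choice, p$w_conf, p$b, p$sd_report,
                           flat_prior = spec$name == "flat_prior",
                           simplified = simplified,
                           n_u = n_u, n_v = n_v, u_max = 8)
  list(choice = ll$choice, conf = ll$conf,
       total = sum(ll$choice) + sum(ll$conf))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Expand variant constraints into the full parameter set.
resolve_params <- function(params, spec) {
  g <- function(nm, default = NULL) {
    v <- tryCatch(params[[nm]], error = function(e) NULL)
    if (is.null(v) || length(v) == 0 || is.na(v)) default else v
  }
  switch(spec$name,
    flexible = list(w_choice = g("w_choice", 1), w_conf = g("w_conf", 1),
                    b = g("b", 1), sd_report = g("sd_report", 0.1)),
    flat_prior = list(w_choice = 1, w_conf = 1, b = g("b", 1),
                      sd_report = g("sd_report", 0.1)),
    optimal = list(w_choice = 1, w_conf = 1, b = g("b", 1),
                   sd_report = g("sd_report", 0.1)),
    equal = {
      w <- g("w", g("w_choice", 1))
      list(w_choice = w, w_conf = w, b = g("b", 1),
           sd_report = g("sd_report", 0.1))
    })
}
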