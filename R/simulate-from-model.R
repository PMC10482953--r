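#' Simulate responses from a fitted model's own likelihood
#'
#' Replaces the choices and confidence reports in a trial table with draws
#' from the observation model a given variant actually fits: the lead
#' choice is Bernoulli with probability `Phi(s_lead)`, the target direction
#' follows the task rule, the target choice follows the marginalized choice
#' probability, and the confidence report is a truncated Gaussian around
#' the (clipped) level-mean model confidence. This is the generative
#' process implied by the hierarchical likelihood itself (including its
#' simplification), as used for model-recovery analyses; contrast with
#' [generate_dataset()], which simulates the full latent-response observer.
#'
#' @param trials Trial tibble with stimuli and normalized strengths
#'   (`s_lead`, `s_target`, level labels, `lead_dir`).
#' @param params_by_participant Tibble with `participant`, `w_choice`,
#'   `w_conf`, `b` columns (ignored entries may be NA for constrained
#'   variants).
#' @param spec A [model_spec()].
#' @param sd_report Report-noise SD.
#' @param seed Optional integer seed.
#' @return The trial tibble with regenerated `lead_choice`,
#'   `lead_correct`, `target_dir`, `target_choice`, `target_correct`,
#'   `conf_report` and re-signed `s_target`.
#' @export
simulate_from_model <- function(trials, params_by_participant,
                                spec = model_spec("flexible"),
                                sd_report = 0.1, seed = NULL) {
  stopifnot(all(c("s_lead", "s_target", "lead_dir") %in% names(trials)))
  with_seed_if(seed, {
    out <- trials
    # lead choice from the prior-free psychometric implied by s_lead
    p_lead_right <- pnorm(out$s_lead)
    out$lead_choice <- ifelse(runif(nrow(out)) < p_lead_right, 1L, -1L)
    out$lead_correct <- out$lead_choice == out$lead_dir
    out$target_dir <- ifelse(out$lead_correct, 1L, -1L)
    out$s_target <- out$target_dir * abs(out$s_target)

    ids <- unique(out$participant)
    pp <- params_by_participant
    for (id in ids) {
      sel <- out$participant == id
      row <- pp[pp$participant == id, ]
      pars <- resolve_params(as.list(row), spec)
      if (spec$name == "flat_prior") {
        p_right <- pnorm(out$s_target[sel])
      } else {
        p_right <- cpp_p_right_simpson(out$s_lead[sel], out$s_target[sel],
                                       out$lead_choice[sel], pars$w_choice,
                                       201L, 8)
      }
      out$target_choice[sel] <- ifelse(runif(sum(sel)) < p_right, 1L, -1L)
      # level-mean confidence, exactly as the simplified likelihood defines
      sub <- out[sel, ]
      mu_lead <- tapply(abs(sub$s_lead), sub$lead_level, mean)
      mu_target <- tapply(abs(sub$s_target), sub$target_level, mean)
      m_lead <- as.numeric(mu_lead[sub$lead_level])
      rbar_t <- sub$target_dir * as.numeric(mu_target[sub$target_level])
      p_prior <- if (spec$name == "flat_prior") 0.5 else
        pnorm(m_lead / (pars$b * pars$w_conf))
      p_like <- pnorm(rbar_t / pars$b)
      cr <- posterior_confidence_right(clamp(p_prior, 1e-9, 1 - 1e-9),
                                       clamp(p_like, 1e-9, 1 - 1e-9))
      mu <- ifelse(out$target_choice[sel] > 0, cr, 1 - cr)
      mu <- clamp(mu, 0.5, 1)
      pl <- pnorm((0.5 - mu) / sd_report)
      pu <- pnorm((1 - mu) / sd_report)
      u <- pl + runif(length(mu)) * (pu - pl)
      out$conf_report[sel] <- clamp(mu + sd_report * qnorm(u), 0.5, 1)
    }
    out$target_correct <- out$target_choice == out$target_dir
    out
  })
}
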