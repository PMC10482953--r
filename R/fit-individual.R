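#' Fit a model variant to one participant by MCMC
#'
#' Posterior sampling over the variant's free parameters using the full
#' (non-simplified) likelihood: the choice term marginalizes the lead
#' response and the confidence term integrates over both internal responses
#' consistent with the observed choices. Sampling is joint adaptive
#' random-walk Metropolis on log-scale parameters, initialized at the
#' posterior mode; priors are lognormal(0, 1) on weighting/bias parameters
#' and half-normal(0.15) on the report-noise SD.
#'
#' @param trials Trial tibble for a single participant. If `s_lead` /
#'   `s_target` are absent, `calibration` must be supplied to normalize.
#' @param spec A [model_spec()].
#' @param calibration Optional calibration tibble (see
#'   [calibrate_participants()]).
#' @param seed Optional integer seed.
#' @param chains,iter,warmup MCMC configuration (per chain).
#' @param conf_simplified Use the level-mean confidence simplification
#'   instead of the full integral (mainly for comparisons).
#' @param n_u,n_v Quadrature nodes (lead-response and target-response
#'   integrals).
#' @return A `pc_fit` object: posterior `draws` (natural scale), a
#'   `summary` tibble (mean, SD, MCSE, 89% CI, split R-hat), `converged`
#'   flag (all R-hat < 1.1), and the sampler configuration.
#' @export
fit_individual <- function(trials, spec = model_spec("flexible"),
                           calibration = NULL, seed = NULL,
                           chains = 2, iter = 500, warmup = 500,
                           conf_simplified = FALSE, n_u = 12, n_v = 8) {
  stopifnot(inherits(spec, "model_spec"))
  if (!all(c("s_lead", "s_target") %in% names(trials))) {
    if (is.null(calibration))
      stop("trials lack normalized strengths; supply `calibration`")
    trials <- normalize_dataset(trials, calibration)
  }
  if (length(unique(trials$participant)) != 1)
    stop("fit_individual expects trials from a single participant")
  if (nrow(trials) < 200)
    warning("fewer than 200 trials; individual estimates will be unstable")
  d <- pc_model_data(trials)
  np <- length(spec$free)
  sd_scale <- 0.15

  with_seed_if(seed, {
    # posterior mode for initialization
    negpost <- function(p) -cpp_logpost_individual(d, spec$code, p,
                                                   conf_simplified, n_u, n_v,
                                                   8, sd_scale)
    init0 <- c(rep(0, np - 1), log(0.1))
    map <- tryCatch(
      optim(init0, negpost, method = "Nelder-Mead",
            control = list(maxit = 150, reltol = 1e-6)),
      error = function(e) list(par = init0))
    chains_raw <- lapply(seq_len(chains), function(ch) {
      init <- map$par + rnorm(np, 0, 0.05)
      res <- cpp_mcmc_individual(d, spec$code, init, warmup, iter,
                                 conf_simplified, n_u, n_v, 8, sd_scale)
      m <- res$draws
      colnames(m) <- spec$free
      attr(m, "accept") <- res$accept
      m
    })
    new_pc_fit(spec, chains_raw, level = "individual",
               participant = unique(trials$participant),
               config = list(chains = chains, iter = iter, warmup = warmup,
                             n_u = n_u, n_v = n_v, seed = seed,
                             conf_simplified = conf_simplified))
  })
}

# Build the pc_fit container from per-chain log-scale draw matrices.
new_pc_fit <- function(spec, chains_raw, level, participant = NULL,
                       config = list(), extra = list()) {
  summ <- summarize_chains(chains_raw, natural = exp)
  draws <- exp(do.call(rbind, chains_raw))
  converged <- all(summ$rhat < 1.1)
  if (!converged)
    warning("fit flagged: split R-hat >= 1.1 for ",
            paste(summ$parameter[summ$rhat >= 1.1], collapse = ", "))
  structure(c(list(level = level, spec = spec, participant = participant,
                   draws = draws, summary = summ, converged = converged,
                   accept = mean(vapply(chains_raw, attr, 0, "accept")),
                   config = config),
              extra),
            class = "pc_fit")
}

#' @export
print.pc_fit <- function(x, ...) {
  cat(sprintf("<pc_fit> %s model, %s level%s\n", x$spec$name, x$level,
              if (!is.null(x$participant)) paste0(" (", x$participant, ")") else ""))
  print(as.data.frame(x$summary), digits = 3, row.names = FALSE)
  if (!x$converged) cat("** flagged: split R-hat >= 1.1 **\n")
  invisible(x)
}

#' Posterior mean point estimates of a fit
#'
#' @param fit A `pc_fit`.
#' @return Named numeric vector of posterior means.
#' @export
point_estimates <- function(fit) {
  stopifnot(inherits(fit, "pc_fit"))
  setNames(fit$summary$mean, fit$summary$parameter)
}
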