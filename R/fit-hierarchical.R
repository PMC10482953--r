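#' Fit a model variant hierarchically across participants
#'
#' Participant-level log-parameters are drawn from group-level normal
#' distributions (`theta_jk ~ N(mu_k, tau_k)`); the group location is
#' reported on the natural scale as `exp(mu_k)` (the population median of
#' the lognormal). The confidence likelihood uses the level-mean
#' simplification — internal signals are replaced by the mean normalized
#' strength of each coherence level on the true-direction side — which
#' keeps the trial-level latent responses out of the parameter vector; the
#' choice likelihood remains the full marginalization. A single
#' report-noise SD is shared across participants. Sampling is
#' Metropolis-within-Gibbs (conjugate Gibbs for `mu_k`; adaptive Metropolis
#' for participant blocks, `tau_k` and the report SD).
#'
#' @param trials Multi-participant trial tibble with `s_lead`/`s_target`
#'   (see [normalize_dataset()]).
#' @param spec A [model_spec()].
#' @param calibration Optional calibration tibble used to normalize if
#'   needed.
#' @param seed Optional integer seed.
#' @param chains,iter,warmup,thin MCMC configuration per chain.
#' @param n_u Gauss-Legendre nodes for the choice marginalization.
#' @return A `pc_fit` with group-level draws (`w_*` columns are `exp(mu)`,
#'   `tau_*` the group SDs on the log scale, plus `sd_report`), plus
#'   participant-level draws in `$theta` and ids in `$participants`.
#' @export
fit_hierarchical <- function(trials, spec = model_spec("flexible"),
                             calibration = NULL, seed = NULL,
                             chains = 2, iter = 600, warmup = 600, thin = 1,
                             n_u = 16) {
  stopifnot(inherits(spec, "model_spec"))
  if (!all(c("s_lead", "s_target") %in% names(trials))) {
    if (is.null(calibration))
      stop("trials lack normalized strengths; supply `calibration`")
    trials <- normalize_dataset(trials, calibration)
  }
  d <- pc_model_data(trials)
  J <- length(d$ids)
  if (J < 2) stop("hierarchical fit needs at least 2 participants")
  K <- length(spec$hier_free)

  with_seed_if(seed, {
    chains_group <- list(); chains_theta <- list()
    for (ch in seq_len(chains)) {
      init_theta <- matrix(rnorm(J * K, 0, 0.2), J, K)
      init_mu <- rnorm(K, 0, 0.2)
      init_tau <- rep(0.3, K)
      res <- cpp_mcmc_hier(d, spec$code, J, init_theta, init_mu, init_tau,
                           log(0.1), warmup, iter, thin, n_u, 8,
                           0.15, 1, 1)
      g <- res$group
      colnames(g) <- c(paste0("mu_", spec$hier_free),
                       paste0("tau_", spec$hier_free), "sd_report")
      attr(g, "accept") <- res$accept_part
      chains_group[[ch]] <- g
      chains_theta[[ch]] <- res$theta
    }
    # summaries: natural scale for locations (exp mu), identity for tau/sd
    group_log <- lapply(chains_group, function(g) {
      m <- g
      for (k in seq_len(K)) m[, K + k] <- log(m[, K + k])
      m[, 2 * K + 1] <- log(m[, 2 * K + 1])
      m
    })
    summ <- summarize_chains(group_log, natural = exp)
    summ$parameter <- c(spec$hier_free, paste0("tau_", spec$hier_free),
                        "sd_report")
    draws <- do.call(rbind, chains_group)
    draws_nat <- draws
    for (k in seq_len(K)) draws_nat[, k] <- exp(draws[, k])
    colnames(draws_nat) <- summ$parameter
    converged <- all(summ$rhat < 1.1)
    if (!converged)
      warning("fit flagged: split R-hat >= 1.1 for ",
              paste(summ$parameter[summ$rhat >= 1.1], collapse = ", "))
    structure(list(level = "hierarchical", spec = spec,
                   participants = d$ids,
                   draws = draws_nat, group_draws_raw = draws,
                   theta = do.call(rbind, chains_theta),
                   summary = summ, converged = converged,
                   accept = mean(vapply(chains_group, attr, 0, "accept")),
                   config = list(chains = chains, iter = iter,
                                 warmup = warmup, thin = thin, n_u = n_u,
                                 seed = seed)),
              class = "pc_fit")
  })
}

#' Posterior distribution of a difference between group parameters
#'
#' Computed draw-wise (e.g. `w_choice - w_conf`) with an 89% equal-tailed
#' credible interval.
#'
#' @param fit A hierarchical `pc_fit`.
#' @param par1,par2 Parameter names on the natural scale.
#' @return List with `draws`, `mean`, `ci89` and `prob_positive`.
#' @export
group_difference <- function(fit, par1 = "w_choice", par2 = "w_conf") {
  stopifnot(inherits(fit, "pc_fit"), fit$level == "hierarchical")
  d <- fit$draws[, par1] - fit$draws[, par2]
  list(draws = d, mean = mean(d),
       ci89 = unname(quantile(d, c(0.055, 0.945))),
       prob_positive = mean(d > 0))
}

#' Exclude outlying participants from group-level analysis
#'
#' Iteratively removes participants whose point estimate of any weighting
#' parameter lies more than `threshold` SDs from the group mean (one
#' participant per iteration, the most extreme first). The mean and SD for
#' each participant's z-score are computed leaving that participant out:
#' with contaminated statistics a single outlier can never exceed
#' `(n-1)/sqrt(n)` SDs, so an include-self rule could not fire at any
#' realistic threshold. Deterministic and invariant to participant
#' ordering.
#'
#' @param fits List of individual `pc_fit` objects (or a tibble with a
#'   `participant` column and one column per weighting parameter).
#' @param threshold Exclusion threshold in group SDs (default 6).
#' @return List with `retained` ids and an `excluded` tibble logging each
#'   exclusion (participant, parameter, z-score).
#' @export
exclude_outliers <- function(fits, threshold = 6) {
  if (is.data.frame(fits)) {
    est <- fits
  } else {
    est <- dplyr::bind_rows(lapply(fits, function(f) {
      pe <- point_estimates(f)
      keep <- intersect(names(pe), c("w_choice", "w_conf", "w"))
      tibble::tibble(participant = f$participant, !!!as.list(pe[keep]))
    }))
  }
  pars <- setdiff(names(est), "participant")
  retained <- est
  excluded <- tibble::tibble(participant = character(), parameter = character(),
                             z = numeric())
  repeat {
    if (nrow(retained) < 3) break
    zmat <- sapply(pars, function(p) {
      x <- retained[[p]]
      vapply(seq_along(x), function(i) {
        rest <- x[-i]
        s <- sd(rest)
        if (!is.finite(s) || s < 1e-12) 0 else abs(x[i] - mean(rest)) / s
      }, 0)
    })
    zmat <- matrix(zmat, nrow = nrow(retained))
    worst <- which(zmat == max(zmat), arr.ind = TRUE)[1, ]
    if (max(zmat) <= threshold) break
    excluded <- dplyr::bind_rows(excluded, tibble::tibble(
      participant = retained$participant[worst[1]],
      parameter = pars[worst[2]], z = max(zmat)))
    retained <- retained[-worst[1], ]
  }
  list(retained = retained$participant, excluded = excluded)
}
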