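#' Parameter-recovery study
#'
#' Simulates one synthetic observer per row of `true_params` through the
#' complete pipeline (experiment generation with live staircases,
#' psychometric calibration from prior-free decisions, individual MCMC
#' fit), and tabulates recovery quality per parameter: bias, RMSE and
#' Spearman rank correlation between true and recovered values.
#'
#' @param true_params Data frame with columns `w_choice`, `w_conf`, `b`
#'   (one row per synthetic observer); other [observer_params()] fields
#'   may be supplied as columns too.
#' @param trials_per_obs Main-task trials per observer (multiple of 36).
#' @param seed Integer seed.
#' @param spec Model variant to fit (default flexible).
#' @param chains,iter,warmup,n_u,n_v Passed to [fit_individual()].
#' @return A `pc_recovery` object with the true-vs-recovered `table`,
#'   per-parameter `metrics`, and the list of flagged (non-converged)
#'   observers.
#' @export
parameter_recovery_study <- function(true_params, trials_per_obs = 720,
                                     seed = NULL,
                                     spec = model_spec("flexible"),
                                     chains = 2, iter = 400, warmup = 400,
                                     n_u = 12, n_v = 8) {
  stopifnot(is.data.frame(true_params), nrow(true_params) >= 1,
            trials_per_obs %% 36 == 0)
  n_obs <- nrow(true_params)
  with_seed_if(seed, {
    rows <- list(); flagged <- character()
    for (i in seq_len(n_obs)) {
      tp <- as.list(true_params[i, , drop = FALSE])
      known <- intersect(names(tp), names(formals(observer_params)))
      par_i <- do.call(observer_params, tp[known])
      design <- experiment_design(sessions = 2,
                                  n_blocks = trials_per_obs / 72)
      ds <- generate_dataset(list(par_i), design = design)
      calib <- calibrate_participants(ds$main, ds$control)
      trials <- normalize_dataset(ds$main, calib)
      fit <- suppressWarnings(
        fit_individual(trials, spec, chains = chains, iter = iter,
                       warmup = warmup, n_u = n_u, n_v = n_v))
      if (!fit$converged) flagged <- c(flagged, paste0("obs", i))
      pe <- point_estimates(fit)
      psd <- setNames(fit$summary$sd, fit$summary$parameter)
      rows[[i]] <- tibble::tibble(
        observer = i,
        parameter = spec$free,
        true = vapply(spec$free, function(p) {
          if (p == "sd_report") par_i$report_noise_sd
          else if (p == "w") par_i$w_choice
          else par_i[[p]] %||% NA_real_
        }, 0),
        recovered = unname(pe[spec$free]),
        post_sd = unname(psd[spec$free]),
        converged = fit$converged)
    }
    tab <- dplyr::bind_rows(rows)
    if (all(!tab$converged))
      stop("all recovery fits were flagged as non-converged; no report")
    metrics <- dplyr::summarise(
      dplyr::group_by(tab, parameter),
      bias = mean(recovered - true),
      rmse = sqrt(mean((recovered - true)^2)),
      rank_cor = if (dplyr::n() >= 3 && sd(true) > 0)
        cor(true, recovered, method = "spearman") else NA_real_,
      .groups = "drop")
    structure(list(table = tab, metrics = metrics, flagged = flagged),
              class = "pc_recovery")
  })
}

#' @export
print.pc_recovery <- function(x, ...) {
  cat("<pc_recovery>\n")
  print(as.data.frame(x$metrics), digits = 3, row.names = FALSE)
  if (length(x$flagged))
    cat("flagged observers:", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

# Draw a cohort of observer parameter sets from group-level lognormal
# distributions (used by recovery drivers and tests).
draw_cohort_params <- function(n, group = list(w_choice = 2.17, w_conf = 1.27,
                                               b = 2.18),
                               sd_log = 0.3, sigma = 0.23, sigma_sd_log = 0.1,
                               bias_sd = 0.02, report_noise_sd = 0.08) {
  lapply(seq_len(n), function(j) {
    observer_params(
      w_choice = exp(rnorm(1, log(group$w_choice), sd_log)),
      w_conf = exp(rnorm(1, log(group$w_conf), sd_log)),
      b = exp(rnorm(1, log(group$b), sd_log)),
      sigma = exp(rnorm(1, log(sigma), sigma_sd_log)),
      bias = rnorm(1, 0, bias_sd),
      report_noise_sd = report_noise_sd)
  })
}

#' Model-recovery study
#'
#' Simulates cohorts from each generating model variant, fits every
#' candidate variant hierarchically, scores them (group-predictive log
#' score by default, or full [logo_cv()]), and records the winning model in
#' a confusion matrix. The winner respects the parsimony decision rule: the
#' best-scoring model wins only over models it beats by `min_diff` elpd and
#' `2 x` the SE of the difference; otherwise the simplest surviving model
#' (fewest hierarchical parameters) is selected.
#'
#' @param specs Candidate [model_spec()] list.
#' @param n_reps Replicates per generating model.
#' @param n_participants,trials_per_obs Cohort size.
#' @param group Group-level generating parameters for the flexible
#'   generator; other variants apply their constraint (`flat_prior`
#'   effectively removes the prior; `optimal` sets both weights to 1;
#'   `equal` uses `w_choice` for both).
#' @param seed Integer seed.
#' @param method `"proxy"` (group-predictive score) or `"logo"`.
#' @param generator `"likelihood"` simulates responses from each variant's
#'   own fitted observation model via [simulate_from_model()] (the
#'   well-specified model-recovery setting); `"observer"` simulates the
#'   full latent-response observer, under which the level-mean
#'   simplification makes the candidate models mildly misspecified.
#' @param min_diff elpd margin of the decision rule.
#' @param chains,iter,warmup,n_u Passed to [fit_hierarchical()].
#' @return A `pc_model_recovery` with the `confusion` matrix (generating x
#'   winning) and per-cell score tables.
#' @export
model_recovery_study <- function(specs = lapply(c("flexible", "flat_prior",
                                                  "optimal", "equal"),
                                                model_spec),
                                 n_reps = 1, n_participants = 8,
                                 trials_per_obs = 360,
                                 group = list(w_choice = 2.17, w_conf = 1.27,
                                              b = 2.18),
                                 seed = NULL, method = c("proxy", "logo"),
                                 generator = c("likelihood", "observer"),
                                 min_diff = 4, chains = 2, iter = 400,
                                 warmup = 400, n_u = 16) {
  method <- match.arg(method)
  generator <- match.arg(generator)
  if (length(specs) < 2) stop("need at least 2 model specs")
  model_names <- vapply(specs, `[[`, "", "name")
  complexity <- vapply(specs, function(s) length(s$hier_free), 0L)
  confusion <- matrix(0L, length(specs), length(specs),
                      dimnames = list(generating = model_names,
                                      winner = model_names))
  details <- list()
  with_seed_if(seed, {
    for (g in seq_along(specs)) {
      for (rep in seq_len(n_reps)) {
        grp <- group
        gen_name <- model_names[g]
        if (gen_name == "flat_prior") {
          grp$w_choice <- grp$w_conf <- 1e6
        } else if (gen_name == "optimal") {
          grp$w_choice <- grp$w_conf <- 1
        } else if (gen_name == "equal") {
          grp$w_conf <- grp$w_choice
        }
        cohort <- draw_cohort_params(n_participants, grp,
                                     sd_log = if (gen_name %in%
                                                  c("flat_prior", "optimal"))
                                       0 else 0.3)
        design <- experiment_design(sessions = 1,
                                    n_blocks = trials_per_obs / 36)
        ds <- generate_dataset(cohort, design = design)
        calib <- calibrate_participants(ds$main, ds$control)
        trials <- normalize_dataset(ds$main, calib)
        if (generator == "likelihood") {
          pp <- tibble::tibble(
            participant = unique(trials$participant),
            w_choice = vapply(cohort, `[[`, 0, "w_choice"),
            w_conf = vapply(cohort, `[[`, 0, "w_conf"),
            w = vapply(cohort, `[[`, 0, "w_choice"),
            b = vapply(cohort, `[[`, 0, "b"))
          trials <- simulate_from_model(trials, pp, specs[[g]],
                                        sd_report = 0.1)
        }
        if (method == "logo") {
          rep_cv <- logo_cv(trials, specs,
                            n_folds = n_participants / 2, holdout_size = 2,
                            chains = chains, iter = iter, warmup = warmup,
                            n_u = n_u)
          pointwise <- rep_cv$pointwise
        } else {
          pointwise <- sapply(specs, function(sp) {
            fit <- suppressWarnings(
              fit_hierarchical(trials, sp, chains = chains, iter = iter,
                               warmup = warmup, n_u = n_u))
            group_predictive_score(fit, trials)$pointwise
          })
          colnames(pointwise) <- model_names
        }
        totals <- colSums(pointwise)
        best <- which.max(totals)
        # parsimony rule: models not decisively beaten survive
        surviving <- vapply(seq_along(specs), function(m) {
          if (m == best) return(TRUE)
          dd <- pointwise[, best] - pointwise[, m]
          diff <- sum(dd); sediff <- sd(dd) * sqrt(length(dd))
          !(diff >= min_diff && diff >= 2 * sediff)
        }, TRUE)
        cand <- which(surviving)
        winner <- cand[order(complexity[cand], -totals[cand])][1]
        confusion[g, winner] <- confusion[g, winner] + 1L
        details[[paste(gen_name, rep, sep = "_")]] <- totals
      }
    }
    structure(list(confusion = confusion, scores = details,
                   n_reps = n_reps),
              class = "pc_model_recovery")
  })
}

#' @export
print.pc_model_recovery <- function(x, ...) {
  cat("<pc_model_recovery> confusion matrix (rows = generating)\n")
  print(x$confusion)
  invisible(x)
}
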