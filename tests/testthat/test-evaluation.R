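test_that("LOGO-CV partitions participants exactly once and is seed-reproducible", {
  fx <- make_cohort_trials(6, n_blocks = 4, seed = 101)
  specs <- list(model_spec("flexible"), model_spec("flat_prior"))
  cv1 <- suppressWarnings(logo_cv(fx$trials, specs, n_folds = 3,
                                  holdout_size = 2, seed = 7,
                                  chains = 1, iter = 200, warmup = 200))
  # exact partition
  expect_setequal(names(cv1$folds), unique(fx$trials$participant))
  expect_true(all(table(cv1$folds) == 2))
  # every pointwise term finite
  expect_true(all(is.finite(cv1$pointwise)))
  expect_equal(nrow(cv1$pointwise), nrow(fx$trials))
  # identical rerun under the same seed
  cv2 <- suppressWarnings(logo_cv(fx$trials, specs, n_folds = 3,
                                  holdout_size = 2, seed = 7,
                                  chains = 1, iter = 200, warmup = 200))
  expect_identical(cv1$folds, cv2$folds)
  expect_equal(cv1$table$elpd, cv2$table$elpd, tolerance = 1e-12)
  expect_error(logo_cv(fx$trials, specs, n_folds = 10, holdout_size = 2),
               "participants")
})

test_that("identical model specs tie exactly under a shared seed", {
  fx <- make_cohort_trials(6, n_blocks = 4, seed = 103)
  specs <- list(model_spec("equal"), model_spec("equal"))
  cv <- suppressWarnings(logo_cv(fx$trials, specs, n_folds = 3,
                                 holdout_size = 2, seed = 9,
                                 chains = 1, iter = 250, warmup = 250))
  expect_equal(unname(cv$table$elpd_diff[2]), 0, tolerance = 1e-12)
  dec <- elpd_decision(cv)
  expect_false(dec$decisive[1])
})

test_that("model recovery is diagonal at reduced scale under the parsimony rule", {
  mr <- suppressWarnings(
    model_recovery_study(n_reps = 1, n_participants = 8,
                         trials_per_obs = 360, seed = 808,
                         generator = "likelihood", method = "proxy",
                         chains = 2, iter = 500, warmup = 500))
  expect_equal(unname(rowSums(mr$confusion)), rep(1L, 4))
  expect_equal(unname(diag(mr$confusion)), rep(1L, 4))
  # generating from the flat prior produces decisively worse scores for
  # the optimal model (which wrongly forces full use of the prior)
  expect_lt(mr$scores$flat_prior_1[["optimal"]],
            mr$scores$flat_prior_1[["flat_prior"]] - 100)
})

test_that("recovery study drivers tabulate bias, RMSE and rank correlation", {
  grid <- tibble::tibble(w_choice = c(1.0, 2.5), w_conf = c(1.5, 0.8),
                         b = c(1.0, 2.0))
  rec <- suppressWarnings(
    parameter_recovery_study(grid, trials_per_obs = 360, seed = 11,
                             chains = 2, iter = 300, warmup = 300))
  expect_s3_class(rec, "pc_recovery")
  expect_equal(nrow(rec$table), 2 * 4)
  expect_true(all(c("bias", "rmse", "rank_cor") %in% names(rec$metrics)))
  expect_true(all(is.finite(rec$metrics$rmse)))
  # even two noisy short fits must order a 2.5-fold difference in w_choice
  wc <- rec$table[rec$table$parameter == "w_choice", ]
  expect_equal(order(wc$true), order(wc$recovered))
})

test_that("condition summaries reproduce the folded-X and condition patterns", {
  fx <- make_cohort_trials(8, n_blocks = 10, sessions = 2, seed = 41)
  s <- condition_summaries(fx$trials)
  expect_named(s, c("accuracy", "confidence", "folded"))
  expect_equal(nrow(s$accuracy), 6)
  # accuracy rises with posterior level
  acc_by_level <- tapply(s$accuracy$mean_accuracy, s$accuracy$posterior_level,
                         mean)
  expect_true(acc_by_level[["L"]] < acc_by_level[["M"]],
              acc_by_level[["M"]] < acc_by_level[["H"]])
  # folded-X: confidence rises with posterior level on correct trials and
  # falls on incorrect trials
  f <- s$folded
  cc <- f$mean_confidence[f$target_correct]
  ee <- f$mean_confidence[!f$target_correct]
  expect_true(all(diff(cc) > 0))
  expect_lt(ee[3], ee[1])
  # empty cells are reported missing, not fabricated
  sub <- fx$trials[fx$trials$condition == "stronger_lead", ]
  s2 <- condition_summaries(sub)
  expect_equal(nrow(s2$accuracy), 3)
})

test_that("responses simulated from a variant's own likelihood honour its constraints", {
  fx <- make_cohort_trials(2, n_blocks = 3, seed = 121)
  pp <- tibble::tibble(participant = unique(fx$trials$participant),
                       w_choice = 2, w_conf = 2, w = 2, b = 1.5)
  sim <- simulate_from_model(fx$trials, pp, model_spec("flat_prior"),
                             sd_report = 0.05, seed = 5)
  # flat prior: task rule still holds, confidence ignores the lead level
  expect_identical(sim$target_dir == 1L, sim$lead_correct)
  expect_true(all(sim$conf_report >= 0.5 & sim$conf_report <= 1))
  agg <- tapply(sim$conf_report, paste(sim$lead_level, sim$target_level),
                mean)
  # same target level, different lead levels -> same implied confidence
  byt <- split(sim$conf_report, sim$target_level)
  bylead <- tapply(sim$conf_report, sim$lead_level, mean)
  expect_lt(diff(range(bylead)), diff(range(vapply(byt, mean, 0))) + 0.05)
})
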