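test_that("generated datasets respect the task rule, conditions and control structure", {
  ds <- generate_dataset(list(observer_params(w_choice = 2),
                              observer_params(w_conf = 0.8)),
                         design = experiment_design(sessions = 2,
                                                    n_blocks = 3),
                         seed = 21)
  main <- ds$main
  # task-rule conservation (exact, every trial)
  expect_identical(main$target_dir == 1L, main$lead_correct)
  # condition matching: level pairs reverse between conditions
  for (pl in c("L", "M", "H")) {
    sl <- main[main$posterior_level == pl & main$condition == "stronger_lead", ]
    st <- main[main$posterior_level == pl & main$condition == "stronger_target", ]
    expect_identical(sort(unique(paste(sl$lead_level, sl$target_level))),
                     sort(unique(paste(st$target_level, st$lead_level))))
  }
  # control task: 90 trials per session, 30 per coherence across sessions
  ctrl <- ds$control
  expect_equal(nrow(ctrl), 2 * 2 * 90)
  one <- ctrl[ctrl$participant == "P01", ]
  expect_equal(nrow(one), 180)
  expect_true(all(table(one$coh) == 30))
  expect_setequal(unique(one$coh), c(0.05, 0.10, 0.12, 0.15, 0.20, 0.30))
  # manifest records generating parameters and seed
  expect_equal(ds$manifest$seed, 21L)
  expect_equal(ds$manifest$participants$P01$w_choice, 2)
})

test_that("regeneration with the same seed is identical; seeds differ otherwise", {
  d1 <- generate_dataset(list(observer_params()),
                         design = experiment_design(sessions = 1, n_blocks = 2),
                         seed = 5)
  d2 <- generate_dataset(list(observer_params()),
                         design = experiment_design(sessions = 1, n_blocks = 2),
                         seed = 5)
  d3 <- generate_dataset(list(observer_params()),
                         design = experiment_design(sessions = 1, n_blocks = 2),
                         seed = 6)
  expect_identical(d1$main, d2$main)
  expect_identical(d1$control, d2$control)
  expect_false(identical(d1$main$conf_report, d3$main$conf_report))
})

test_that("lapses dilute accuracy toward chance as expected", {
  # near-perfect discrimination + lapse 0.5: half the responses are coin
  # flips, so lead accuracy is 0.5 * 1 + 0.5 * 0.5 = 0.75
  tr <- simulate_trials(observer_params(sigma = 0.01, lapse = 0.5),
                        rep(c(1L, -1L), 2.5e4), 0.3, 0.3, seed = 9)
  expect_equal(mean(tr$lead_correct), 0.75, tolerance = 0.02)
  # without discriminability every accuracy is chance regardless of lapse
  ds2 <- generate_dataset(list(observer_params(lapse = 0.5, sigma = 100)),
                          design = experiment_design(sessions = 1,
                                                     n_blocks = 5),
                          seed = 8)
  expect_equal(mean(ds2$main$lead_correct), 0.5, tolerance = 0.05)
  expect_equal(mean(ds2$main$target_correct), 0.5, tolerance = 0.05)
})

test_that("in-task staircases drive lead accuracy toward their targets", {
  ds <- generate_dataset(list(observer_params()),
                         design = experiment_design(sessions = 2,
                                                    n_blocks = 10),
                         seed = 31)
  main <- ds$main
  late <- main[main$session == 2, ]
  accM <- mean(late$lead_correct[late$lead_level == "M"])
  accH <- mean(late$lead_correct[late$lead_level == "H"])
  expect_equal(accM, 0.707, tolerance = 0.06)
  expect_equal(accH, 0.794, tolerance = 0.06)
  # low level is yoked 5 coherence points below the medium staircase
  cohL <- c(main$lead_coh[main$lead_level == "L"],
            main$target_coh[main$target_level == "L"])
  cohM <- c(main$lead_coh[main$lead_level == "M"],
            main$target_coh[main$target_level == "M"])
  expect_lt(abs(mean(cohL) - (mean(cohM) - 0.05)), 0.015)
})

test_that("dataset round-trips through plain-text files and a column mapping", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(list(observer_params()),
                         design = experiment_design(sessions = 1,
                                                    n_blocks = 1),
                         seed = 9)
  paths <- write_dataset(ds, dir)
  back <- read_trials(paths["main"])
  expect_equal(nrow(back), nrow(ds$main))
  expect_equal(back$conf_report, ds$main$conf_report, tolerance = 1e-12)

  # external deposit with renamed columns and 50-100 confidence scale
  ext <- data.frame(subj = "s1", resp1 = c(1, -1), resp2 = c(1, 1),
                    conf = c(55, 98))
  f <- file.path(dir, "deposit.csv")
  utils::write.table(ext, f, sep = ",", row.names = FALSE, quote = FALSE)
  got <- read_trials(f, mapping = c(participant = "subj",
                                    lead_choice = "resp1",
                                    target_choice = "resp2",
                                    conf_report = "conf"), sep = ",")
  expect_named(got, c("participant", "lead_choice", "target_choice",
                      "conf_report"))
  expect_equal(got$conf_report, c(0.55, 0.98))
  expect_error(read_trials(f, mapping = c(participant = "nope"), sep = ","),
               "not found")
})

test_that("the dropout hook removes the requested fraction of trials", {
  ds <- generate_dataset(list(observer_params()),
                         design = experiment_design(sessions = 1,
                                                    n_blocks = 5),
                         seed = 10, dropout = 0.2)
  expect_lt(nrow(ds$main), 180)
  expect_gt(nrow(ds$main), 110)
})

test_that("cohorts with the published weighting pattern show the behavioural signature", {
  fx <- make_cohort_trials(8, n_blocks = 10, sessions = 2, seed = 41)
  main <- fx$trials
  # accuracy higher when the target is the stronger stimulus
  acc <- tapply(main$target_correct, main$condition, mean)
  expect_gt(acc[["stronger_target"]], acc[["stronger_lead"]])
  # after errors, confidence is lower in the Stronger-Lead condition
  err <- main[!main$target_correct, ]
  conf_err <- tapply(err$conf_report, err$condition, mean)
  expect_gt(conf_err[["stronger_target"]], conf_err[["stronger_lead"]])
  # after correct decisions the difference is much smaller than after errors
  cor_ <- main[main$target_correct, ]
  conf_cor <- tapply(cor_$conf_report, cor_$condition, mean)
  expect_lt(abs(conf_cor[["stronger_target"]] - conf_cor[["stronger_lead"]]),
            abs(conf_err[["stronger_target"]] - conf_err[["stronger_lead"]]))
})
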