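test_that("stimulus normalization matches its definition and validates inputs", {
  expect_equal(normalize_stimulus(stimulus_spec(1, 0.15), sigma = 0.1), 1.5)
  expect_equal(normalize_stimulus(stimulus_spec(-1, 0.10), sigma = 0.12,
                                  bias = 0.02), -1.0)
  expect_equal(normalize_stimulus(stimulus_spec(1, 0.02), sigma = 0.5,
                                  bias = 0.02), 0)
  expect_error(normalize_stimulus(stimulus_spec(1, 0.1), sigma = 0),
               "sigma")
  expect_error(stimulus_spec(2, 0.1), "direction")
  expect_error(stimulus_spec(1, 1.2), "coherence")
})

test_that("lead confidence is Phi(|r|), at least 0.5 and symmetric", {
  expect_equal(lead_confidence(0), 0.5)
  expect_equal(lead_confidence(1), pnorm(1), tolerance = 1e-10)
  expect_equal(lead_confidence(1), 0.8413, tolerance = 1e-4)
  expect_equal(lead_confidence(-2), lead_confidence(2))
  r <- seq(-3, 3, by = 0.5)
  expect_true(all(lead_confidence(r) >= 0.5))
})

test_that("criterion shift is -|r|/w_choice, never positive", {
  expect_equal(shifted_criterion(2, 1), -2)
  expect_equal(shifted_criterion(2, 1e9), 0, tolerance = 1e-8)
  expect_equal(shifted_criterion(0, 0.3), 0)
  expect_equal(shifted_criterion(-1.5, 3), -0.5)
  expect_true(all(shifted_criterion(rnorm(50), 0.7) <= 0))
  expect_error(shifted_criterion(1, 0), "w_choice")
})

test_that("marginal rightward-choice probability matches limits and the MC oracle", {
  # flat-prior limit
  expect_equal(p_right_target(1, 0.5, 1, 1e6), pnorm(0.5), tolerance = 1e-4)
  expect_equal(p_right_target(0.8, -0.3, -1, 1e6), pnorm(-0.3),
               tolerance = 1e-4)
  # extreme target evidence
  expect_gt(p_right_target(1, 8, 1, 2), 1 - 1e-6)
  # spec point vs brute-force marginalization (moderate draws here; the
  # full 1e6-draw check runs with the acceptance suite)
  set.seed(1)
  expect_equal(p_right_target(1, 0.5, 1, 2),
               mc_p_right(1, 0.5, 1, 2, 4e5), tolerance = 2e-3)
  expect_error(p_right_target(1, 0.5, 1, -1), "w_choice")
  expect_error(p_right_target(1, 0.5, 2, 1), "lead_choice")
})

test_that("marginal choice probability is monotone in target strength and lead evidence", {
  s_t <- seq(-2, 2, by = 0.5)
  p <- p_right_target(rep(1, length(s_t)), s_t, 1, 2)
  expect_true(all(diff(p) > 0))
  # stronger lead evidence after a correct rightward lead -> stronger
  # rightward shift
  s_l <- seq(0.2, 2.2, by = 0.4)
  p2 <- p_right_target(s_l, rep(-0.5, length(s_l)), 1, 2)
  expect_true(all(diff(p2) > 0))
})

test_that("confidence prior and likelihood follow their definitions", {
  expect_equal(confidence_prior(0, 1, 1), 0.5)
  expect_equal(confidence_prior(1, 1, 1), 0.8413, tolerance = 1e-4)
  expect_equal(confidence_prior(1, 2, 2), pnorm(0.25), tolerance = 1e-10)
  expect_equal(confidence_prior(1, 2, 2), 0.5987, tolerance = 1e-4)
  # agreement with lead confidence when b * w_conf = 1
  r <- seq(-2, 2, by = 0.25)
  expect_equal(confidence_prior(r, b = 2, w_conf = 0.5), lead_confidence(r))
  expect_equal(confidence_likelihood(0, 1), 0.5)
  expect_equal(confidence_likelihood(1, 1), 0.8413, tolerance = 1e-4)
  expect_equal(confidence_likelihood(3, 1e9), 0.5, tolerance = 1e-6)
  expect_error(confidence_prior(1, 0, 1), "b")
  expect_error(confidence_likelihood(1, -2), "b")
})

test_that("posterior confidence combination reduces to prior/likelihood identities", {
  for (x in c(0.2, 0.5, 0.77, 0.95)) {
    expect_equal(posterior_confidence_right(0.5, x), x)
    expect_equal(posterior_confidence_right(x, 0.5), x)
  }
  expect_equal(posterior_confidence_right(0.8, 0.75), 0.9231,
               tolerance = 1e-4)
  # leftward confidence is the complement
  expect_equal(1 - posterior_confidence_right(0.7, 0.6),
               posterior_confidence_right(0.3, 0.4), tolerance = 1e-12)
  expect_warning(p <- posterior_confidence_right(1, 0.5), "clamped")
  expect_lt(p, 1)
})

test_that("simulated trials respect the task rule, report range and chance level", {
  p <- observer_params()
  tr <- simulate_trials(p, rep(c(1L, -1L), 300), 0.15, 0.15, seed = 1)
  # task rule: target direction right iff lead response correct (exact)
  expect_identical(tr$target_dir == 1L, tr$lead_correct)
  expect_true(all(tr$conf_report >= 0.5 & tr$conf_report <= 1))
  # chance-level lead stimulus -> chance lead accuracy
  tr0 <- simulate_trials(observer_params(sigma = 1), rep(c(1L, -1L), 2500),
                         1e-6, 0.15, seed = 2)
  expect_equal(mean(tr0$lead_correct), 0.5, tolerance = 0.03)
  # model confidence in the chosen option can drop below 0.5 when the
  # confidence weighting disagrees with the choice weighting
  trw <- simulate_trials(observer_params(w_choice = 0.3, w_conf = 4,
                                         sigma = 0.23),
                         rep(c(1L, -1L), 2000), 0.08, 0.08, seed = 3)
  expect_gt(sum(trw$conf_model < 0.5), 0)
  expect_true(all(trw$conf_report >= 0.5))
})

test_that("simulated accuracy matches the closed form Phi((a+c)/sqrt(2)) at optimal weighting", {
  p <- observer_params(sigma = 0.23)
  n <- 1.5e5
  set.seed(4)
  for (pair in list(c(0.127, 0.077), c(0.077, 0.127), c(0.19, 0.127))) {
    tr <- simulate_trials(p, sample(c(1L, -1L), n, TRUE), pair[1], pair[2])
    a <- pair[1] / 0.23; cc <- pair[2] / 0.23
    expect_equal(mean(tr$target_correct), pnorm((a + cc) / sqrt(2)),
                 tolerance = 0.005)
  }
})

test_that("prior underweighting favours the Stronger-Target condition", {
  # matched pair at one posterior level: (M lead, L target) vs (L, M)
  p <- observer_params(w_choice = 3, sigma = 0.23)
  n <- 4e4
  set.seed(5)
  sl <- simulate_trials(p, sample(c(1L, -1L), n, TRUE), 0.127, 0.077)
  st <- simulate_trials(p, sample(c(1L, -1L), n, TRUE), 0.077, 0.127)
  expect_gt(mean(st$target_correct), mean(sl$target_correct) + 0.02)
})

test_that("model confidence is calibrated under the observer's own (broad-prior) generative", {
  # strengths drawn from increasingly broad distributions approach the
  # flat prior the confidence equations assume; the mean-confidence /
  # accuracy gap must shrink and become small
  set.seed(6)
  n <- 6e4
  gap <- vapply(c(0.6, 1.5, 4), function(spread) {
    lead_coh <- pmin(abs(rnorm(n, 0, spread)) * 0.23, 0.9)
    target_coh <- pmin(abs(rnorm(n, 0, spread)) * 0.23, 0.9)
    tr <- simulate_trials(observer_params(sigma = 0.23, report_noise_sd = 0),
                          sample(c(1L, -1L), n, TRUE), lead_coh, target_coh)
    mean(tr$conf_model) - mean(tr$target_correct)
  }, 0)
  expect_true(all(diff(abs(gap)) < 0))
  expect_lt(abs(gap[3]), 0.02)
})

test_that("mean-zero metacognitive noise leaves the confidence prior unbiased to first order", {
  # Gaussian noise on the internal response perturbs the rightward prior
  # p(R)_conf = Phi(|r|/(b w_conf)) with a bias that is second order in the
  # noise SD (quadratic scaling), while inflating its trial-to-trial
  # variability.
  set.seed(7)
  n <- 4e5
  r <- rnorm(n, 0.552, 1)
  base <- confidence_prior(r, 1, 1)
  shift <- vapply(c(0.2, 0.5), function(sdm) {
    mean(confidence_prior(r + rnorm(n, 0, sdm), 1, 1)) - mean(base)
  }, 0)
  # no first-order bias: a linear-in-sd bias would be ~E|f'| * 0.2 ~ 0.06
  expect_lt(abs(shift[1]), 0.005)
  # quadratic scaling: (0.5/0.2)^2 = 6.25
  expect_gt(shift[2] / shift[1], 3)
  expect_lt(shift[2] / shift[1], 10)
  noisy <- confidence_prior(r + rnorm(n, 0, 0.5), 1, 1)
  expect_gt(var(noisy), var(base))
  # decorrelating confidence from the first-order choice lowers mean
  # confidence in the *chosen* option (noise harms metacognition)
  tr_b <- simulate_trials(observer_params(sigma = 0.23),
                          sample(c(1L, -1L), 1e5, TRUE), 0.127, 0.127,
                          seed = 8)
  tr_n <- simulate_trials(observer_params(sigma = 0.23,
                                          metacog_noise_sd = 0.5,
                                          metacog_noise_family = "gaussian"),
                          sample(c(1L, -1L), 1e5, TRUE), 0.127, 0.127,
                          seed = 9)
  expect_lt(mean(tr_n$conf_model), mean(tr_b$conf_model))
  # first-order accuracy is untouched by metacognitive noise
  expect_equal(mean(tr_n$target_correct), mean(tr_b$target_correct),
               tolerance = 0.01)
})

test_that("observer parameter validation enforces the documented ranges", {
  expect_error(observer_params(w_choice = -1), "w_choice")
  expect_error(observer_params(w_conf = 0), "w_conf")
  expect_error(observer_params(b = 0), "b")
  expect_error(observer_params(lapse = 0.7), "lapse")
  expect_error(observer_params(metacog_noise_sd = -0.1), "metacog")
  expect_s3_class(observer_params(), "observer_params")
})
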