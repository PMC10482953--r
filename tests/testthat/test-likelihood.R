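test_that("choice likelihood normalizes, matches the flat-prior reduction and the MC oracle", {
  # flat prior: exactly log Phi(+/- s_target)
  tr <- make_trial_tbl(s_lead = c(0.8, 0.8), s_target = c(0.6, 0.6),
                       target_choice = c(1L, -1L))
  ll <- choice_loglik(tr, list(w_choice = 1), spec = model_spec("flat_prior"))
  expect_equal(ll, log(c(pnorm(0.6), pnorm(-0.6))), tolerance = 1e-9)
  # probabilities over {left, right} sum to one for any parameter set
  for (w in c(0.4, 1, 3)) {
    llw <- choice_loglik(tr, list(w_choice = w))
    expect_equal(sum(exp(llw)), 1, tolerance = 1e-8)
  }
  # full marginal vs Monte-Carlo oracle on a strength grid
  set.seed(1)
  for (s_l in c(0.4, 1.1)) for (s_t in c(-0.6, 0.8)) {
    tr1 <- make_trial_tbl(s_l, s_t, lead_choice = 1L, target_choice = 1L)
    p_full <- exp(choice_loglik(tr1, list(w_choice = 2)))
    expect_equal(p_full, mc_p_right(s_l, s_t, 1, 2, 3e5), tolerance = 3e-3)
  }
})

test_that("simplified and full choice likelihoods agree only in the flat-prior limit", {
  tr <- make_trial_tbl(s_lead = 0.9, s_target = 0.4)
  full <- choice_loglik(tr, list(w_choice = 1.5))
  simp <- choice_loglik(tr, list(w_choice = 1.5), simplified = TRUE)
  expect_false(isTRUE(all.equal(full, simp)))
  full_inf <- choice_loglik(tr, list(w_choice = 1e8))
  simp_inf <- choice_loglik(tr, list(w_choice = 1e8), simplified = TRUE)
  expect_equal(full_inf, simp_inf, tolerance = 1e-6)
  expect_equal(full_inf, log(pnorm(0.4)), tolerance = 1e-6)
})

test_that("the flat-prior model is invariant to lead-stimulus information", {
  fx <- make_cohort_trials(2, n_blocks = 3, seed = 61)
  tr <- fx$trials
  perm <- tr
  set.seed(2)
  shuffle <- sample(nrow(perm))
  perm$s_lead <- perm$s_lead[shuffle]
  perm$lead_level <- perm$lead_level[shuffle]
  ps <- list(b = 1.4, sd_report = 0.1)
  spec <- model_spec("flat_prior")
  expect_equal(sum(choice_loglik(tr, ps, spec = spec)),
               sum(choice_loglik(perm, ps, spec = spec)), tolerance = 1e-9)
  expect_equal(sum(confidence_loglik(tr, ps, spec = spec, simplified = TRUE)),
               sum(confidence_loglik(perm, ps, spec = spec,
                                     simplified = TRUE)), tolerance = 1e-8)
})

test_that("confidence report density is normalized and reduces correctly", {
  cg <- seq(0.5, 1, length.out = 1001)
  tr <- make_trial_tbl(rep(0.8, 1001), 0.5, conf = cg)
  ps <- list(w_choice = 2, w_conf = 1.3, b = 1.8, sd_report = 0.08)
  dens <- exp(confidence_loglik(tr, ps))
  expect_equal(sum(dens) * 0.5 / 1000, 1, tolerance = 2e-3)
  # flat-prior + simplification: truncated Gaussian around the clipped
  # level-mean confidence Phi(|s_t| / b)
  spec <- model_spec("flat_prior")
  ps2 <- list(b = 1.5, sd_report = 0.1)
  d2 <- exp(confidence_loglik(tr, ps2, spec = spec, simplified = TRUE))
  mu <- pnorm(0.5 / 1.5)
  z <- (cg - mu) / 0.1
  ref <- dnorm(z) / 0.1 / (pnorm((1 - mu) / 0.1) - pnorm((0.5 - mu) / 0.1))
  expect_equal(d2, ref, tolerance = 1e-6)
  expect_error(confidence_loglik(tr, list(b = 1, sd_report = 0)),
               "zero-width")
})

test_that("the level-mean simplification underestimates confidence", {
  fx <- make_cohort_trials(2, n_blocks = 4, sd_log = 0, seed = 71)
  tr <- fx$trials[1:60, ]
  ps <- list(w_choice = 2.17, w_conf = 1.27, b = 2.18, sd_report = 0.1)
  cg <- seq(0.5, 1, length.out = 201)
  implied_mean <- function(simplified) {
    vapply(seq_len(nrow(tr)), function(i) {
      g <- tr[rep(i, 201), ]
      g$conf_report <- cg
      d <- exp(confidence_loglik(g, ps, simplified = simplified))
      sum(cg * d) / sum(d)
    }, 0)
  }
  m_full <- implied_mean(FALSE)
  m_simp <- implied_mean(TRUE)
  expect_lt(mean(m_simp), mean(m_full) - 0.01)
})

test_that("extreme parameters keep log-likelihoods finite (clamped floors)", {
  tr <- make_trial_tbl(s_lead = 3, s_target = -3, lead_choice = 1L,
                       target_choice = 1L, conf = 0.999)
  ps <- list(w_choice = 0.05, w_conf = 0.05, b = 0.05, sd_report = 0.02)
  expect_true(is.finite(choice_loglik(tr, ps)))
  expect_true(is.finite(confidence_loglik(tr, ps)))
  expect_true(is.finite(confidence_loglik(tr, ps, simplified = TRUE)))
  total <- dataset_loglik(tr, ps)
  expect_true(is.finite(total$total))
})
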