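# Simulated prior-free decisions with a known psychometric function.
sim_decisions <- function(n, sigma, bias = 0, lapse = 0) {
  x <- sample(c(-1, 1), n, TRUE) * sample(c(0.05, 0.1, 0.12, 0.15, 0.2, 0.3),
                                          n, TRUE)
  p <- lapse / 2 + (1 - lapse) * pnorm((x - bias) / sigma)
  tibble::tibble(x = x, chose_right = runif(n) < p)
}

test_that("psychometric variants recover their generating parameters", {
  set.seed(1)
  d <- sim_decisions(5000, sigma = 0.1)
  f <- fit_psychometric(d, "noise_only")
  expect_lt(abs(f$sigma - 0.1), 0.1 * 0.1)             # within 10%
  # symmetric balanced data -> bias near zero
  fb <- fit_psychometric(d, "noise_bias")
  expect_lt(abs(fb$bias), 0.01)
  # the full variant can never have lower log-likelihood than nested ones
  ll <- vapply(c("noise_only", "noise_bias", "noise_lapse"),
               function(v) fit_psychometric(d, v)$loglik, 0)
  full <- fit_psychometric(d, "noise_bias_lapse")
  expect_true(all(full$loglik >= ll - 1e-4))
  # recovery with bias and lapse present
  set.seed(2)
  d2 <- sim_decisions(8000, sigma = 0.15, bias = 0.03, lapse = 0.08)
  f2 <- fit_psychometric(d2, "noise_bias_lapse")
  expect_lt(abs(f2$sigma - 0.15), 0.03)
  expect_lt(abs(f2$bias - 0.03), 0.02)
  expect_lt(abs(f2$lapse - 0.08), 0.05)
})

test_that("degenerate decision data are rejected with a clear error", {
  bad <- tibble::tibble(x = c(0.1, -0.1, 0.2, -0.2),
                        chose_right = c(TRUE, TRUE, TRUE, TRUE))
  expect_error(fit_psychometric(bad), "degenerate")
  one_level <- tibble::tibble(x = c(0.1, -0.1), chose_right = c(TRUE, FALSE))
  expect_error(fit_psychometric(one_level), "coherence")
})

test_that("Akaike weights follow the closed form", {
  mk <- function(aic, variant = "noise_only", sigma = 0.1, bias = 0,
                 lapse = 0) {
    structure(list(variant = variant, sigma = sigma, bias = bias,
                   lapse = lapse, loglik = -aic / 2, aic = aic, n = 100),
              class = "psychometric_fit")
  }
  eq <- akaike_combine(list(mk(10, "noise_only"), mk(10, "noise_bias"),
                            mk(10, "noise_lapse"),
                            mk(10, "noise_bias_lapse")))
  expect_equal(unname(eq$weights), rep(0.25, 4))
  two <- akaike_combine(list(mk(10, "noise_only"), mk(12, "noise_bias")))
  expect_equal(two$weights[["noise_only"]] / two$weights[["noise_bias"]],
               exp(1), tolerance = 1e-10)
  far <- akaike_combine(list(mk(10, "noise_only"), mk(30, "noise_bias")))
  expect_lt(far$weights[["noise_bias"]], 1e-4)
  # weighted parameter combination, absent parameters entering as zero
  cmb <- akaike_combine(list(mk(10, "noise_only", sigma = 0.1),
                             mk(10, "noise_bias", sigma = 0.2, bias = 0.04)))
  expect_equal(cmb$sigma, 0.15)
  expect_equal(cmb$bias, 0.02)
})

test_that("the generating variant usually earns the highest Akaike weight", {
  # reduced-scale identifiability check: variants with clearly present
  # bias / lapse should be picked over the plain-noise variant
  set.seed(3)
  variants <- c("noise_only", "noise_bias_lapse")
  hits <- sapply(variants, function(v) {
    wins <- 0L
    for (r in 1:12) {
      d <- if (v == "noise_only") sim_decisions(5000, 0.1)
           else sim_decisions(5000, 0.1, bias = 0.05, lapse = 0.12)
      fits <- lapply(c("noise_only", "noise_bias", "noise_lapse",
                       "noise_bias_lapse"), function(x) fit_psychometric(d, x))
      w <- akaike_combine(fits)$weights
      best <- names(w)[which.max(w)]
      ok <- if (v == "noise_only") best %in% "noise_only" else
        best == "noise_bias_lapse"
      wins <- wins + ok
    }
    wins
  })
  expect_gt(hits[["noise_only"]], 6)
  expect_gt(hits[["noise_bias_lapse"]], 6)
})

test_that("combined noise estimates are consistent as data grow", {
  set.seed(4)
  rmse_at <- function(n, reps = 8) {
    e <- replicate(reps, {
      d <- sim_decisions(n, sigma = 0.12)
      fits <- lapply(c("noise_only", "noise_bias", "noise_lapse",
                       "noise_bias_lapse"), function(v) fit_psychometric(d, v))
      akaike_combine(fits)$sigma - 0.12
    })
    sqrt(mean(e^2))
  }
  r <- c(rmse_at(500), rmse_at(2000), rmse_at(8000))
  expect_gt(r[1], r[3])
  expect_lt(r[3], 0.01)
})

test_that("calibration pipeline and normalization agree with the shared definition", {
  ds <- generate_dataset(list(observer_params(sigma = 0.2, bias = 0.01)),
                         design = experiment_design(sessions = 2,
                                                    n_blocks = 5),
                         seed = 51)
  calib <- calibrate_participants(ds$main, ds$control)
  expect_equal(nrow(calib), 1)
  expect_equal(calib$sigma, 0.2, tolerance = 0.05)
  ws <- rowSums(calib[, grep("^w_", names(calib))])
  expect_equal(ws, 1, tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(calibrate_participants(ds$main,
                                      ds$control[0, ]), "P01")

  # identity normalization and element-wise agreement with the core op
  tr <- normalize_dataset(ds$main, list(sigma = 1, bias = 0))
  expect_equal(tr$s_lead, tr$lead_dir * tr$lead_coh)
  tr2 <- normalize_dataset(ds$main, calib)
  expect_equal(tr2$s_lead,
               normalize_stimulus(ds$main$lead_dir, ds$main$lead_coh,
                                  sigma = calib$sigma, bias = calib$bias))
  # round trip back to raw coherence
  expect_equal(tr2$s_lead * calib$sigma + calib$bias,
               ds$main$lead_dir * ds$main$lead_coh, tolerance = 1e-12)
})
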