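# Model variants, priors, the reference backend's mechanics, and the
# posterior-draw machinery. Estimation accuracy itself is exercised by the
# recovery and end-to-end reliability checks in test-acceptance.R.

test_that("model variants carry the expected free/fixed maps", {
  m2 <- default_model_spec("M2")
  expect_setequal(m2$spec$free, c("a", "v1", "v2", "ndt", "alpha"))
  expect_equal(m2$spec$fixed, c(zr = 0.5, sndt = 0))
  m1 <- default_model_spec("M1")
  expect_setequal(m1$spec$free,
                  c("a", "zr", "v1", "v2", "ndt", "sndt", "alpha"))
  ect <- default_model_spec("ECT")
  expect_length(ect$spec$free, 4)
  expect_setequal(ect$spec$free, c("a", "v", "ndt", "alpha"))
  apt <- default_model_spec("APT_M2")
  expect_length(apt$spec$conditions, 4)
  expect_setequal(grep("^ndt", apt$spec$free, value = TRUE),
                  paste0("ndt", 1:4))
  expect_error(default_model_spec("M3"))
})

test_that("default priors bound alpha to [1, 2] and samples respect the
           non-decision constraint", {
  pr <- default_model_spec("M1")$prior
  ab <- pr[pr$param == "alpha", ]
  expect_equal(c(ab$lower, ab$upper), c(1, 2))
  expect_error(prior_spec(default_model_spec("M1")$spec,
                          overrides = list(alpha = c(0.5, 2))),
               "alpha prior")
  set.seed(1)
  draws <- sample_prior(pr, 500)
  expect_true(all(draws[, "alpha"] >= 1 & draws[, "alpha"] <= 2))
  expect_true(all(draws[, "ndt"] - draws[, "sndt"] / 2 > 0.05 - 1e-12))
})

test_that("fitting validates its inputs", {
  fx <- make_m2_participant(60)
  expect_error(fit_participant(fx$trials[0, ], fx$spec, fx$prior,
                               tiny_backend()),
               "under-data")
  expect_error(fit_participant(fx$trials[1:20, ], fx$spec, fx$prior,
                               tiny_backend()),
               "under-data")
  bad <- fx$trials
  bad$condition[1] <- "c9"
  expect_error(fit_participant(bad, fx$spec, fx$prior, tiny_backend()),
               "conditions")
  onesided <- fx$trials[!fx$trials$censored, ]
  onesided$response <- 1
  expect_warning(
    fit_participant(onesided, fx$spec, fx$prior, tiny_backend()),
    "degenerate")
})

test_that("the reference fit is deterministic and inside the prior", {
  fx <- make_m2_participant(80)
  f1 <- fit_participant(fx$trials, fx$spec, fx$prior, tiny_backend(),
                        seed = 17)
  f2 <- fit_participant(fx$trials, fx$spec, fx$prior, tiny_backend(),
                        seed = 17)
  expect_identical(f1$estimates, f2$estimates)
  est <- f1$estimates[fx$prior$param]
  expect_true(all(est >= fx$prior$lower & est <= fx$prior$upper))
  expect_gt(f1$diagnostics$n_evals, 0)
  expect_equal(f1$backend, "reference")
})

test_that("drift composites follow their defining formulas", {
  expect_equal(drift_composites(c(v1 = 2, v2 = -1)),
               c(v_total = 3, v_bias = 1))
  expect_equal(drift_composites(c(v1 = 0, v2 = 0)),
               c(v_total = 0, v_bias = 0))
  expect_equal(drift_composites(c(v1 = 3.2, v2 = -2.7)),
               c(v_total = 5.9, v_bias = 0.5))
  expect_error(drift_composites(c(v = 1)), "unsupported")
})

test_that("summary vectors have fixed length with masked empty cells", {
  fx <- make_m2_participant(60)
  s1 <- summary_vector(fx$trials, fx$spec)
  only_upper <- fx$trials[fx$trials$response == 1 & !fx$trials$censored, ]
  s2 <- summary_vector(only_upper, fx$spec)
  expect_length(s2$stats, length(s1$stats))
  expect_true(any(!s2$mask))
  expect_true(all(is.finite(s2$stats)))
})

test_that("SBC machinery: calibrated draws give uniform ranks,
           mis-specified draws do not", {
  mp <- default_model_spec("ECT")
  sbc_ok <- run_sbc(mp$spec, mp$prior, n_sims = 150, n_draws = 60,
                    n_trials = 60, backend = mock_prior_backend(),
                    seed = 5)
  expect_true(all(sbc_ok$uniformity$p_value > 0.01))
  expect_true(all(sbc_ok$ranks >= 0 & sbc_ok$ranks <= 60))
  sbc_bad <- run_sbc(mp$spec, mp$prior, n_sims = 150, n_draws = 60,
                     n_trials = 60, backend = mock_prior_backend(0.3),
                     seed = 5)
  expect_true(any(sbc_bad$uniformity$p_value < 0.01))
})

test_that("SBC refuses the point-estimate backend and tiny runs", {
  mp <- default_model_spec("ECT")
  expect_error(run_sbc(mp$spec, mp$prior, backend = backend_reference()),
               "recovery_study")
  expect_error(run_sbc(mp$spec, mp$prior, n_sims = 10,
                       backend = mock_prior_backend()),
               "n_sims")
})

test_that("the ABC backend returns in-support posterior draws", {
  fx <- make_m2_participant(60)
  be <- backend_abc(n_table = 150, dt = 0.01)
  fit <- fit_participant(fx$trials, fx$spec, fx$prior, be, seed = 3,
                         n_draws = 40)
  expect_equal(nrow(fit$draws), 40)
  for (p in fx$prior$param) {
    expect_true(all(fit$draws[, p] >= fx$prior$lower[fx$prior$param == p] &
                      fit$draws[, p] <= fx$prior$upper[fx$prior$param == p]))
  }
  expect_equal(fit$backend, "abc")
  est <- fit$estimates[fx$prior$param]
  expect_true(all(est >= fx$prior$lower & est <= fx$prior$upper))
})

test_that("recovery_study validates sizes and flags degenerate truths", {
  mp <- default_model_spec("M2")
  expect_error(recovery_study(mp$spec, mp$prior, n_participants = 5),
               "n_participants")
})
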