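# Forward simulation of the accumulator and its Gaussian-limit oracle.

test_that("parameter validation enforces the accumulator's domain", {
  expect_error(lfm_params(c(c1 = 1), a = -1), "a")
  expect_error(lfm_params(c(c1 = 1), a = 1, zr = 1), "zr")
  expect_error(lfm_params(c(c1 = 1), a = 1, ndt = 0.1, sndt = 0.3),
               "sndt")
  expect_error(lfm_params(c(c1 = 1), a = 1, alpha = 0.9), "alpha")
  expect_error(lfm_params(c(1, 2), a = 1), "named")
  expect_error(sim_config(dt = 0.02), "dt")
  p <- lfm_params(c(c1 = 1), a = 1)
  expect_error(simulate_dataset(p, c(c2 = 10)), "not present")
  expect_error(simulate_dataset(p, stats::setNames(integer(0),
                                                   character(0))),
               "at least one")
})

test_that("unbiased start splits boundary hits evenly at any alpha", {
  for (alpha in c(1.1, 2)) {
    p <- lfm_params(c(c1 = 0), a = 1.5, zr = 0.5, ndt = 0.3, alpha = alpha)
    tab <- simulate_dataset(p, c(c1 = 2e4),
                            sim_config(dt = 2e-3, seed = round(alpha * 7)))
    up <- mean(tab$response == 1, na.rm = TRUE)
    expect_lt(abs(up - 0.5), 3 * sqrt(0.25 / 2e4) + 0.01)
  }
})

test_that("Gaussian-noise simulation matches the Wiener hitting formula", {
  p <- lfm_params(c(c1 = 1), a = 2, zr = 0.5, ndt = 0, alpha = 2)
  tab <- simulate_dataset(p, c(c1 = 3e4),
                          sim_config(dt = 5e-4, seed = 11))
  p_up <- mean(tab$response == 1, na.rm = TRUE)
  p_ref <- (1 - exp(-1)) / (1 - exp(-2)) # 0.7311
  expect_lt(abs(p_up - p_ref), 3 * sqrt(p_ref * (1 - p_ref) / 3e4))
})

test_that("reaction times respect the non-decision-time floor", {
  p <- lfm_params(c(c1 = 2), a = 1.5, ndt = 0.3, sndt = 0, alpha = 1.5)
  tab <- simulate_dataset(p, c(c1 = 2000), sim_config(seed = 5))
  expect_true(all(tab$rt[!tab$censored] >= 0.3))
  p2 <- lfm_params(c(c1 = 2), a = 1.5, ndt = 0.3, sndt = 0.2, alpha = 1.5)
  tab2 <- simulate_dataset(p2, c(c1 = 2000), sim_config(seed = 5))
  expect_true(all(tab2$rt[!tab2$censored] >= 0.2))
  expect_true(any(tab2$rt[!tab2$censored] < 0.3 + tab2$decision_time[
    !tab2$censored]))
})

test_that("datasets are reproducible and tagged by condition", {
  p <- lfm_params(c(word = 2, nonword = -2), a = 1.5, alpha = 1.4)
  cfg <- sim_config(seed = 9)
  t1 <- simulate_dataset(p, c(word = 100, nonword = 50), cfg)
  t2 <- simulate_dataset(p, c(word = 100, nonword = 50), cfg)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_equal(nrow(t1), 150)
  expect_equal(sum(t1$condition == "word"), 100)
})

test_that("lower alpha steepens the lower edge of the decision-time
           distribution", {
  # rare early jumps at low alpha put decisions in the first few
  # milliseconds: the 5th percentile falls relative to the median
  ratios <- sapply(c(1.2, 2), function(alpha) {
    p <- lfm_params(c(c1 = 1.5), a = 2, ndt = 0.3, alpha = alpha)
    tab <- simulate_dataset(p, c(c1 = 2e4),
                            sim_config(dt = 2e-3, seed = 13))
    q <- quantile(tab$decision_time[!tab$censored], c(0.05, 0.5))
    q[1] / q[2]
  })
  expect_lt(ratios[1], ratios[2])
})

test_that("the Wiener oracle is internally consistent", {
  expect_equal(wiener_oracle(0, 1, 0.5)$p_upper, 0.5)
  expect_equal(wiener_oracle(1, 2, 0.5, sqrt(2))$p_upper,
               (1 - exp(-1)) / (1 - exp(-2)), tolerance = 1e-10)
  tg <- seq(1e-3, 20, by = 1e-3)
  orc <- wiener_oracle(1, 1, 0.5, 1, tg)
  expect_lt(abs(sum(orc$f_upper) * 1e-3 - orc$p_upper), 1e-3)
  expect_lt(abs(sum(orc$f_lower) * 1e-3 - orc$p_lower), 1e-3)
  expect_error(wiener_oracle(1, -1, 0.5), "a")
})

test_that("halving the Euler step does not shift hitting probabilities", {
  for (alpha in c(1.2, 1.6, 2)) {
    ps <- sapply(c(4e-3, 2e-3), function(dt) {
      p <- lfm_params(c(c1 = 1.5), a = 1.5, ndt = 0, alpha = alpha)
      tab <- simulate_dataset(p, c(c1 = 2e4),
                              sim_config(dt = dt,
                                         seed = round(1000 * dt + alpha)))
      mean(tab$response == 1, na.rm = TRUE)
    })
    pooled_se <- sqrt(sum(ps * (1 - ps) / 2e4))
    expect_lt(abs(ps[1] - ps[2]), 3 * pooled_se + 0.005)
  }
})

test_that("mean decision time falls as the boundary tightens", {
  means <- sapply(c(2.5, 2.0, 1.5, 1.0), function(a) {
    p <- lfm_params(c(c1 = 1.5), a = a, ndt = 0, alpha = 1.6)
    tab <- simulate_dataset(p, c(c1 = 1e4),
                            sim_config(dt = 2e-3, seed = round(a * 10)))
    mean(tab$decision_time[!tab$censored])
  })
  expect_true(all(diff(means) < 0))
})

test_that("prediction summaries partition paths and show fast errors", {
  base <- lfm_params(c(c1 = 1.5), a = 1.5, zr = 0.5, ndt = 0.3,
                     alpha = 1.5)
  ps <- characterize_predictions(base, c(1, 2), n_paths = 2e4,
                                 cfg = sim_config(dt = 2e-3, seed = 21))
  expect_equal(ps$pc + ps$p_error + ps$p_censored, rep(1, 2))
  # errors faster than correct responses at alpha = 1
  gap1 <- ps$mean_correct[1] - ps$mean_error[1]
  expect_gt(gap1, 0)
  # the gap closes at the Gaussian limit (equal conditional FPT laws)
  gap2 <- abs(ps$mean_correct[2] - ps$mean_error[2])
  se2 <- sqrt(ps$sd_correct[2]^2 / (2e4 * ps$pc[2]) +
                ps$sd_error[2]^2 / (2e4 * ps$p_error[2]))
  expect_lt(gap2, 3 * se2)
  expect_error(characterize_predictions(base, c(0.9, 2)), "alpha_grid")
  expect_error(characterize_predictions(base, 1.5, n_paths = 100),
               "n_paths")
})
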