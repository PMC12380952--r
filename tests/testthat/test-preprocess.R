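# RT filters, the variance-stabilizing transform, and behavioral measures.

mk_trials <- function(rt, participant = 1, condition = "c1", response = 1,
                      session = 1, task = "T") {
  tibble::tibble(participant = participant, session = session, task = task,
                 condition = condition, response = response, rt = rt)
}

test_that("absolute bounds drop fast and slow trials", {
  tr <- mk_trials(c(0.15, 0.5, 2.6))
  out <- apply_rt_filter(tr, filter_rule("lerche"))
  expect_equal(out$trials$rt, 0.5)
  expect_equal(out$log$n_removed_bounds, 2)
  expect_equal(out$log$n_removed_sd, 0)
  expect_error(apply_rt_filter(tr[0, ], filter_rule("lerche")), "empty")
})

test_that("the participant-level SD step catches stragglers inside the
           absolute bounds", {
  set.seed(8)
  tr <- mk_trials(c(rnorm(1000, 0.6, 0.1), 2.9))
  out <- apply_rt_filter(tr, filter_rule("elp"))
  expect_false(2.9 %in% out$trials$rt)
  expect_gte(out$log$n_removed_sd, 1)
  # identical trials: zero SD removes nothing
  out2 <- apply_rt_filter(mk_trials(rep(0.5, 20)), filter_rule("elp"))
  expect_equal(nrow(out2$trials), 20)
})

test_that("the condition-level log-RT rule works per cell and filtering is
           idempotent", {
  set.seed(9)
  tr <- dplyr::bind_rows(
    mk_trials(exp(rnorm(500, log(0.5), 0.1)), condition = "c1"),
    mk_trials(c(exp(rnorm(500, log(0.9), 0.1)), 2.95), condition = "c2"))
  out <- apply_rt_filter(tr, filter_rule("schubert"))
  expect_false(2.95 %in% out$trials$rt)
  again <- apply_rt_filter(out$trials, filter_rule("schubert"))
  expect_equal(nrow(again$trials), nrow(out$trials))
  # a participant losing everything is flagged, not silently dropped
  tr2 <- dplyr::bind_rows(mk_trials(rep(0.05, 5), participant = 7),
                          mk_trials(rep(0.5, 5), participant = 8))
  out2 <- apply_rt_filter(tr2, filter_rule("schubert"))
  expect_equal(out2$log$participants_fully_excluded, 7)
})

test_that("stabilizing transform is monotone with a verifiable arcsin
           midpoint", {
  x <- c(1.05, 1.3, 1.5, 1.77, 1.95)
  st <- stabilizing_transform(x, subtract_one = TRUE)
  expect_false(is.unsorted(st$values))
  expect_equal(cor(x, st$values, method = "spearman"), 1)
  expect_equal(asin(1.5 - 1), 0.5236, tolerance = 1e-4)
  # accuracy chain: same pipeline without the subtraction
  acc <- c(0.62, 0.8, 0.9, 0.97)
  st2 <- stabilizing_transform(acc)
  expect_false(is.unsorted(st2$values))
  expect_error(stabilizing_transform(c(0.5, 1.5)), "out of range")
  expect_error(stabilizing_transform(rep(0.5, 5)), "constant")
  # random monotonicity sweep
  set.seed(10)
  for (i in 1:5) {
    v <- sort(runif(50))
    expect_false(is.unsorted(stabilizing_transform(v)$values))
  }
})

test_that("participant measures match hand-computable cases", {
  rt <- exp(c(0, 1, 2, 3))
  tr <- mk_trials(rt)
  m <- participant_measures(tr)
  expect_equal(unlist(m[, paste0("q", 1:4, "_crt")], use.names = FALSE),
               c(0, 1, 2, 3))
  expect_equal(m$accuracy, 1)
  expect_true(is.na(m$mean_log_ert)) # no error trials
  expect_true(is.na(m$rt_diff))
  # mixed responses: rt_diff = mean log CRT - mean log ERT
  tr2 <- dplyr::bind_rows(mk_trials(c(0.6, 0.7), response = 1),
                          mk_trials(c(0.4, 0.5), response = 0))
  m2 <- participant_measures(tr2)
  expect_equal(m2$rt_diff,
               mean(log(c(0.6, 0.7))) - mean(log(c(0.4, 0.5))))
  expect_equal(m2$accuracy, 0.5)
})

test_that("sample skewness is near zero for symmetric RT distributions", {
  set.seed(11)
  tr <- mk_trials(exp(rnorm(1e4, log(0.6), 0.2)))
  m <- participant_measures(tr)
  expect_lt(abs(m$skew_crt), 0.1)
})

test_that("the ELP SD step removes the expected normal tail fraction", {
  set.seed(12)
  n_part <- 200; n_trial <- 500
  tr <- tibble::tibble(
    participant = rep(seq_len(n_part), each = n_trial),
    session = 1, task = "T", condition = "c1", response = 1,
    rt = rnorm(n_part * n_trial, 1.2, 0.15))
  out <- apply_rt_filter(tr, filter_rule("elp"))
  frac <- out$log$n_removed_sd / out$log$n_input
  # two-sided normal tail beyond 2.5 SD is ~1.24%
  expect_lt(abs(frac - 0.0124), 0.003)
})
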