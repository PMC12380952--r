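# The two-session synthetic study generator.

small_spec <- function(n = 50, rho_alpha = 0.6, shift_alpha = -0.08,
                       trials = 60, seed = 1) {
  tr <- default_traits()
  tr$rho[tr$param == "alpha"] <- rho_alpha
  tr$shift[tr$param == "alpha"] <- shift_alpha
  population_spec(
    n_participants = n,
    task_designs = list(LDTlike = list(
      variant = "M2", design = c(c1 = trials, c2 = trials))),
    traits = tr, seed = seed)
}

test_that("perfect trait correlation with no shift copies sessions", {
  spec <- small_spec(n = 40, rho_alpha = 1, shift_alpha = 0)
  truth <- generate_population(spec)
  a1 <- truth$alpha[truth$session == 1]
  a2 <- truth$alpha[truth$session == 2]
  expect_equal(a1, a2)
})

test_that("planted trait correlations are recovered at the Fisher-z
           rate", {
  hits <- 0; reps <- 200
  for (i in seq_len(reps)) {
    truth <- generate_population(small_spec(n = 500, seed = 1000 + i))
    r <- cor(truth$alpha[truth$session == 1],
             truth$alpha[truth$session == 2])
    z <- atanh(r); half <- 1.96 / sqrt(500 - 3)
    if (atanh(0.6) > z - half && atanh(0.6) < z + half) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.93)
})

test_that("a negative practice shift lowers session-2 stability
           indices", {
  tr <- default_traits()
  tr$shift[tr$param == "alpha"] <- -0.1
  spec <- population_spec(n_participants = 200,
                          task_designs = list(T1 = list(
                            variant = "M2", design = c(c1 = 40, c2 = 40))),
                          traits = tr, seed = 3)
  truth <- generate_population(spec)
  a1 <- truth$alpha[truth$session == 1]
  a2 <- truth$alpha[truth$session == 2]
  expect_lt(t.test(a2, a1, paired = TRUE)$p.value / 2, 0.05)
  expect_lt(mean(a2), mean(a1))
})

test_that("generated parameters respect their ranges and clipping is
           reported", {
  truth <- generate_population(small_spec(n = 300, seed = 4))
  expect_true(all(truth$alpha >= 1.01 & truth$alpha <= 1.99))
  expect_true(all(truth$a >= 0.5 & truth$a <= 3))
  expect_true(all(truth$ndt >= 0.1 & truth$ndt <= 0.8))
  expect_true(is.numeric(attr(truth, "clip_fraction")))
  bad <- default_traits()
  bad$mean[bad$param == "alpha"] <- 4
  expect_error(population_spec(traits = bad), "infeasible")
})

test_that("study generation is deterministic bookkeeping over the
           design", {
  spec <- small_spec(n = 6, trials = 50, seed = 9)
  cfg <- sim_config(dt = 0.005, max_time = 5, seed = 2)
  study <- generate_study(spec, cfg)
  expect_equal(nrow(study$truth), 6 * 2)
  expect_equal(nrow(study$trials), 6 * 2 * 100)
  expect_setequal(unique(study$trials$condition), c("c1", "c2"))
  study2 <- generate_study(spec, cfg)
  expect_identical(as.data.frame(study$trials),
                   as.data.frame(study2$trials))
  expect_true(all(c("participant", "session", "task", "condition",
                    "response", "rt") %in% names(study$trials)))
})
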