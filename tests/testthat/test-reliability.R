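# The statistical suite: screening, correlation, MI/CMI, GBR, practice
# effects, regressions.

test_that("Mahalanobis screening removes gross outliers at the documented
           cutoff", {
  set.seed(21)
  ps <- paired_series(1:201, c(rnorm(200), 10), c(rnorm(200), 10))
  out <- mahalanobis_filter(ps, 0.001)
  expect_equal(out$excluded_ids, 201)
  expect_equal(out$cutoff, qchisq(0.999, 2))
  expect_equal(round(out$cutoff, 4), 13.8155)
  degenerate <- paired_series(1:5, 1:5, 2 * (1:5))
  expect_error(mahalanobis_filter(degenerate), "degenerate")
  expect_error(mahalanobis_filter(ps, 0.7), "p_threshold")
})

test_that("retest correlation handles exact and degenerate relations", {
  x <- rnorm(50)
  expect_equal(retest_correlation(paired_series(1:50, x, x))$r, 1)
  expect_equal(retest_correlation(paired_series(1:50, x, -x))$r, -1)
  flat <- retest_correlation(paired_series(1:50, rep(1, 50), x))
  expect_true(is.na(flat$r))
  expect_true(flat$undefined)
})

test_that("retest estimates cover the population correlation at the
           Fisher-z rate", {
  set.seed(22)
  rho <- 0.6; n <- 500; hits <- 0; reps <- 200
  for (i in seq_len(reps)) {
    x <- rnorm(n); y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    r <- retest_correlation(paired_series(seq_len(n), x, y))$r
    z <- atanh(r); half <- 1.96 / sqrt(n - 3)
    if (atanh(rho) > z - half && atanh(rho) < z + half) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.93)
})

test_that("k-NN MI matches the Gaussian closed form and exceeds it under
           nonlinearity", {
  set.seed(23)
  n <- 2000
  for (rho in c(0, 0.5, 0.9)) {
    x <- rnorm(n); y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    mi <- knn_mi(x, y)
    tol <- c(`0` = 0.05, `0.5` = 0.07, `0.9` = 0.10)[as.character(rho)]
    expect_lt(abs(mi$mi_mean - gaussian_mi(rho)), tol)
  }
  x <- rnorm(n); y <- x^2 + 0.1 * rnorm(n)
  expect_gte(knn_mi(x, y)$mi_mean, 0.3)
  expect_lte(gaussian_mi(cor(x, y)), 0.02)
  expect_error(knn_mi(x[1:30], y[1:30]), "n >= 50")
  expect_error(knn_mi(x[1:100], y[1:100], k_grid = 60), "k")
  mib <- knn_mi(x, y, unit = "bits")
  expect_equal(mib$mi_mean, knn_mi(x, y)$mi_mean / log(2))
})

test_that("gaussian_mi anchors evaluate exactly", {
  expect_equal(gaussian_mi(0), 0)
  expect_equal(gaussian_mi(0.5), 0.14384, tolerance = 1e-4)
  expect_equal(gaussian_mi(0.9), 0.83037, tolerance = 1e-4)
  expect_error(gaussian_mi(1), "r")
})

test_that("CMI retention separates irrelevant conditioning from a common
           cause", {
  set.seed(24)
  n <- 2000
  # irrelevant conditioning: retention ~ 1
  x <- rnorm(n); y <- 0.6 * x + 0.8 * rnorm(n); w <- rnorm(n)
  ret <- cmi_retention(x, y, list(w = w))
  expect_lt(abs(ret$sets$w$retention_mean - 1), 0.15)
  # common cause: conditioning removes the dependence
  z <- rnorm(n); x1 <- z + rnorm(n); x2 <- z + rnorm(n)
  ret2 <- cmi_retention(x1, x2, list(z = z))
  expect_lt(ret2$sets$z$retention_mean, 0.25)
  # Gaussian triple: CMI matches the partial-correlation closed form
  pc <- with(list(r12 = cor(x1, x2), r1z = cor(x1, z), r2z = cor(x2, z)),
             (r12 - r1z * r2z) / sqrt((1 - r1z^2) * (1 - r2z^2)))
  expect_lt(abs(mean(ret2$sets$z$cmi_per_k) + 0.5 * log(1 - pc^2)), 0.1)
  # high-dimensional conditioning refused
  expect_error(cmi_retention(x1, x2, list(big = cbind(z, x, y))),
               "unsupported dimension")
})

test_that("GBR finds a planted signal, reports honest null fits, and is
           reproducible", {
  set.seed(25)
  n <- 250
  f <- data.frame(alpha_s1 = rnorm(n), a_s1 = rnorm(n), ndt_s1 = rnorm(n))
  g <- gbr_reliability(f, 2 * f$alpha_s1, seed = 1)
  expect_gte(g$cv_r2_mean, 0.95)
  imp <- g$importances
  expect_equal(imp$feature[which.max(imp$importance)], "alpha_s1")
  g0 <- gbr_reliability(f, rnorm(n), seed = 1)
  expect_lte(g0$cv_r2_mean, 0.05)
  # row-order invariance and seed determinism
  perm <- sample(n)
  g2 <- gbr_reliability(f[perm, ], (2 * f$alpha_s1)[perm], seed = 1)
  expect_equal(g2$cv_r2_mean, g$cv_r2_mean)
  expect_equal(g2$importances$importance, g$importances$importance)
  expect_error(gbr_reliability(f[1:10, ], rnorm(10), folds = 5), "5 rows")
})

test_that("GBR partial dependence of a monotone signal is monotone", {
  set.seed(26)
  n <- 250
  x <- rnorm(n)
  f <- data.frame(u = x, w = rnorm(n))
  g <- gbr_reliability(f, x + 0.05 * rnorm(n), seed = 2)
  # stepwise tree ensembles allow micro-dips; require near-monotonicity
  # plus a strong overall increasing trend
  rng <- diff(range(g$pdp$u$response))
  expect_true(all(diff(g$pdp$u$response) > -0.01 * rng))
  expect_gt(cor(g$pdp$u$grid, g$pdp$u$response, method = "spearman"),
            0.99)
})

test_that("practice-effect summaries reproduce the published effect sizes
           from their printed row statistics", {
  ref <- table3_reference()
  for (row in c("LDT.M2", "ELP.M1", "ELP.M2")) {
    parts <- strsplit(row, ".", fixed = TRUE)[[1]]
    r <- ref[ref$task == parts[1] & ref$model == parts[2], ]
    d <- cohen_d_rms(r$mean_s1, r$std_s1, r$mean_s2, r$std_s2)
    expect_lt(abs(d - r$cohen_d), 0.001)
  }
  # and for every row of the reference table
  d_all <- cohen_d_rms(ref$mean_s1, ref$std_s1, ref$mean_s2, ref$std_s2)
  expect_true(all(abs(d_all - ref$cohen_d) < 0.001))
})

test_that("the paired practice-effect test behaves on constructed data", {
  set.seed(27)
  s1 <- rnorm(60, 0.2, 0.1)
  pe <- practice_effect(s1, s1 - 0.05 + rnorm(60, 0, 0.02))
  expect_equal(pe$dof, 59)
  expect_lt(pe$p, 0.001)
  expect_true(pe$ci95[1] < pe$ci95[2])
  expect_gt(pe$cohen_d, 0)
  identical_sessions <- rnorm(10)
  expect_error(practice_effect(identical_sessions, identical_sessions),
               "degenerate")
})

test_that("regression presets detect planted effects and reject collinear
           designs", {
  set.seed(28)
  n <- 300
  meas <- data.frame(
    mean_log_crt = rnorm(n), mean_log_ert = rnorm(n),
    accuracy_T = rnorm(n), a = rnorm(n), ndt = rnorm(n))
  meas$alpha_T <- 0.6 * meas$mean_log_ert + rnorm(n, 0, 0.5)
  rep1 <- ols_suite(meas, "aspects")
  ert_row <- rep1$terms[rep1$terms$term == "mean_log_ert", ]
  expect_gt(ert_row$coefficient, 0)
  expect_lt(ert_row$p, 0.001)
  # null: no term significant, negligible R2
  meas$alpha_T <- rnorm(n)
  rep0 <- ols_suite(meas, "aspects")
  expect_lte(rep0$r_squared, 0.07)
  # duplicated predictor
  meas$rt_diff <- meas$mean_log_ert
  meas$sd_crt <- meas$mean_log_ert
  meas$skew_crt <- meas$mean_log_ert
  expect_error(ols_suite(meas, "shape"), "collinear")
  expect_error(ols_suite(meas[1:8, ], "rt_diff"), "complete cases")
})

test_that("null regressions rarely reach the strict significance level", {
  set.seed(29)
  n <- 300; sig <- 0
  for (i in 1:50) {
    meas <- data.frame(rt_diff = rnorm(n), alpha_T = rnorm(n))
    r <- ols_suite(meas, "rt_diff")
    pterm <- r$terms$p[r$terms$term == "rt_diff"]
    if (pterm < 0.001 || r$r_squared > 0.05) sig <- sig + 1
  }
  expect_lte(sig / 50, 0.05)
})
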