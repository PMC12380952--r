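# Retest reliability, mutual information, CMI retention, gradient-boosted
# intrinsic-reliability analysis, practice effects, and regression presets.

#' Matched paired series
#'
#' @param participant Participant ids.
#' @param x,y Matched values from two occasions (or two tasks).
#' @return A `paired_series` tibble.
#' @export
paired_series <- function(participant, x, y) {
  if (length(x) != length(y) || length(x) != length(participant))
    stop("participant, x and y must have equal length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 matched pairs", call. = FALSE)
  out <- tibble::tibble(participant = participant, x = x, y = y)
  class(out) <- c("paired_series", class(out))
  out
}

#' Bivariate outlier screening by Mahalanobis distance
#'
#' Squared Mahalanobis distances from the sample mean and covariance of
#' (x, y); pairs beyond the chi-squared(2) quantile at `1 - p_threshold`
#' (13.8155 at p = 0.001) are excluded in a single non-iterative pass.
#'
#' @param pairs A [paired_series()].
#' @param p_threshold Tail probability in (0, 0.5); default the screening
#'   level 0.001.
#' @return List with `kept` (paired_series), `excluded_ids`, and `cutoff`.
#' @export
mahalanobis_filter <- function(pairs, p_threshold = 0.001) {
  if (p_threshold <= 0 || p_threshold >= 0.5)
    stop("`p_threshold` must be in (0, 0.5)", call. = FALSE)
  if (nrow(pairs) < 3) stop("need n >= 3 pairs", call. = FALSE)
  m <- cbind(pairs$x, pairs$y)
  cv <- stats::cov(m)
  if (abs(det(cv)) < 1e-14)
    stop("degenerate geometry: singular covariance", call. = FALSE)
  d2 <- stats::mahalanobis(m, colMeans(m), cv)
  cutoff <- stats::qchisq(1 - p_threshold, df = 2)
  keep <- d2 <= cutoff
  list(kept = pairs[keep, , drop = FALSE],
       excluded_ids = pairs$participant[!keep], cutoff = cutoff, d2 = d2)
}

significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Test-retest (or across-task) Pearson correlation
#'
#' @param pairs A [paired_series()] (after any outlier screening).
#' @return List with `r`, `p`, `stars`, `n`; zero variance in either margin
#'   gives an NA sentinel instead of an error.
#' @export
retest_correlation <- function(pairs) {
  if (nrow(pairs) < 3) stop("need n >= 3 pairs", call. = FALSE)
  if (stats::sd(pairs$x) == 0 || stats::sd(pairs$y) == 0)
    return(list(r = NA_real_, p = NA_real_, stars = "",
                n = nrow(pairs), undefined = TRUE))
  ct <- stats::cor.test(pairs$x, pairs$y)
  list(r = unname(ct$estimate), p = ct$p.value,
       stars = significance_stars(ct$p.value), n = nrow(pairs),
       undefined = FALSE)
}

#' Kraskov k-NN mutual information
#'
#' KSG estimator (variant 1, max-norm) evaluated on a grid of neighbour
#' counts and averaged. A deterministic jitter of magnitude 1e-10 breaks
#' ties. Estimates are reported as computed (they can be slightly
#' negative).
#'
#' @param x,y Numeric vectors (n >= 50).
#' @param k_grid Neighbour counts, each < n/2.
#' @param unit "nats" (default) or "bits".
#' @return List with `mi_per_k` (named), `mi_mean`, `unit`.
#' @export
knn_mi <- function(x, y, k_grid = c(3, 5, 7, 10, 15, 20),
                   unit = c("nats", "bits")) {
  unit <- match.arg(unit)
  n <- length(x)
  if (n != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (n < 50) stop("need n >= 50", call. = FALSE)
  if (any(k_grid >= n / 2)) stop("all k must be < n/2", call. = FALSE)
  jit <- with_preserved_seed(20817L, {
    list(x = stats::runif(n, -1, 1) * 1e-10,
         y = stats::runif(n, -1, 1) * 1e-10)
  })
  xs <- as.numeric(scale(x)) + jit$x
  ys <- as.numeric(scale(y)) + jit$y
  mi <- vapply(k_grid, function(k) cpp_ksg_mi(xs, ys, as.integer(k)),
               numeric(1))
  if (unit == "bits") mi <- mi / log(2)
  list(mi_per_k = stats::setNames(mi, paste0("k", k_grid)),
       mi_mean = mean(mi), unit = unit)
}

#' Mutual information of a bivariate Gaussian
#'
#' `-0.5 * log(1 - r^2)` nats: the theoretical curve against which the
#' k-NN estimates are compared.
#'
#' @param r Pearson correlation, |r| < 1.
#' @param unit "nats" or "bits".
#' @return Mutual information.
#' @export
gaussian_mi <- function(r, unit = c("nats", "bits")) {
  unit <- match.arg(unit)
  if (any(abs(r) >= 1)) stop("|r| must be < 1", call. = FALSE)
  mi <- -0.5 * log(1 - r^2)
  if (unit == "bits") mi / log(2) else mi
}

#' Conditional-MI reliability retention index
#'
#' Estimates the unconditional MI between two session scores and the
#' conditional MI given each named conditioning set (dimension at most 2;
#' higher-dimensional sets are refused because the k-NN conditional
#' estimator becomes unreliable there). Retention = CMI / MI per k,
#' averaged over the k grid; ratios are reported raw and flagged when the
#' unconditional MI is too small to divide by.
#'
#' @param x1,x2 Session scores (matched).
#' @param conditioning Named list; each element a vector, matrix, or data
#'   frame with at most 2 columns.
#' @param k_grid Neighbour counts.
#' @param mi_floor Unconditional-MI magnitude below which retention ratios
#'   are flagged unreliable.
#' @return List per conditioning set with `cmi_per_k`, `retention_per_k`,
#'   `retention_mean`, and flags; plus the unconditional `mi` record.
#' @export
cmi_retention <- function(x1, x2, conditioning,
                          k_grid = c(3, 5, 7, 10, 15, 20),
                          mi_floor = 0.01) {
  n <- length(x1)
  if (n != length(x2)) stop("x1 and x2 must match", call. = FALSE)
  jit_seed <- 48613L
  mk_z <- function(z) {
    z <- as.matrix(z)
    if (ncol(z) > 2)
      stop("unsupported dimension: conditioning sets of dimension > 2 are ",
           "refused (k-NN conditional estimates become unreliable)",
           call. = FALSE)
    if (nrow(z) != n) stop("conditioning set must match x1/x2 length",
                           call. = FALSE)
    apply(z, 2, function(col) as.numeric(scale(col)))
  }
  zs <- lapply(conditioning, mk_z)
  jit <- with_preserved_seed(jit_seed, {
    lapply(1:2, function(i) stats::runif(n, -1, 1) * 1e-10)
  })
  xs <- as.numeric(scale(x1)) + jit[[1]]
  ys <- as.numeric(scale(x2)) + jit[[2]]
  mi_k <- vapply(k_grid, function(k) cpp_ksg_mi(xs, ys, as.integer(k)),
                 numeric(1))
  sets <- lapply(zs, function(z) {
    cmi_k <- vapply(k_grid, function(k)
      cpp_ksg_cmi(xs, ys, z, as.integer(k)), numeric(1))
    ratio <- cmi_k / mi_k
    list(cmi_per_k = stats::setNames(cmi_k, paste0("k", k_grid)),
         retention_per_k = stats::setNames(ratio, paste0("k", k_grid)),
         retention_mean = mean(ratio),
         outside_unit = any(ratio < 0 | ratio > 1),
         unreliable = abs(mean(mi_k)) < mi_floor)
  })
  list(mi_per_k = stats::setNames(mi_k, paste0("k", k_grid)),
       mi_mean = mean(mi_k), sets = sets,
       unreliable = abs(mean(mi_k)) < mi_floor)
}

#' Gradient-boosted intrinsic-reliability analysis
#'
#' Predicts a session-2 score (typically the transformed stability index)
#' from session-1 scores and nuisance parameters with gradient-boosted
#' regression trees under K-fold cross-validation. Reports mean/SD test R^2
#' (negative values are reportable), MAE, RMSE, held-out permutation
#' importances per feature, and one-dimensional partial-dependence curves.
#'
#' @param features Data frame of predictors (no missing cells).
#' @param target Numeric response.
#' @param folds Number of CV folds.
#' @param seed Integer seed (fold assignment and permutations).
#' @param nrounds,eta,max_depth,subsample Boosting hyperparameters.
#' @param n_perm Permutation-importance repeats per feature per fold.
#' @param pdp_points Grid size of the partial-dependence curves.
#' @return A `gbr_report` list.
#' @export
gbr_reliability <- function(features, target, folds = 5, seed = 1L,
                            nrounds = 500, eta = 0.05, max_depth = 3,
                            subsample = 1, n_perm = 30, pdp_points = 50) {
  features <- as.data.frame(features)
  n <- nrow(features)
  if (n < folds) stop("fewer rows than folds", call. = FALSE)
  if (n < 5 * folds) stop("need at least 5 rows per fold", call. = FALSE)
  if (anyNA(features) || anyNA(target))
    stop("missing cells are not allowed", call. = FALSE)
  # canonical row order makes the report invariant to input permutation
  ord <- do.call(order, c(list(target), as.list(features)))
  features <- features[ord, , drop = FALSE]
  target <- target[ord]
  X <- as.matrix(features)
  fold_id <- with_preserved_seed(seed, sample(rep(seq_len(folds),
                                                  length.out = n)))
  fnames <- colnames(X)
  r2s <- maes <- rmses <- numeric(folds)
  imp <- array(NA_real_, c(folds, n_perm, length(fnames)),
               dimnames = list(NULL, NULL, fnames))
  pdp_grid <- lapply(fnames, function(f)
    seq(min(X[, f]), max(X[, f]), length.out = pdp_points))
  names(pdp_grid) <- fnames
  pdp_acc <- lapply(fnames, function(f) matrix(0, folds, pdp_points))
  names(pdp_acc) <- fnames
  for (k in seq_len(folds)) {
    tr <- fold_id != k; te <- !tr
    dtr <- xgboost::xgb.DMatrix(X[tr, , drop = FALSE], label = target[tr])
    bst <- xgboost::xgb.train(params = list(eta = eta,
                                            max_depth = max_depth,
                                            subsample = subsample,
                                            nthread = 1,
                                            objective = "reg:squarederror"),
                              data = dtr, nrounds = nrounds, verbose = 0)
    pred <- stats::predict(bst, xgboost::xgb.DMatrix(X[te, , drop = FALSE]))
    res <- target[te] - pred
    sst <- sum((target[te] - mean(target[te]))^2)
    r2s[k] <- 1 - sum(res^2) / sst
    maes[k] <- mean(abs(res)); rmses[k] <- sqrt(mean(res^2))
    perm_idx <- with_preserved_seed(seed + 1000L * k, {
      lapply(seq_len(n_perm), function(r) sample(sum(te)))
    })
    for (f in fnames) {
      for (r in seq_len(n_perm)) {
        Xp <- X[te, , drop = FALSE]
        Xp[, f] <- Xp[perm_idx[[r]], f]
        rp <- target[te] - stats::predict(bst, xgboost::xgb.DMatrix(Xp))
        imp[k, r, f] <- (1 - sum(rp^2) / sst) # permuted R^2
      }
      # PDP on the training fold's model, averaged over all rows
      for (g in seq_len(pdp_points)) {
        Xg <- X
        Xg[, f] <- pdp_grid[[f]][g]
        pdp_acc[[f]][k, g] <- mean(stats::predict(bst, xgboost::xgb.DMatrix(Xg)))
      }
    }
  }
  imp_drop <- sweep(-imp, 1, r2s, "+") # baseline R2 - permuted R2
  importances <- tibble::tibble(
    feature = fnames,
    importance = vapply(fnames, function(f) mean(imp_drop[, , f]),
                        numeric(1)),
    importance_sd = vapply(fnames, function(f) stats::sd(c(imp_drop[, , f])),
                           numeric(1)))
  pdp <- lapply(fnames, function(f)
    tibble::tibble(grid = pdp_grid[[f]], response = colMeans(pdp_acc[[f]])))
  names(pdp) <- fnames
  structure(list(cv_r2_mean = mean(r2s), cv_r2_sd = stats::sd(r2s),
                 mae_mean = mean(maes), rmse_mean = mean(rmses),
                 importances = importances, pdp = pdp, folds = folds,
                 seed = seed),
            class = "gbr_report")
}

#' Practice-effect test
#'
#' Paired two-sided t test between matched session-1 and session-2 scores,
#' with Cohen's d computed as the absolute mean difference over the
#' root-mean-square of the two session SDs.
#'
#' @param s1,s2 Matched session scores (n >= 3).
#' @return A `practice_effect` list: session means/SDs, t, dof, p, 95% CI of
#'   the mean difference, and cohen_d.
#' @export
practice_effect <- function(s1, s2) {
  if (length(s1) != length(s2)) stop("sessions must be matched",
                                     call. = FALSE)
  if (length(s1) < 3) stop("need n >= 3 pairs", call. = FALSE)
  if (stats::sd(s1 - s2) == 0)
    stop("degenerate: zero-variance differences", call. = FALSE)
  tt <- stats::t.test(s1, s2, paired = TRUE)
  structure(list(
    mean_s1 = mean(s1), std_s1 = stats::sd(s1),
    mean_s2 = mean(s2), std_s2 = stats::sd(s2),
    t = unname(tt$statistic), dof = unname(tt$parameter),
    p = tt$p.value, ci95 = unname(tt$conf.int),
    cohen_d = cohen_d_rms(mean(s1), stats::sd(s1), mean(s2),
                          stats::sd(s2)),
    n = length(s1)), class = "practice_effect")
}

#' Cohen's d from session summary statistics
#'
#' `|mean_s1 - mean_s2| / sqrt((std_s1^2 + std_s2^2) / 2)`: the mean
#' difference scaled by the root-mean-square of the two session SDs, the
#' convention that reproduces published practice-effect effect sizes from
#' their printed row summaries.
#'
#' @param mean_s1,std_s1,mean_s2,std_s2 Session means and SDs.
#' @return Cohen's d (non-negative).
#' @export
cohen_d_rms <- function(mean_s1, std_s1, mean_s2, std_s2) {
  abs(mean_s1 - mean_s2) / sqrt((std_s1^2 + std_s2^2) / 2)
}

#' Regression presets relating the stability index to behavioral measures
#'
#' Ordinary least squares of the transformed stability index on a preset
#' term set, with every variable z-standardized before fitting (so
#' coefficient signs and significance are the comparable quantities):
#' \describe{
#'   \item{aspects}{mean log CRT, mean log ERT, transformed accuracy, a,
#'     ndt.}
#'   \item{crt_quartiles / ert_quartiles}{intercept + quartile-bin means
#'     q1-q4 of log CRT / log ERT.}
#'   \item{rt_diff}{intercept + (mean log CRT - mean log ERT).}
#'   \item{shape}{intercept + SD and skewness of log CRT.}
#' }
#'
#' @param measures Data frame holding the response column `alpha_T` plus
#'   the preset's predictors (see Details above for required names).
#' @param preset One of "aspects", "crt_quartiles", "ert_quartiles",
#'   "rt_diff", "shape".
#' @return A `regression_report`: preset, r_squared, and per-term
#'   coefficient/p tibble.
#' @export
ols_suite <- function(measures, preset = c("aspects", "crt_quartiles",
                                           "ert_quartiles", "rt_diff",
                                           "shape")) {
  preset <- match.arg(preset)
  terms <- switch(preset,
    aspects = c("mean_log_crt", "mean_log_ert", "accuracy_T", "a", "ndt"),
    crt_quartiles = c("q1_crt", "q2_crt", "q3_crt", "q4_crt"),
    ert_quartiles = c("q1_ert", "q2_ert", "q3_ert", "q4_ert"),
    rt_diff = "rt_diff",
    shape = c("sd_crt", "skew_crt"))
  need <- c("alpha_T", terms)
  missing_cols <- setdiff(need, names(measures))
  if (length(missing_cols) > 0)
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df <- measures[stats::complete.cases(measures[, need]), need, drop = FALSE]
  if (nrow(df) < 10 + length(terms))
    stop("too few complete cases (need >= ", 10 + length(terms), ")",
         call. = FALSE)
  dfz <- as.data.frame(lapply(df, function(col) as.numeric(scale(col))))
  mm <- stats::model.matrix(~ ., dfz[, terms, drop = FALSE])
  qr_rank <- qr(mm)$rank
  if (qr_rank < ncol(mm)) {
    al <- colnames(mm)[(qr_rank + 1):ncol(mm)]
    stop("collinear design: offending term(s) ", paste(al, collapse = ", "),
         call. = FALSE)
  }
  fit <- stats::lm(stats::reformulate(terms, "alpha_T"), data = dfz)
  sm <- summary(fit)
  co <- stats::coef(sm)
  structure(list(preset = preset, r_squared = sm$r.squared,
                 n = nrow(df),
                 terms = tibble::tibble(
                   term = rownames(co),
                   coefficient = co[, "Estimate"],
                   p = co[, "Pr(>|t|)"],
                   stars = significance_stars(co[, "Pr(>|t|)"]))),
            class = "regression_report")
}
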