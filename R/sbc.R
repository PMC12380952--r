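# Posterior-draw backends, simulation-based calibration, and the parameter
# recovery harness.

#' Summary-statistic vector for likelihood-free inference
#'
#' Fixed-length summary of a trial table given a model spec: per condition
#' and response option the trial count, RT deciles (0.1..0.9), and mean/SD
#' of log RT, plus the overall upper-response rate. Empty response cells are
#' filled with a 0 sentinel and flagged by the accompanying mask.
#'
#' @param trials Trial table (condition, response, rt).
#' @param spec A `model_spec`.
#' @return List with `stats` (numeric vector) and `mask` (logical vector,
#'   TRUE where the entry is real).
#' @export
summary_vector <- function(trials, spec) {
  conds <- names(spec$conditions)
  qs <- seq(0.1, 0.9, by = 0.1)
  stats_out <- c(); mask_out <- c()
  for (c in conds) {
    for (r in 0:1) {
      rt <- trials$rt[trials$condition == c & trials$response == r]
      rt <- rt[is.finite(rt)]
      if (length(rt) >= 2) {
        block <- c(length(rt), stats::quantile(rt, qs, names = FALSE),
                   mean(log(rt)), stats::sd(log(rt)))
        mask <- rep(TRUE, length(block))
      } else {
        block <- c(length(rt), rep(0, length(qs) + 2))
        mask <- c(TRUE, rep(FALSE, length(qs) + 2))
      }
      stats_out <- c(stats_out, block); mask_out <- c(mask_out, mask)
    }
  }
  stats_out <- c(stats_out, mean(trials$response == 1))
  mask_out <- c(mask_out, TRUE)
  list(stats = stats_out, mask = mask_out)
}

#' k-NN rejection-ABC backend
#'
#' Approximate posterior draws by nearest-neighbour rejection on summary
#' vectors: a reference table of prior draws and their simulated summaries
#' is built once per (spec, design) and reused; for observed data the
#' `n_draws` prior parameter vectors whose simulated summaries are closest
#' (Euclidean distance on per-column standardized summaries) are returned as
#' posterior draws. Coarse but draw-capable, which makes it eligible for
#' [run_sbc()].
#'
#' @param n_table Reference-table size (prior simulations).
#' @param dt,max_time Euler step and censoring horizon for the table
#'   simulations.
#' @return Backend object for [fit_participant()] / [run_sbc()].
#' @export
backend_abc <- function(n_table = 3000, dt = 0.005, max_time = 5) {
  cache <- new.env(parent = emptyenv())
  be <- list(id = "abc", n_table = n_table, dt = dt, max_time = max_time)
  be$sample_posterior <- function(trials, spec, prior, n_draws, seed) {
    design <- table(trials$condition)
    design <- stats::setNames(as.integer(design), names(design))
    key <- paste(spec$variant, paste(names(design), design, collapse = "_"),
                 sep = "|")
    if (is.null(cache[[key]])) {
      cfg <- sim_config(dt = dt, max_time = max_time, seed = 1L)
      tab <- with_preserved_seed(77001L, sample_prior(prior, n_table))
      S <- matrix(NA_real_, n_table, 0)
      slist <- vector("list", n_table)
      for (j in seq_len(n_table)) {
        cfg$seed <- (77100L + j) %% 2147480000L
        sim <- simulate_from_theta(tab[j, ], spec, design, cfg)
        sim <- sim[!sim$censored, , drop = FALSE]
        slist[[j]] <- summary_vector(sim, spec)$stats
      }
      S <- do.call(rbind, slist)
      mu <- colMeans(S); sdv <- apply(S, 2, stats::sd); sdv[sdv == 0] <- 1
      cache[[key]] <- list(theta = tab, S = S, mu = mu, sd = sdv)
    }
    ref <- cache[[key]]
    s_obs <- summary_vector(trials, spec)$stats
    z_obs <- (s_obs - ref$mu) / ref$sd
    Z <- sweep(sweep(ref$S, 2, ref$mu), 2, ref$sd, "/")
    d2 <- rowSums(sweep(Z, 2, z_obs)^2)
    idx <- order(d2)[seq_len(min(n_draws, nrow(ref$theta)))]
    ref$theta[idx, , drop = FALSE]
  }
  class(be) <- c("lfm_backend_abc", "lfm_backend")
  be
}

#' Simulation-based calibration of a posterior backend
#'
#' Draws `n_sims` parameter vectors from the prior, simulates a dataset from
#' each, obtains `n_draws` posterior draws from the backend, and records the
#' rank of the true value among the draws per parameter. For a calibrated
#' posterior the ranks are uniform on \{0..n_draws\}; uniformity is tested by
#' a chi-squared test on binned ranks.
#'
#' @param spec,prior Model variant and prior.
#' @param n_sims Number of simulated datasets (>= 100).
#' @param n_draws Posterior draws per dataset.
#' @param n_trials Trials per simulated dataset (split evenly over
#'   conditions).
#' @param backend A draw-capable backend (e.g. [backend_abc()]); the
#'   point-estimate reference backend is refused.
#' @param seed Integer seed.
#' @param n_bins Bins for the chi-squared uniformity test.
#' @return An `sbc_report`: ranks matrix plus per-parameter chi-squared
#'   statistic and p value.
#' @export
run_sbc <- function(spec, prior, n_sims = 200, n_draws = 100, n_trials = 500,
                    backend = backend_abc(), seed = 1L, n_bins = 10) {
  if (is.null(backend$sample_posterior))
    stop("unsupported backend: the point-estimate reference backend has no ",
         "posterior draws; use recovery_study() for it", call. = FALSE)
  if (n_sims < 100) stop("`n_sims` must be >= 100", call. = FALSE)
  theta_true <- with_preserved_seed(seed, sample_prior(prior, n_sims))
  conds <- names(spec$conditions)
  per_cond <- stats::setNames(rep(ceiling(n_trials / length(conds)),
                                  length(conds)), conds)
  ranks <- matrix(NA_integer_, n_sims, ncol(theta_true),
                  dimnames = list(NULL, colnames(theta_true)))
  cfg <- sim_config(dt = 0.005, max_time = 5, seed = 1L)
  for (i in seq_len(n_sims)) {
    cfg$seed <- (seed + 31L * i) %% 2147480000L
    sim <- simulate_from_theta(theta_true[i, ], spec, per_cond, cfg)
    sim <- sim[!sim$censored, , drop = FALSE]
    draws <- backend$sample_posterior(sim, spec, prior, n_draws,
                                      (seed + 7L * i) %% 2147480000L)
    ranks[i, ] <- colSums(sweep(draws, 2, theta_true[i, colnames(draws)],
                                "<"))
  }
  L <- n_draws
  tests <- lapply(colnames(ranks), function(p) {
    bins <- cut(ranks[, p], breaks = seq(-0.5, L + 0.5, length.out =
                                           n_bins + 1), include.lowest = TRUE)
    tab <- table(bins)
    ch <- suppressWarnings(stats::chisq.test(tab))
    data.frame(param = p, statistic = unname(ch$statistic),
               p_value = unname(ch$p.value))
  })
  structure(list(ranks = ranks, uniformity = do.call(rbind, tests),
                 n_draws = n_draws, n_sims = n_sims),
            class = "sbc_report")
}

#' Parameter recovery study
#'
#' Draws `n_participants` true parameter vectors from the prior, simulates
#' `n_trials` trials each, fits every dataset, and scores recovery per free
#' parameter: bias, RMSE, Pearson and Spearman correlation between truth and
#' estimate (plus the same for the drift composites when two drifts exist).
#' Zero-variance truths give an NA correlation sentinel rather than an
#' error.
#'
#' @param spec,prior Model variant and prior.
#' @param n_participants Number of simulated participants (>= 20).
#' @param n_trials Trials per participant, split evenly over conditions.
#' @param backend Estimation backend.
#' @param seed Integer seed (controls truths, data, and fits).
#' @param cfg_data [sim_config()] for the data-generating simulations.
#' @return List with `metrics` (tibble per parameter), `truth` and
#'   `estimates` matrices, and the run's seed.
#' @export
recovery_study <- function(spec, prior, n_participants = 100,
                           n_trials = 1000, backend = backend_reference(),
                           seed = 1L, cfg_data = sim_config(dt = 0.002,
                                                            max_time = 5)) {
  if (n_participants < 20)
    stop("`n_participants` must be >= 20", call. = FALSE)
  theta_true <- with_preserved_seed(seed, sample_prior(prior, n_participants))
  conds <- names(spec$conditions)
  per_cond <- stats::setNames(rep(ceiling(n_trials / length(conds)),
                                  length(conds)), conds)
  est <- matrix(NA_real_, n_participants, ncol(theta_true),
                dimnames = list(NULL, colnames(theta_true)))
  for (i in seq_len(n_participants)) {
    cfg_i <- cfg_data
    cfg_i$seed <- (seed + 101L * i) %% 2147480000L
    sim <- simulate_from_theta(theta_true[i, ], spec, per_cond, cfg_i)
    fit <- fit_participant(sim, spec, prior, backend,
                           seed = (seed + 13L * i) %% 2147480000L)
    est[i, ] <- fit$estimates[colnames(est)]
  }
  truth_df <- theta_true; est_df <- est
  if (all(c("v1", "v2") %in% colnames(est))) {
    truth_df <- cbind(truth_df,
                      v_total = theta_true[, "v1"] - theta_true[, "v2"],
                      v_bias = theta_true[, "v1"] + theta_true[, "v2"])
    est_df <- cbind(est_df, v_total = est[, "v1"] - est[, "v2"],
                    v_bias = est[, "v1"] + est[, "v2"])
  }
  safe_cor <- function(x, y, method) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y, method = method)
  }
  metrics <- dplyr::bind_rows(lapply(colnames(truth_df), function(p) {
    tr <- truth_df[, p]; es <- est_df[, p]
    tibble::tibble(param = p, bias = mean(es - tr),
                   rmse = sqrt(mean((es - tr)^2)),
                   pearson = safe_cor(tr, es, "pearson"),
                   spearman = safe_cor(tr, es, "spearman"))
  }))
  list(metrics = metrics, truth = truth_df, estimates = est_df, seed = seed)
}
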