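# Simulation-based fitting of per-participant LFM parameters.

#' Reference estimation backend: quantile-bin composite likelihood
#'
#' Deterministic, derivative-free point estimation by the
#' quantile-probability method. Bins are fixed by the observed data: per
#' condition and response option, edges at the observed RT quantiles
#' `probs`. For a candidate parameter vector, `n_sim` trials per condition
#' are simulated with a common-random-number pool (the same
#' uniform/exponential noise inputs are re-scaled per alpha through the
#' Chambers-Mallows-Stuck transform, so the objective is a deterministic
#' function of the parameters); the simulated proportion in each bin is the
#' predicted probability and the observed counts are scored by the
#' multinomial log-likelihood, maximized by differential evolution within
#' the prior bounds followed by a Nelder-Mead polish on the same surface.
#'
#' @param n_sim Simulated trials per condition per objective evaluation.
#' @param probs Quantile levels defining the bins. The default includes
#'   tail quantiles (0.025, 0.975) because the stability index is identified
#'   mostly by the tails of the RT distribution.
#' @param pop,generations Differential-evolution population size and
#'   maximum generations.
#' @param de_f,de_cr DE mutation weight and crossover rate.
#' @param dt,max_time Euler step and censoring horizon used for the
#'   candidate simulations.
#' @param tol,patience Early-stopping: stop when the population objective
#'   spread falls below `tol`, or after `patience` generations without
#'   improvement.
#' @param nm_iter Maximum iterations of the Nelder-Mead polish run from the
#'   DE optimum on the same (deterministic) CRN surface; 0 disables it.
#' @return A backend object usable by [fit_participant()].
#' @export
backend_reference <- function(n_sim = 1500,
                              probs = c(0.025, 0.05, 0.1, 0.2, 0.3, 0.4,
                                        0.5, 0.6, 0.7, 0.8, 0.9, 0.95,
                                        0.975),
                              pop = 24, generations = 40, de_f = 0.7,
                              de_cr = 0.9, dt = 0.005, max_time = 5,
                              tol = 0.2, patience = 12, nm_iter = 250) {
  structure(list(id = "reference", n_sim = n_sim, probs = probs, pop = pop,
                 generations = generations, de_f = de_f, de_cr = de_cr,
                 dt = dt, max_time = max_time, tol = tol,
                 patience = patience, nm_iter = nm_iter,
                 sample_posterior = NULL),
            class = c("lfm_backend_reference", "lfm_backend"))
}

# Latin-hypercube initial population within bounds (uses current RNG state).
lhs_population <- function(pop, lower, upper) {
  d <- length(lower)
  u <- vapply(seq_len(d), function(j)
    (sample.int(pop) - stats::runif(pop)) / pop, numeric(pop))
  sweep(sweep(matrix(u, nrow = pop), 2, upper - lower, "*"), 2, lower, "+")
}

# Differential evolution (rand/1/bin) maximizer; deterministic given the
# RNG state at entry. `repair` enforces joint parameter constraints.
de_maximize <- function(obj, lower, upper, pop, generations, de_f, de_cr,
                        tol, patience, repair = identity) {
  d <- length(lower)
  X <- lhs_population(pop, lower, upper)
  X <- t(apply(X, 1, repair))
  f <- apply(X, 1, obj)
  n_evals <- pop
  best_hist <- max(f)
  stale <- 0L
  for (g in seq_len(generations)) {
    for (i in seq_len(pop)) {
      r <- sample(setdiff(seq_len(pop), i), 3)
      mutant <- X[r[1], ] + de_f * (X[r[2], ] - X[r[3], ])
      cross <- stats::runif(d) < de_cr
      cross[sample.int(d, 1)] <- TRUE
      trial <- ifelse(cross, mutant, X[i, ])
      trial <- pmin(pmax(trial, lower), upper)
      trial <- repair(trial)
      ft <- obj(trial)
      n_evals <- n_evals + 1L
      if (ft >= f[i]) { X[i, ] <- trial; f[i] <- ft }
    }
    if (max(f) > best_hist + 1e-9) { best_hist <- max(f); stale <- 0L }
    else stale <- stale + 1L
    if (max(f) - min(f) < tol || stale >= patience) break
  }
  i_best <- which.max(f)
  list(par = X[i_best, ], value = f[i_best], n_evals = n_evals,
       generations = g)
}

# Enforce ndt - sndt/2 > 0.05 on a free-parameter vector.
make_repair <- function(param_names) {
  has <- all(c("ndt", "sndt") %in% param_names)
  i_ndt <- match("ndt", param_names); i_sndt <- match("sndt", param_names)
  function(theta) {
    if (has) {
      cap <- max(2 * (theta[i_ndt] - 0.05), 0)
      if (theta[i_sndt] > cap) theta[i_sndt] <- cap
    }
    theta
  }
}

# Observed-quantile bin edges and bin counts arranged for the C++
# objective: per condition, the lower-response block then the
# upper-response block. Blocks without observed trials carry NaN edges.
prepare_observed <- function(trials, spec, probs) {
  conds <- names(spec$conditions)
  nq <- length(probs)
  edges <- c(); counts <- c()
  for (c in conds) {
    for (r in 0:1) {
      rt <- trials$rt[trials$condition == c & trials$response == r]
      if (length(rt) == 0) {
        edges <- c(edges, rep(NaN, nq))
        counts <- c(counts, rep(0, nq + 1))
      } else {
        e <- stats::quantile(rt, probs, names = FALSE, type = 7)
        cnt <- diff(c(0, findInterval(e, sort(rt)), length(rt)))
        edges <- c(edges, e)
        counts <- c(counts, cnt)
      }
    }
  }
  list(edges = edges, counts = counts, nq = nq)
}

#' Fit one participant's trial data
#'
#' Estimates the free parameters of a model variant from trial-level data by
#' simulation-based inference. Censored trials (and trials marked `censored`
#' in the table) are dropped before fitting with their count recorded in the
#' diagnostics.
#'
#' @param trials Trial table with columns condition, response (1 upper / 0
#'   lower) and rt (s); an optional logical `censored` column marks trials
#'   to drop.
#' @param spec A `model_spec` (see [default_model_spec()]).
#' @param prior A [prior_spec()].
#' @param backend A backend object, e.g. [backend_reference()] or
#'   [backend_abc()].
#' @param seed Integer seed; identical inputs and seed give an identical
#'   fit.
#' @param n_draws Posterior draws to return (draw-capable backends only).
#' @return An `lfm_fit`: list with `estimates` (all parameters, fixed ones
#'   included), optional `draws`, and `diagnostics`.
#' @export
fit_participant <- function(trials, spec, prior, backend = backend_reference(),
                            seed = 1L, n_draws = 500L) {
  if (!inherits(spec, "model_spec")) stop("`spec` must be a model_spec",
                                          call. = FALSE)
  n_cens <- 0L
  if ("censored" %in% names(trials)) {
    n_cens <- sum(trials$censored, na.rm = TRUE)
    trials <- trials[!trials$censored & !is.na(trials$rt), , drop = FALSE]
  }
  if (nrow(trials) < 40)
    stop("under-data: need >= 40 non-censored trials, got ", nrow(trials),
         call. = FALSE)
  bad <- setdiff(unique(trials$condition), names(spec$conditions))
  if (length(bad) > 0)
    stop("trial conditions not in model spec: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (length(unique(trials$response)) < 2)
    warning("degenerate data: all trials share one response; ",
            "estimates pushed toward the prior boundary", call. = FALSE)

  if (inherits(backend, "lfm_backend_reference")) {
    obs <- prepare_observed(trials, spec, backend$probs)
    pool <- cpp_crn_pool(seed, 2L^19L)
    param_names <- prior$param
    n_sim <- backend$n_sim
    obj <- function(theta) {
      names(theta) <- param_names
      cv <- theta_to_cond_vectors(theta, spec)
      cpp_qmle_loglik(cv$v, cv$ndt, cv$a, cv$zr, cv$sndt, cv$alpha,
                      backend$dt, backend$max_time, n_sim, pool,
                      obs$edges, obs$counts, obs$nq)
    }
    res <- with_preserved_seed(seed, {
      de_maximize(obj, prior$lower, prior$upper, backend$pop,
                  backend$generations, backend$de_f, backend$de_cr,
                  backend$tol, backend$patience,
                  repair = make_repair(param_names))
    })
    if (backend$nm_iter > 0) {
      # local polish on the same deterministic CRN surface
      lower <- prior$lower; upper <- prior$upper
      repair <- make_repair(param_names)
      obj_clamped <- function(theta)
        -obj(repair(pmin(pmax(theta, lower), upper)))
      nm <- stats::optim(res$par, obj_clamped, method = "Nelder-Mead",
                         control = list(maxit = backend$nm_iter,
                                        reltol = 1e-8,
                                        parscale = (upper - lower) / 10))
      if (-nm$value > res$value) {
        res$par <- repair(pmin(pmax(nm$par, lower), upper))
        res$value <- -nm$value
      }
      res$n_evals <- res$n_evals + nm$counts[1]
    }
    est <- stats::setNames(res$par, param_names)
    structure(list(
      estimates = c(est, spec$fixed),
      draws = NULL,
      diagnostics = list(loglik = res$value, n_evals = res$n_evals,
                         generations = res$generations,
                         n_sim = n_sim, censored_dropped = n_cens),
      backend = backend$id, variant = spec$variant, seed = seed),
      class = "lfm_fit")
  } else if (!is.null(backend$sample_posterior)) {
    draws <- backend$sample_posterior(trials, spec, prior, n_draws, seed)
    est <- colMeans(draws)
    structure(list(
      estimates = c(est, spec$fixed),
      draws = draws,
      diagnostics = list(n_draws = nrow(draws),
                         censored_dropped = n_cens),
      backend = backend$id, variant = spec$variant, seed = seed),
      class = "lfm_fit")
  } else {
    stop("unknown backend", call. = FALSE)
  }
}

#' @export
print.lfm_fit <- function(x, ...) {
  cat(sprintf("LFM fit (%s, backend %s)\n", x$variant, x$backend))
  print(round(x$estimates, 4))
  invisible(x)
}

#' Drift-rate composites
#'
#' Processing speed `v_total = v1 - v2` and accumulation bias
#' `v_bias = v1 + v2` from a two-drift fit (v1 belongs to the upper-boundary
#' stimulus class, v2 -- typically negative -- to the lower).
#'
#' @param fit An `lfm_fit` (or anything with named `estimates`).
#' @return Named numeric vector `c(v_total, v_bias)`.
#' @export
drift_composites <- function(fit) {
  est <- if (inherits(fit, "lfm_fit")) fit$estimates else fit
  if (!all(c("v1", "v2") %in% names(est)))
    stop("unsupported variant: drift composites need v1 and v2",
         call. = FALSE)
  c(v_total = unname(est["v1"] - est["v2"]),
    v_bias = unname(est["v1"] + est["v2"]))
}

# Simulate a trial table from a free-parameter vector under a model spec
# (handles per-condition non-decision times, as in the priming variants).
simulate_from_theta <- function(theta, spec, design, cfg) {
  cv <- theta_to_cond_vectors(theta, spec)
  conds <- names(spec$conditions)
  out <- lapply(seq_along(conds), function(i) {
    c_name <- conds[i]
    if (!c_name %in% names(design)) return(NULL)
    p <- lfm_params(drifts = stats::setNames(cv$v[i], c_name), a = cv$a,
                    zr = cv$zr, ndt = cv$ndt[i], sndt = cv$sndt,
                    alpha = cv$alpha)
    cfg_i <- cfg; cfg_i$seed <- (cfg$seed + i * 7919L) %% 2147480000L
    simulate_dataset(p, design[c_name], cfg_i)
  })
  dplyr::bind_rows(out)
}
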