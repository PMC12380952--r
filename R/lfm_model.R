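#' Levy-flight accumulator parameters
#'
#' Parameter vector of the Levy-flight decision model (LFM): evidence starts
#' at `zr * a`, drifts at rate `v` (per condition), and accumulates symmetric
#' alpha-stable noise until it reaches the upper boundary `a` or the lower
#' boundary 0. A non-decision time, uniform on
#' `[ndt - sndt/2, ndt + sndt/2]`, is added to the decision time.
#'
#' @param drifts Named numeric vector: drift rate per condition label
#'   (evidence units / s).
#' @param a Boundary separation (> 0).
#' @param zr Relative starting point in (0, 1); 0.5 is unbiased.
#' @param ndt Mean non-decision time (s, >= 0).
#' @param sndt Non-decision-time range (s, >= 0); `ndt - sndt/2` must be
#'   >= 0.
#' @param alpha Stability index in \[1, 2\].
#' @return An object of class `lfm_params`.
#' @export
lfm_params <- function(drifts, a, zr = 0.5, ndt = 0.3, sndt = 0, alpha = 2) {
  if (is.null(names(drifts)) || any(!nzchar(names(drifts))))
    stop("`drifts` must be a named vector (condition labels)", call. = FALSE)
  if (!all(is.finite(drifts)))
    stop("all drift rates must be finite", call. = FALSE)
  stopifnot_scalar <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("`%s` must be a single finite number", nm), call. = FALSE)
  }
  stopifnot_scalar(a, "a"); stopifnot_scalar(zr, "zr")
  stopifnot_scalar(ndt, "ndt"); stopifnot_scalar(sndt, "sndt")
  stopifnot_scalar(alpha, "alpha")
  if (a <= 0) stop("`a` must be > 0", call. = FALSE)
  if (zr <= 0 || zr >= 1) stop("`zr` must be in (0, 1)", call. = FALSE)
  if (ndt < 0 || sndt < 0 || ndt - sndt / 2 < 0)
    stop("need ndt >= 0, sndt >= 0 and ndt - sndt/2 >= 0", call. = FALSE)
  if (alpha < 1 || alpha > 2)
    stop("`alpha` must be in [1, 2]", call. = FALSE)
  structure(list(drifts = drifts, a = a, zr = zr, ndt = ndt, sndt = sndt,
                 alpha = alpha), class = "lfm_params")
}

#' @export
print.lfm_params <- function(x, ...) {
  cat("LFM parameters\n")
  cat("  drifts:", paste(sprintf("%s = %g", names(x$drifts), x$drifts),
                         collapse = ", "), "\n")
  cat(sprintf("  a = %g, zr = %g, ndt = %g, sndt = %g, alpha = %g\n",
              x$a, x$zr, x$ndt, x$sndt, x$alpha))
  invisible(x)
}

#' Simulation configuration
#'
#' @param dt Euler step (s), in (0, 0.01].
#' @param max_time Censoring horizon (s), >= 1: trials still undecided at
#'   `max_time` are returned censored.
#' @param seed Integer seed for the simulation RNG.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 1e-3, max_time = 10, seed = 1L) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0 ||
      dt > 0.01)
    stop("`dt` must be in (0, 0.01]", call. = FALSE)
  if (!is.numeric(max_time) || length(max_time) != 1L || max_time < 1)
    stop("`max_time` must be >= 1", call. = FALSE)
  structure(list(dt = dt, max_time = max_time, seed = as.integer(seed)),
            class = "sim_config")
}

with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a single LFM trial
#'
#' @param params An [lfm_params()] object.
#' @param condition Condition label; must name an entry of `params$drifts`.
#' @param cfg A [sim_config()].
#' @return A one-row data frame (see [simulate_dataset()] for the schema).
#' @export
simulate_trial <- function(params, condition, cfg = sim_config()) {
  simulate_dataset(params, stats::setNames(1L, condition), cfg)
}

#' Simulate an LFM trial table
#'
#' Forward-simulates the accumulator for each requested condition. The
#' returned table carries one row per trial with the decision boundary
#' (`response`: 1 upper, 0 lower), the full reaction time `rt` (decision
#' time plus non-decision time, seconds), the bare `decision_time`, and a
#' `censored` flag for trials still undecided at `max_time` (their response
#' and rt are `NA`). The number of censored trials is attached as attribute
#' `censored_count`.
#'
#' @param params An [lfm_params()] object.
#' @param design Named integer vector: trials per condition (all >= 1).
#' @param cfg A [sim_config()]; `cfg$seed` makes the table reproducible.
#' @return A tibble with columns condition, response, rt, decision_time,
#'   censored.
#' @export
simulate_dataset <- function(params, design, cfg = sim_config()) {
  if (!inherits(params, "lfm_params")) stop("`params` must be lfm_params",
                                            call. = FALSE)
  if (length(design) == 0L)
    stop("`design` must request at least one condition", call. = FALSE)
  if (is.null(names(design)) || any(!nzchar(names(design))))
    stop("`design` must be a named vector of trial counts", call. = FALSE)
  if (any(design < 1)) stop("all design counts must be >= 1", call. = FALSE)
  unknown <- setdiff(names(design), names(params$drifts))
  if (length(unknown) > 0)
    stop("condition(s) not present in params$drifts: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  v <- rep(unname(params$drifts[names(design)]), times = design)
  cond <- rep(names(design), times = design)
  sim <- with_preserved_seed(cfg$seed, {
    cpp_simulate_trials(v, params$a, params$zr, params$ndt, params$sndt,
                        params$alpha, cfg$dt, cfg$max_time)
  })
  out <- tibble::tibble(
    condition = cond,
    response = sim[, 2],
    rt = sim[, 4],
    decision_time = sim[, 1],
    censored = sim[, 3] == 1
  )
  attr(out, "censored_count") <- sum(out$censored)
  out
}

#' Analytic Wiener first-passage oracle (Gaussian-noise limit)
#'
#' At `alpha = 2` (and noise scale gamma = 1) the LFM is a Wiener diffusion
#' with diffusion coefficient `sqrt(2)`. This oracle returns the exact upper
#' boundary probability and the defective first-passage-time densities at
#' both boundaries, using the classical small-time / large-time series for
#' absorption of a drifting Brownian motion between two boundaries.
#'
#' @param v Drift rate.
#' @param a Boundary separation (> 0).
#' @param zr Relative starting point in (0, 1).
#' @param s Diffusion scale (> 0). The LFM's gamma = 1 noise corresponds to
#'   `s = sqrt(2)`.
#' @param t_grid Positive increasing vector of decision times (s).
#' @return List with `p_upper`, `p_lower`, and defective densities
#'   `f_upper`, `f_lower` evaluated on `t_grid`.
#' @export
wiener_oracle <- function(v, a, zr, s = 1, t_grid = seq(0.001, 10, by = 0.001)) {
  if (a <= 0 || s <= 0) stop("`a` and `s` must be > 0", call. = FALSE)
  if (zr <= 0 || zr >= 1) stop("`zr` must be in (0, 1)", call. = FALSE)
  if (any(t_grid <= 0) || is.unsorted(t_grid))
    stop("`t_grid` must be positive increasing", call. = FALSE)
  # reduce to unit diffusion
  av <- a / s; vv <- v / s
  p_upper <- if (abs(vv) < 1e-12) zr else
    (1 - exp(-2 * vv * zr * av)) / (1 - exp(-2 * vv * av))
  f_lower <- wfpt_lower(t_grid, vv, av, zr)
  f_upper <- wfpt_lower(t_grid, -vv, av, 1 - zr)
  list(p_upper = p_upper, p_lower = 1 - p_upper,
       f_upper = f_upper, f_lower = f_lower, t_grid = t_grid)
}

# Defective FPT density at the LOWER boundary of a unit-diffusion Wiener
# process with drift v, boundary separation a, relative start w. Switches
# between the small-time and large-time series by the standard accuracy
# criterion.
wfpt_lower <- function(t, v, a, w, eps = 1e-10) {
  vapply(t, function(tt) {
    tn <- tt / a^2 # normalized time
    # number of terms needed (Navarro & Fuss style bounds)
    ks <- 2L
    if (pi * tn * eps < 1) {
      ks <- max(2L, ceiling(sqrt(-2 * log(pi * tn * eps) / (pi^2 * tn))))
    }
    kl <- 1L
    if (pi * tn * eps < 1) {
      kl <- max(1L, ceiling(sqrt(-2 * log(pi * tn * eps)) / (pi * sqrt(tn))))
    }
    mult <- exp(-v * a * w - v^2 * tt / 2) / a^2
    if (ks < kl) {
      # small-time expansion
      k <- seq.int(-floor((ks - 1) / 2), ceiling((ks - 1) / 2))
      dens <- sum((w + 2 * k) * exp(-(w + 2 * k)^2 / (2 * tn))) /
        sqrt(2 * pi * tn^3)
    } else {
      k <- seq_len(kl)
      dens <- pi * sum(k * exp(-k^2 * pi^2 * tn / 2) * sin(k * pi * w))
    }
    max(mult * dens, 0)
  }, numeric(1))
}

#' Characterize predicted decision-time distributions across alpha
#'
#' For each alpha on a grid, simulates `n_paths` trials from a base
#' parameter set (alpha overridden), codes the upper boundary as the correct
#' response, and summarizes the decision-time distribution separately for
#' correct and error responses. Used to reproduce the fast-error signature of
#' heavy-tailed noise: at low alpha, errors arise from early large jumps and
#' are faster than correct responses; the gap closes as alpha approaches the
#' Gaussian case.
#'
#' @param base An [lfm_params()]; its first condition (or `condition`) is
#'   simulated.
#' @param alpha_grid Numeric vector of stability indices within \[1, 2\].
#' @param n_paths Trials per alpha (>= 1e4).
#' @param cfg A [sim_config()].
#' @param condition Condition label to simulate; defaults to the first.
#' @return Tibble, one row per alpha: `pc` (probability correct among all
#'   paths), fraction of errors and censored paths, and mean/SD/skew of the
#'   decision time for correct and error responses (NA when a cell is
#'   empty).
#' @export
characterize_predictions <- function(base, alpha_grid, n_paths = 1e4,
                                     cfg = sim_config(),
                                     condition = names(base$drifts)[1]) {
  if (any(alpha_grid < 1 | alpha_grid > 2))
    stop("`alpha_grid` must lie within [1, 2]", call. = FALSE)
  if (n_paths < 1e4) stop("`n_paths` must be >= 1e4", call. = FALSE)
  rows <- lapply(seq_along(alpha_grid), function(i) {
    p <- base
    p$alpha <- alpha_grid[i]
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + i - 1L
    tab <- simulate_dataset(p, stats::setNames(n_paths, condition), cfg_i)
    dtm <- tab$decision_time
    correct <- !tab$censored & tab$response == 1
    error <- !tab$censored & tab$response == 0
    summ <- function(x) {
      if (length(x) < 3) return(c(mean = NA_real_, sd = NA_real_,
                                  skew = NA_real_))
      c(mean = mean(x), sd = stats::sd(x),
        skew = e1071::skewness(x, type = 2))
    }
    sc <- summ(dtm[correct]); se <- summ(dtm[error])
    tibble::tibble(
      alpha = alpha_grid[i],
      pc = mean(correct),
      p_error = mean(error),
      p_censored = mean(tab$censored),
      mean_correct = sc["mean"], sd_correct = sc["sd"],
      skew_correct = sc["skew"],
      mean_error = se["mean"], sd_error = se["sd"], skew_error = se["skew"]
    )
  })
  dplyr::bind_rows(rows)
}
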