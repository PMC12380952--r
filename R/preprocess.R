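# Trial filtering, variance-stabilizing transformations, and per-participant
# behavioral measures.

#' Reaction-time filter rules
#'
#' Named presets mirroring the three source protocols:
#' \describe{
#'   \item{lerche}{absolute bounds 0.2-2.5 s, no SD step.}
#'   \item{elp}{absolute bounds 0.2-3.0 s, then per participant remove
#'     trials beyond 2.5 SD of that participant's mean raw RT.}
#'   \item{schubert}{absolute bounds 0.1-3.0 s, then per participant and
#'     condition remove trials whose log RT is beyond 3 SD of the cell
#'     mean.}
#' }
#'
#' @param name One of "lerche", "elp", "schubert", or "custom".
#' @param lower,upper Absolute RT bounds (s), used for "custom".
#' @param sd_rule "none", "participant_raw_2.5", or "condition_log_3".
#' @return A `filter_rule`.
#' @export
filter_rule <- function(name = c("lerche", "elp", "schubert", "custom"),
                        lower = NULL, upper = NULL, sd_rule = NULL) {
  name <- match.arg(name)
  rule <- switch(name,
    lerche = list(lower = 0.2, upper = 2.5, sd_rule = "none"),
    elp = list(lower = 0.2, upper = 3.0, sd_rule = "participant_raw_2.5"),
    schubert = list(lower = 0.1, upper = 3.0, sd_rule = "condition_log_3"),
    custom = list(lower = lower, upper = upper,
                  sd_rule = if (is.null(sd_rule)) "none" else sd_rule)
  )
  if (rule$lower >= rule$upper)
    stop("lower bound must be below upper bound", call. = FALSE)
  structure(c(list(name = name), rule), class = "filter_rule")
}

#' Apply a reaction-time filter
#'
#' Absolute bounds are applied first; the rule's SD-based step is then
#' computed on the surviving trials only. Participants who lose all their
#' trials are flagged in the log rather than silently dropped.
#'
#' @param trials Trial table with at least participant, condition, rt
#'   columns.
#' @param rule A [filter_rule()].
#' @return List with `trials` (filtered table) and `log` (counts per
#'   criterion and any fully-excluded participants).
#' @export
apply_rt_filter <- function(trials, rule) {
  if (nrow(trials) == 0) stop("empty trial table", call. = FALSE)
  if (!inherits(rule, "filter_rule")) stop("`rule` must be a filter_rule",
                                           call. = FALSE)
  n0 <- nrow(trials)
  keep_abs <- trials$rt >= rule$lower & trials$rt <= rule$upper
  out <- trials[keep_abs, , drop = FALSE]
  n_abs <- n0 - nrow(out)
  n_sd <- 0L
  if (rule$sd_rule == "participant_raw_2.5" && nrow(out) > 0) {
    keep <- unlist(lapply(split(seq_len(nrow(out)), out$participant),
      function(idx) {
        m <- mean(out$rt[idx]); s <- stats::sd(out$rt[idx])
        if (!is.finite(s) || s == 0) return(idx)
        idx[abs(out$rt[idx] - m) <= 2.5 * s]
      }))
    n_sd <- nrow(out) - length(keep)
    out <- out[sort(keep), , drop = FALSE]
  } else if (rule$sd_rule == "condition_log_3" && nrow(out) > 0) {
    grp <- interaction(out$participant, out$condition, drop = TRUE)
    keep <- unlist(lapply(split(seq_len(nrow(out)), grp), function(idx) {
      lr <- log(out$rt[idx])
      m <- mean(lr); s <- stats::sd(lr)
      if (!is.finite(s) || s == 0) return(idx)
      idx[abs(lr - m) <= 3 * s]
    }))
    n_sd <- nrow(out) - length(keep)
    out <- out[sort(keep), , drop = FALSE]
  }
  lost <- setdiff(unique(trials$participant), unique(out$participant))
  log <- list(rule = rule$name, n_input = n0,
              n_removed_bounds = n_abs, n_removed_sd = n_sd,
              n_kept = nrow(out),
              participants_fully_excluded = lost)
  list(trials = out, log = log)
}

#' Variance-stabilizing transformation for bounded scores
#'
#' The chain used for the stability index and for accuracy rates before
#' correlational analyses: optionally subtract 1 (mapping \[1, 2\] scores
#' into \[0, 1\]), apply `asin`, shift into positive territory if needed,
#' then a Box-Cox transformation with lambda chosen by profile maximum
#' likelihood. Every step is strictly monotone, so ranks are preserved
#' exactly.
#'
#' @param values Numeric vector in \[0, 1\] (or \[1, 2\] with
#'   `subtract_one = TRUE`).
#' @param subtract_one Subtract 1 first (for scores living on \[1, 2\]).
#' @return List with `values` (transformed), `lambda`, and `shift`.
#' @export
stabilizing_transform <- function(values, subtract_one = FALSE) {
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  x <- if (subtract_one) values - 1 else values
  if (any(x < 0 | x > 1))
    stop("values out of range: expected [", if (subtract_one) "1, 2" else
      "0, 1", "]", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("constant input: Box-Cox lambda undefined", call. = FALSE)
  y <- asin(x)
  shift <- 0
  if (any(y <= 0)) {
    shift <- abs(min(y)) + 1e-6
    y <- y + shift
  }
  # profile log-likelihood for the Box-Cox lambda
  bc_loglik <- function(lambda) {
    z <- if (abs(lambda) < 1e-8) log(y) else (y^lambda - 1) / lambda
    -length(y) / 2 * log(stats::var(z) * (length(y) - 1) / length(y)) +
      (lambda - 1) * sum(log(y))
  }
  lambda <- stats::optimize(bc_loglik, c(-5, 5), maximum = TRUE)$maximum
  z <- if (abs(lambda) < 1e-8) log(y) else (y^lambda - 1) / lambda
  list(values = z, lambda = lambda, shift = shift)
}

bin_means <- function(lr) {
  # mean log RT within the four quartile bins (cuts at the 25/50/75
  # percentiles of this participant's distribution)
  cuts <- stats::quantile(lr, c(0.25, 0.5, 0.75), names = FALSE)
  bin <- findInterval(lr, cuts, left.open = TRUE) + 1L
  vapply(1:4, function(b) if (any(bin == b)) mean(lr[bin == b]) else
    NA_real_, numeric(1))
}

#' Per-participant behavioral measures
#'
#' Computes, per (participant, session, task): mean log RT of correct and
#' error responses (CRT, ERT), accuracy, quartile-bin means q1-q4 of log
#' CRT and log ERT, SD and bias-corrected skewness of log CRT, and
#' `rt_diff = mean log CRT - mean log ERT`. Cells that need at least one
#' correct (or error) trial are NA-flagged when empty.
#'
#' @param trials Trial table with participant, session, task, response, rt.
#' @return Tibble, one row per participant-session-task.
#' @export
participant_measures <- function(trials) {
  if (!all(c("participant", "session", "task", "response", "rt") %in%
           names(trials)))
    stop("trial table must have participant, session, task, response, rt",
         call. = FALSE)
  trials <- trials[is.finite(trials$rt), , drop = FALSE]
  grp <- interaction(trials$participant, trials$session, trials$task,
                     drop = TRUE, sep = "\r")
  rows <- lapply(split(seq_len(nrow(trials)), grp), function(idx) {
    sub <- trials[idx, ]
    crt <- log(sub$rt[sub$response == 1])
    ert <- log(sub$rt[sub$response == 0])
    qc <- if (length(crt) >= 1) bin_means(crt) else rep(NA_real_, 4)
    qe <- if (length(ert) >= 1) bin_means(ert) else rep(NA_real_, 4)
    tibble::tibble(
      participant = sub$participant[1], session = sub$session[1],
      task = sub$task[1],
      n_trials = nrow(sub),
      accuracy = mean(sub$response == 1),
      mean_log_crt = if (length(crt)) mean(crt) else NA_real_,
      mean_log_ert = if (length(ert)) mean(ert) else NA_real_,
      q1_crt = qc[1], q2_crt = qc[2], q3_crt = qc[3], q4_crt = qc[4],
      q1_ert = qe[1], q2_ert = qe[2], q3_ert = qe[3], q4_ert = qe[4],
      sd_crt = if (length(crt) >= 2) stats::sd(crt) else NA_real_,
      skew_crt = if (length(crt) >= 3) e1071::skewness(crt, type = 2) else
        NA_real_,
      rt_diff = if (length(crt) && length(ert)) mean(crt) - mean(ert) else
        NA_real_)
  })
  dplyr::bind_rows(rows)
}
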