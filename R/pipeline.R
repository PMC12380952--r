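# Orchestration: synth -> fit -> preprocess -> analyze as one configured,
# logged, reproducible run.

#' Pipeline run configuration
#'
#' @param population A [population_spec()] (synthetic input), or NULL when
#'   `trials_csv` points at an existing trial table.
#' @param trials_csv Optional path to a trial CSV (columns participant,
#'   session, task, condition, response, rt; response coded 1 =
#'   upper/correct, 0 = lower/error).
#' @param rt_unit "s" or "ms" for the CSV's rt column.
#' @param filter_rule_name RT filter preset name (see [filter_rule()]).
#' @param backend Estimation backend.
#' @param analyses Character subset of c("retest", "mi", "cmi", "gbr",
#'   "practice", "regressions").
#' @param out_dir Output directory for the parameter table, report JSON and
#'   logs.
#' @param seed Integer master seed.
#' @param cfg [sim_config()] used for synthetic data generation.
#' @return A `run_config`.
#' @export
run_config <- function(population = population_spec(), trials_csv = NULL,
                       rt_unit = c("s", "ms"),
                       filter_rule_name = "lerche",
                       backend = backend_reference(),
                       analyses = c("retest", "mi", "cmi", "gbr",
                                    "practice", "regressions"),
                       out_dir = tempfile("lfm_run_"), seed = 1L,
                       cfg = sim_config()) {
  rt_unit <- match.arg(rt_unit)
  if (!is.null(trials_csv) && !file.exists(trials_csv))
    stop("trials_csv does not exist: ", trials_csv, call. = FALSE)
  analyses <- match.arg(analyses, several.ok = TRUE)
  structure(list(population = population, trials_csv = trials_csv,
                 rt_unit = rt_unit, filter_rule_name = filter_rule_name,
                 backend = backend, analyses = analyses, out_dir = out_dir,
                 seed = as.integer(seed), cfg = cfg),
            class = "run_config")
}

log_stage <- function(log_path, stage, ...) {
  rec <- c(list(stage = stage), list(...))
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n", file = log_path,
      append = TRUE)
}

#' Run the full analysis pipeline
#'
#' Stages: obtain trials (synthesize or load) -> RT filter -> fit every
#' (participant, session, task) -> behavioral measures -> reliability
#' analyses (retest r with Mahalanobis screening, k-NN MI, CMI retention,
#' gradient-boosted intrinsic reliability, practice effects, regression
#' presets). Each stage appends a line-delimited JSON log record; outputs
#' (parameter table CSV, report JSON) are written to `config$out_dir`.
#' Rerunning with the same config and seed reproduces all numbers.
#'
#' Conditional-MI analyses whose conditioning set would exceed dimension 2
#' (as with four separate non-decision times) are recorded as
#' `skipped_unsupported` rather than estimated.
#'
#' @param config A [run_config()].
#' @return A `run_report` list (also serialized to
#'   `file.path(config$out_dir, "report.json")`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stop("`config` must be a run_config",
                                            call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run_log.jsonl")
  if (file.exists(log_path)) unlink(log_path)

  # --- stage: data ---------------------------------------------------------
  if (!is.null(config$trials_csv)) {
    trials <- utils::read.csv(config$trials_csv, stringsAsFactors = FALSE)
    need <- c("participant", "session", "task", "condition", "response",
              "rt")
    miss <- setdiff(need, names(trials))
    if (length(miss) > 0)
      stop("stage data: missing column(s) ", paste(miss, collapse = ", "),
           call. = FALSE)
    if (config$rt_unit == "ms") trials$rt <- trials$rt / 1000
    truth <- NULL
  } else {
    study <- generate_study(config$population, config$cfg)
    trials <- study$trials
    truth <- study$truth
  }
  log_stage(log_path, "data", n_trials = nrow(trials), seed = config$seed)

  # --- stage: filter -------------------------------------------------------
  rule <- filter_rule(config$filter_rule_name)
  if ("censored" %in% names(trials)) {
    trials <- trials[!trials$censored & is.finite(trials$rt), ,
                     drop = FALSE]
  }
  flt <- apply_rt_filter(trials, rule)
  trials <- flt$trials
  log_stage(log_path, "filter", rule = rule$name, kept = flt$log$n_kept,
            removed_bounds = flt$log$n_removed_bounds,
            removed_sd = flt$log$n_removed_sd)

  # --- stage: fit ----------------------------------------------------------
  cells <- dplyr::distinct(trials[, c("participant", "session", "task")])
  fits <- vector("list", nrow(cells))
  skipped <- list()
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    variant <- config$population$task_designs[[cell$task]]$variant
    if (is.null(variant)) variant <- "M2"
    mp <- default_model_spec(variant)
    sub <- trials[trials$participant == cell$participant &
                    trials$session == cell$session &
                    trials$task == cell$task, , drop = FALSE]
    fit <- tryCatch(
      fit_participant(sub, mp$spec, mp$prior, config$backend,
                      seed = (config$seed + 977L * i) %% 2147480000L),
      error = function(e) e)
    if (inherits(fit, "error")) {
      skipped[[length(skipped) + 1L]] <-
        list(participant = cell$participant, session = cell$session,
             task = cell$task, reason = conditionMessage(fit))
      fits[[i]] <- NULL
    } else {
      fits[[i]] <- tibble::as_tibble(c(
        list(participant = cell$participant, session = cell$session,
             task = cell$task, variant = variant,
             backend = config$backend$id),
        as.list(fit$estimates)))
    }
  }
  param_table <- dplyr::bind_rows(fits)
  utils::write.csv(param_table, file.path(config$out_dir,
                                          "param_table.csv"),
                   row.names = FALSE)
  log_stage(log_path, "fit", n_fits = nrow(param_table),
            n_skipped = length(skipped))

  # --- stage: measures -----------------------------------------------------
  measures <- participant_measures(trials)
  log_stage(log_path, "measures", n_rows = nrow(measures))

  # --- stage: analyze ------------------------------------------------------
  report <- list(config_seed = config$seed,
                 n_participants = length(unique(trials$participant)),
                 skipped_fits = skipped)
  params_fit <- setdiff(names(param_table),
                        c("participant", "session", "task", "variant",
                          "backend"))
  wide <- function(p, task) {
    s1 <- param_table[param_table$session == 1 & param_table$task == task, ]
    s2 <- param_table[param_table$session == 2 & param_table$task == task, ]
    common <- intersect(s1$participant, s2$participant)
    if (length(common) < 3) return(NULL)
    paired_series(common, s1[[p]][match(common, s1$participant)],
                  s2[[p]][match(common, s2$participant)])
  }
  tasks <- unique(param_table$task)
  if ("retest" %in% config$analyses) {
    report$retest <- list()
    for (task in tasks) {
      for (p in params_fit) {
        ps <- wide(p, task)
        if (is.null(ps) || stats::sd(ps$x) == 0) next
        scr <- mahalanobis_filter(ps, 0.001)
        rr <- retest_correlation(scr$kept)
        entry <- list(r = rr$r, p = rr$p, stars = rr$stars, n = rr$n,
                      n_excluded = length(scr$excluded_ids))
        if ("mi" %in% config$analyses && nrow(scr$kept) >= 50) {
          mi <- knn_mi(scr$kept$x, scr$kept$y)
          entry$mi_mean_nats <- mi$mi_mean
          entry$mi_gaussian_nats <- if (abs(rr$r) < 1)
            gaussian_mi(rr$r) else NA_real_
        }
        report$retest[[paste(task, p, sep = ".")]] <- entry
      }
    }
  }
  if ("cmi" %in% config$analyses) {
    report$cmi <- list()
    for (task in tasks) {
      pa <- wide("alpha", task)
      if (is.null(pa)) next
      cond_names <- list(threshold = "a", ndt = grep(
        "^ndt", params_fit, value = TRUE))
      for (cn in names(cond_names)) {
        ps <- cond_names[[cn]]
        if (length(ps) * 2 > 2) {
          report$cmi[[paste(task, cn, sep = ".")]] <-
            list(status = "skipped_unsupported",
                 reason = "conditioning dimension > 2")
          next
        }
        zs <- lapply(ps, function(p) { w <- wide(p, task); cbind(w$x, w$y) })
        z <- do.call(cbind, zs)
        # a 2-column conditioning set (both sessions of one parameter)
        ret <- cmi_retention(pa$x, pa$y, stats::setNames(list(z), cn))
        report$cmi[[paste(task, cn, sep = ".")]] <-
          list(status = "ok",
               retention_mean = ret$sets[[cn]]$retention_mean,
               mi_mean = ret$mi_mean, unreliable = ret$unreliable)
      }
    }
  }
  if ("gbr" %in% config$analyses) {
    report$gbr <- list()
    for (task in tasks) {
      pa <- wide("alpha", task)
      if (is.null(pa) || nrow(pa) < 25) next
      feats <- list(alpha_s1 = pa$x)
      for (p in intersect(c("a", grep("^ndt", params_fit, value = TRUE)),
                          params_fit)) {
        w <- wide(p, task)
        feats[[paste0(p, "_s1")]] <- w$x
        feats[[paste0(p, "_s2")]] <- w$y
      }
      g <- gbr_reliability(as.data.frame(feats), pa$y,
                           seed = config$seed)
      report$gbr[[task]] <- list(cv_r2_mean = g$cv_r2_mean,
                                 cv_r2_sd = g$cv_r2_sd,
                                 mae_mean = g$mae_mean,
                                 rmse_mean = g$rmse_mean,
                                 importances = g$importances)
    }
  }
  if ("practice" %in% config$analyses) {
    report$practice <- list()
    for (task in tasks) {
      pa <- wide("alpha", task)
      if (is.null(pa)) next
      tr <- stabilizing_transform(c(pa$x, pa$y), subtract_one = TRUE)
      n <- nrow(pa)
      pe <- practice_effect(tr$values[seq_len(n)],
                            tr$values[n + seq_len(n)])
      report$practice[[task]] <- unclass(pe)
    }
  }
  if ("regressions" %in% config$analyses) {
    report$regressions <- list()
    for (task in tasks) {
      mt <- measures[measures$task == task, ]
      pt <- param_table[param_table$task == task, ]
      joined <- dplyr::inner_join(mt, pt,
                                  by = c("participant", "session", "task"))
      ok_alpha <- is.finite(joined$alpha) &
        joined$alpha > 1 & joined$alpha < 2
      joined <- joined[ok_alpha, ]
      if (nrow(joined) < 20) next
      joined$alpha_T <- stabilizing_transform(joined$alpha,
                                              subtract_one = TRUE)$values
      acc <- pmin(pmax(joined$accuracy, 0), 1)
      joined$accuracy_T <- if (stats::sd(acc) > 0)
        stabilizing_transform(acc)$values else acc
      for (preset in c("aspects", "crt_quartiles", "ert_quartiles",
                       "rt_diff", "shape")) {
        rep_i <- tryCatch(ols_suite(joined, preset), error = function(e) e)
        if (!inherits(rep_i, "error"))
          report$regressions[[paste(task, preset, sep = ".")]] <-
            list(r_squared = rep_i$r_squared, terms = rep_i$terms)
      }
    }
  }
  if (!is.null(truth)) report$clip_fraction <- attr(truth, "clip_fraction")
  report$provenance <- list(seed = config$seed,
                            backend = config$backend$id,
                            filter_rule = config$filter_rule_name)
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  log_stage(log_path, "analyze", analyses = config$analyses)
  structure(c(report, list(param_table = param_table, measures = measures)),
            class = "run_report")
}
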