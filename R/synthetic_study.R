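# Synthetic two-session study generator with known ground truth.

param_ranges <- function() {
  list(a = c(0.5, 3), v = c(-6, 6), zr = c(0.3, 0.7), ndt = c(0.1, 0.8),
       sndt = c(0, 0.4), alpha = c(1.01, 1.99))
}

range_for <- function(p) {
  r <- param_ranges()
  if (grepl("^v", p)) r$v
  else if (grepl("^ndt", p)) r$ndt
  else r[[p]]
}

#' Default trait model for a synthetic population
#'
#' One row per free parameter: session-1 trait mean and SD, cross-session
#' correlation `rho`, and the session-2 practice shift (added to the
#' session-2 mean). Default shifts follow the practice-effect sign
#' conventions: drift magnitudes up, boundary separation, non-decision time
#' and the stability index down (a lower stability index -- more jumps --
#' accompanies better performance).
#'
#' @return Tibble with columns param, mean, sd, rho, shift.
#' @export
default_traits <- function() {
  tibble::tribble(
    ~param, ~mean, ~sd, ~rho, ~shift,
    "a",     1.6,  0.30, 0.70, -0.10,
    "v1",    2.5,  0.80, 0.75,  0.30,
    "v2",   -2.5,  0.80, 0.75, -0.30,
    "v",     2.5,  0.80, 0.75,  0.30,
    "zr",    0.5,  0.05, 0.50,  0.00,
    "ndt",   0.40, 0.08, 0.65, -0.03,
    "sndt",  0.10, 0.05, 0.50,  0.00,
    "alpha", 1.55, 0.20, 0.60, -0.08
  )
}

#' Specification of a synthetic two-session study
#'
#' @param n_participants Number of participants.
#' @param task_designs Named list: per task, a list with `variant` (see
#'   [default_model_spec()]) and `design` (named trial counts per condition
#'   per session, all >= 40).
#' @param traits Trait tibble as in [default_traits()]; rows for parameters
#'   not free in a task's variant are ignored for that task.
#' @param seed Integer seed.
#' @return A `population_spec`.
#' @export
population_spec <- function(n_participants = 100,
                            task_designs = list(
                              LDTlike = list(variant = "M2",
                                             design = c(c1 = 500, c2 = 500))),
                            traits = default_traits(), seed = 1L) {
  if (n_participants < 1) stop("need n_participants >= 1", call. = FALSE)
  for (td in task_designs) {
    if (any(td$design < 40))
      stop("trials per session must be >= 40 per condition set",
           call. = FALSE)
  }
  for (i in seq_len(nrow(traits))) {
    rng <- range_for(traits$param[i])
    if (traits$mean[i] < rng[1] - 3 * traits$sd[i] ||
        traits$mean[i] > rng[2] + 3 * traits$sd[i])
      stop("infeasible trait specification for ", traits$param[i],
           call. = FALSE)
  }
  structure(list(n_participants = n_participants,
                 task_designs = task_designs, traits = traits,
                 seed = as.integer(seed)),
            class = "population_spec")
}

#' Draw true parameters for a synthetic population
#'
#' Per free parameter of each task's variant, (session-1, session-2) values
#' are drawn from a bivariate Gaussian with the trait row's mean/SD/rho,
#' the practice shift added to the session-2 mean, then clipped to the
#' parameter's valid range (the stability index to \[1.01, 1.99\]). The
#' clipped fraction is reported as an attribute.
#'
#' @param spec A [population_spec()].
#' @return Tibble of ground truth: participant, task, session, one column
#'   per parameter; attribute `clip_fraction`.
#' @export
generate_population <- function(spec) {
  with_preserved_seed(spec$seed, {
    n <- spec$n_participants
    out <- list(); clipped <- 0L; total <- 0L
    for (task in names(spec$task_designs)) {
      variant <- spec$task_designs[[task]]$variant
      ms <- default_model_spec(variant)$spec
      vals1 <- list(); vals2 <- list()
      for (p in ms$free) {
        tr <- spec$traits[spec$traits$param == p, ]
        if (nrow(tr) == 0)
          stop("no trait row for free parameter ", p, call. = FALSE)
        z1 <- stats::rnorm(n)
        z2 <- tr$rho * z1 + sqrt(1 - tr$rho^2) * stats::rnorm(n)
        s1 <- tr$mean + tr$sd * z1
        s2 <- tr$mean + tr$shift + tr$sd * z2
        rng <- range_for(p)
        clipped <- clipped + sum(s1 < rng[1] | s1 > rng[2]) +
          sum(s2 < rng[1] | s2 > rng[2])
        total <- total + 2L * n
        vals1[[p]] <- pmin(pmax(s1, rng[1]), rng[2])
        vals2[[p]] <- pmin(pmax(s2, rng[1]), rng[2])
      }
      for (s in 1:2) {
        vals <- if (s == 1) vals1 else vals2
        df <- tibble::as_tibble(vals)
        df$participant <- seq_len(n); df$task <- task; df$session <- s
        out[[length(out) + 1L]] <- df
      }
    }
    res <- dplyr::bind_rows(out)
    res <- dplyr::relocate(res, "participant", "task", "session")
    attr(res, "clip_fraction") <- clipped / total
    res
  })
}

#' Generate a full synthetic study
#'
#' Composes [generate_population()] with the forward model: for every
#' participant, session and task, trials are simulated from that cell's
#' true parameters. Ground truth is returned alongside for recovery
#' scoring.
#'
#' @param spec A [population_spec()].
#' @param cfg A [sim_config()] for the trial simulations.
#' @return List with `trials` (tidy trial table: participant, session,
#'   task, condition, response, rt, censored) and `truth` (from
#'   [generate_population()]).
#' @export
generate_study <- function(spec, cfg = sim_config()) {
  truth <- generate_population(spec)
  rows <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    row <- truth[i, ]
    task <- row$task
    variant <- spec$task_designs[[task]]$variant
    design <- spec$task_designs[[task]]$design
    ms <- default_model_spec(variant)$spec
    theta <- unlist(row[ms$free])
    cfg_i <- cfg
    cfg_i$seed <- (spec$seed + 1009L * i) %% 2147480000L
    tab <- simulate_from_theta(theta, ms, design, cfg_i)
    tab$participant <- row$participant
    tab$session <- row$session
    tab$task <- task
    rows[[i]] <- tab
  }
  trials <- dplyr::bind_rows(rows)
  trials <- dplyr::relocate(trials, "participant", "session", "task",
                            "condition", "response", "rt")
  list(trials = trials, truth = truth)
}
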