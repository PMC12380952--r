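#' Model variants of the Levy-flight decision model
#'
#' Returns the free/fixed parameter map of a named model variant together
#' with its default priors. Variants:
#' \describe{
#'   \item{M1}{two stimulus conditions, free \{a, zr, v1, v2, ndt, sndt,
#'     alpha\}.}
#'   \item{M2}{M1 with the starting point fixed at `zr = 0.5` and
#'     `sndt = 0`.}
#'   \item{APT_M1, APT_M2}{four prime-by-target cells, each with its own
#'     drift and non-decision time.}
#'   \item{ECT}{single condition; free \{a, v, ndt, alpha\} with `zr = 0.5`,
#'     `sndt = 0`.}
#' }
#'
#' @param variant One of "M1", "M2", "APT_M1", "APT_M2", "ECT".
#' @return List with elements `spec` (a `model_spec`) and `prior` (a
#'   `prior_spec`, see [prior_spec()]).
#' @export
default_model_spec <- function(variant) {
  variant <- match.arg(variant, c("M1", "M2", "APT_M1", "APT_M2", "ECT"))
  two_cond <- list(c1 = list(drift = "v1", ndt = "ndt"),
                   c2 = list(drift = "v2", ndt = "ndt"))
  four_cond <- stats::setNames(lapply(1:4, function(i)
    list(drift = paste0("v", i), ndt = paste0("ndt", i))),
    paste0("c", 1:4))
  spec <- switch(variant,
    M1 = list(variant = "M1",
              free = c("a", "zr", "v1", "v2", "ndt", "sndt", "alpha"),
              fixed = c(), conditions = two_cond),
    M2 = list(variant = "M2",
              free = c("a", "v1", "v2", "ndt", "alpha"),
              fixed = c(zr = 0.5, sndt = 0), conditions = two_cond),
    APT_M1 = list(variant = "APT_M1",
                  free = c("a", "zr", paste0("v", 1:4), paste0("ndt", 1:4),
                           "sndt", "alpha"),
                  fixed = c(), conditions = four_cond),
    APT_M2 = list(variant = "APT_M2",
                  free = c("a", paste0("v", 1:4), paste0("ndt", 1:4),
                           "alpha"),
                  fixed = c(zr = 0.5, sndt = 0), conditions = four_cond),
    ECT = list(variant = "ECT", free = c("a", "v", "ndt", "alpha"),
               fixed = c(zr = 0.5, sndt = 0),
               conditions = list(c1 = list(drift = "v", ndt = "ndt")))
  )
  class(spec) <- "model_spec"
  list(spec = spec, prior = prior_spec(spec))
}

#' Default uniform priors for a model variant
#'
#' Independent uniform priors per free parameter: boundary separation
#' `U(0.5, 3)`, drifts `U(-6, 6)`, starting point `U(0.3, 0.7)`,
#' non-decision time `U(0.1, 0.8)`, its range `U(0, 0.4)` (truncated so
#' `ndt - sndt/2 > 0.05`), and the stability index `U(1, 2)`. All bounds
#' can be overridden.
#'
#' @param spec A `model_spec`.
#' @param overrides Optional named list `param = c(lower, upper)`.
#' @return A `prior_spec`: data frame with columns param, lower, upper.
#' @export
prior_spec <- function(spec, overrides = list()) {
  default_bounds <- function(p) {
    if (p == "a") c(0.5, 3)
    else if (grepl("^v", p)) c(-6, 6)
    else if (p == "zr") c(0.3, 0.7)
    else if (grepl("^ndt", p)) c(0.1, 0.8)
    else if (p == "sndt") c(0, 0.4)
    else if (p == "alpha") c(1, 2)
    else stop("no default prior for parameter ", p, call. = FALSE)
  }
  rows <- lapply(spec$free, function(p) {
    b <- if (p %in% names(overrides)) overrides[[p]] else default_bounds(p)
    data.frame(param = p, lower = b[1], upper = b[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if ("alpha" %in% out$param) {
    ab <- out[out$param == "alpha", ]
    if (ab$lower < 1 || ab$upper > 2)
      stop("alpha prior support must lie within [1, 2]", call. = FALSE)
  }
  class(out) <- c("prior_spec", class(out))
  out
}

#' Draw parameter vectors from a prior
#'
#' Respects the joint constraint `ndt - sndt/2 > 0.05` by re-drawing `sndt`
#' where violated.
#'
#' @param prior A [prior_spec()].
#' @param n Number of draws.
#' @return Matrix `n x n_params` with parameter names as columns.
#' @export
sample_prior <- function(prior, n) {
  draws <- vapply(seq_len(nrow(prior)), function(i)
    stats::runif(n, prior$lower[i], prior$upper[i]),
    numeric(n))
  draws <- matrix(draws, nrow = n)
  colnames(draws) <- prior$param
  if (all(c("ndt", "sndt") %in% prior$param)) {
    cap <- pmax(2 * (draws[, "ndt"] - 0.05), 0)
    bad <- draws[, "sndt"] > cap
    draws[bad, "sndt"] <- stats::runif(sum(bad), 0, cap[bad])
  }
  draws
}

# Expand a named free-parameter vector into full lfm_params for the spec.
theta_to_params <- function(theta, spec) {
  full <- c(theta, spec$fixed)
  drifts <- vapply(spec$conditions, function(cc) unname(full[cc$drift]),
                   numeric(1))
  lfm_params(drifts = stats::setNames(drifts, names(spec$conditions)),
             a = unname(full["a"]), zr = unname(full["zr"]),
             ndt = unname(full[spec$conditions[[1]]$ndt]),
             sndt = unname(full["sndt"]), alpha = unname(full["alpha"]))
}

# Per-condition drift / non-decision vectors for the C++ objective.
theta_to_cond_vectors <- function(theta, spec) {
  full <- c(theta, spec$fixed)
  list(v = vapply(spec$conditions, function(cc) unname(full[cc$drift]),
                  numeric(1)),
       ndt = vapply(spec$conditions, function(cc) unname(full[cc$ndt]),
                    numeric(1)),
       a = unname(full["a"]), zr = unname(full["zr"]),
       sndt = unname(full["sndt"]), alpha = unname(full["alpha"]))
}
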