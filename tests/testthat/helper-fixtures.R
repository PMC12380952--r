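# Shared small fixtures and helpers for the test suite.

# Kolmogorov-Smirnov distance of a sample against a CDF function,
# computed directly (avoids tie warnings from stats::ks.test).
ks_distance <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  Fx <- cdf(x)
  max(abs(Fx - (seq_len(n) - 1) / n), abs(Fx - seq_len(n) / n))
}

# Two-sample KS distance.
ks_distance2 <- function(x, y) {
  as.numeric(suppressWarnings(stats::ks.test(x, y)$statistic))
}

# A small simulated M2 participant used across fitting tests.
make_m2_participant <- function(n_per_cond = 100, seed = 3,
                                theta = c(a = 1.6, v1 = 2.5, v2 = -2.5,
                                          ndt = 0.4, alpha = 1.5)) {
  mp <- default_model_spec("M2")
  sim <- levyflight:::simulate_from_theta(
    theta, mp$spec, c(c1 = n_per_cond, c2 = n_per_cond),
    sim_config(dt = 0.005, max_time = 5, seed = seed))
  list(trials = sim, spec = mp$spec, prior = mp$prior, theta = theta)
}

# Cheap reference backend for mechanics-level tests (not accuracy).
tiny_backend <- function() {
  backend_reference(n_sim = 400, pop = 10, generations = 8, nm_iter = 40)
}

# Mock draw-capable backends for SBC machinery tests: a prior-sampling
# backend is calibrated by construction (posterior = prior when the data
# are ignored); a shifted-prior backend is deliberately mis-calibrated.
mock_prior_backend <- function(shift = 0) {
  be <- list(id = if (shift == 0) "mock_prior" else "mock_shifted")
  be$sample_posterior <- function(trials, spec, prior, n_draws, seed) {
    draws <- levyflight:::with_preserved_seed(seed,
                                              sample_prior(prior, n_draws))
    if (shift != 0) {
      rng <- prior$upper - prior$lower
      draws <- sweep(draws, 2, shift * rng, "+")
      draws <- pmin(pmax(draws, rep(prior$lower, each = n_draws)),
                    rep(prior$upper, each = n_draws))
    }
    draws
  }
  class(be) <- "lfm_backend"
  be
}

table3_reference <- function() {
  utils::read.csv(system.file("extdata", "practice_effect_reference.csv",
                              package = "levyflight"))
}
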