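# Shared fixture builders and independent oracles.

# History from consecutive gaps (first injection at day 0).
make_history <- function(gaps, end = 731L, id = "p1") {
  injection_history(id, cumsum(c(0L, as.integer(gaps))), end)
}

# Brute-force day-grid MCR oracle: enumerate every day in [0, denom) and
# count days covered by any injection's [d, d + 183) interval.
mcr_daygrid <- function(history, policy = window_policy(),
                        horizon_days = 731L) {
  denom <- min(horizon_days, history$observation_end_day)
  days <- seq.int(0L, denom - 1L)
  covered <- rep(FALSE, denom)
  for (d in history$injection_days) {
    idx <- days >= d & days < d + policy$nominal_interval_days
    covered[idx] <- TRUE
  }
  100 * sum(covered) / denom
}

# Random histories with arbitrary (not necessarily plausible) gap patterns.
random_history <- function(id, max_span = 1000L) {
  n_inj <- sample(1:6, 1)
  gaps <- sample(1:300, n_inj - 1, replace = TRUE)
  days <- cumsum(c(0L, gaps))
  days <- days[days < max_span]
  injection_history(id, days, max(days) + sample(0:200, 1))
}

# Expand a 2x2 table (exposure x outcome) into patient-level vectors.
expand_2x2 <- function(n_out1_exp1, n_out0_exp1, n_out1_exp0, n_out0_exp0) {
  outcome <- c(rep(TRUE, n_out1_exp1), rep(FALSE, n_out0_exp1),
               rep(TRUE, n_out1_exp0), rep(FALSE, n_out0_exp0))
  exposed <- c(rep(TRUE, n_out1_exp1 + n_out0_exp1),
               rep(FALSE, n_out1_exp0 + n_out0_exp0))
  list(outcome = outcome,
       data = data.frame(exposure = exposed))
}

# Small two-covariate simulation config used across model tests.
two_cov_config <- function(n = 2000L, seed = 1L,
                           fall_lor = log(0.4), null_prev = 0.5) {
  simulation_config(
    n_patients = n,
    covariate_specs = list(
      list(name = "fall_12m", type = "binary", prevalence = 0.3),
      list(name = "null_cov", type = "binary", prevalence = null_prev)),
    true_log_odds = c(fall_12m = fall_lor),
    baseline_continuation_logit = stats::qlogis(0.93),
    seed = seed)
}

# Induced 24-month persistence log odds-ratio for a binary covariate under
# the discrete-hazard generator: persistence requires all k continuation
# draws, each with logistic probability (default jitter never breaks the
# persistence window).
induced_log_or <- function(b0, lor, k = 3L) {
  p1 <- plogis(b0 + lor)^k
  p0 <- plogis(b0)^k
  (log(p1) - log(1 - p1)) - (log(p0) - log(1 - p0))
}
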