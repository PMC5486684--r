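#' Classify 24-month persistence from injection gaps
#'
#' A patient is persistent when all `required_injections` scheduled
#' injections were received and every consecutive gap among them is at most
#' the nominal interval plus the persistence allowance, boundary inclusive
#' ("within 6 months + 8 weeks" reads as gap <= 183 + 56 days). With the
#' default of four injections at ~6-month spacing this is the 24-month
#' persistence classification; `required_injections = 2` over a 12-month
#' horizon gives the 12-month analogue.
#'
#' All gaps among the first `required_injections` injections must satisfy the
#' window, not only the last one: a patient late for the second injection was
#' already non-persistent at 12 months. Injections beyond the required count
#' are ignored here (they still contribute to [compute_mcr()]).
#'
#' @param history An [injection_history()].
#' @param policy A [window_policy()].
#' @param required_injections Number of injections that must be received
#'   within window (default 4, i.e. 24 months of 6-monthly dosing).
#' @return `TRUE`/`FALSE`.
#' @seealso [classify_adherence()], [sensitivity_grid()]
#' @export
classify_persistence <- function(history, policy = window_policy(),
                                 required_injections = 4L) {
  stopifnot(inherits(history, "injection_history"),
            inherits(policy, "window_policy"))
  required_injections <- as.integer(required_injections)
  if (is.na(required_injections) || required_injections < 2L)
    stop("required_injections must be >= 2", call. = FALSE)
  if (length(history$injection_days) < required_injections) return(FALSE)
  gaps <- diff(history$injection_days[seq_len(required_injections)])
  limit <- policy$nominal_interval_days + policy$persistence_allowance_days
  all(gaps <= limit)
}

#' Classify 24-month adherence from injection gaps
#'
#' Adherence is the stricter, two-sided criterion: every consecutive gap
#' among the first `required_injections` injections must lie inside
#' `[nominal - tolerance, nominal + tolerance]`, boundary inclusive
#' (defaults: 183 +/- 28 days, i.e. 6 months +/- 4 weeks). Whenever the
#' adherence tolerance does not exceed the persistence allowance, an
#' adherent patient is necessarily persistent.
#'
#' @inheritParams classify_persistence
#' @return `TRUE`/`FALSE`.
#' @export
classify_adherence <- function(history, policy = window_policy(),
                               required_injections = 4L) {
  stopifnot(inherits(history, "injection_history"),
            inherits(policy, "window_policy"))
  required_injections <- as.integer(required_injections)
  if (is.na(required_injections) || required_injections < 2L)
    stop("required_injections must be >= 2", call. = FALSE)
  if (length(history$injection_days) < required_injections) return(FALSE)
  gaps <- diff(history$injection_days[seq_len(required_injections)])
  lo <- policy$nominal_interval_days - policy$adherence_tolerance_days
  hi <- policy$nominal_interval_days + policy$adherence_tolerance_days
  all(gaps >= lo & gaps <= hi)
}

#' Medication coverage ratio (MCR)
#'
#' Percentage of observation time during which the patient is
#' pharmacologically covered, assuming each injection provides
#' `nominal_interval_days` (183) days of coverage. Coverage is the length of
#' the union of the half-open intervals `[d, d + 183)` over all injection
#' days `d`, intersected with `[0, denominator)`; the denominator is
#' `min(horizon_days, observation_end_day)`. The union guarantees that early
#' re-injection never double-counts days, so the MCR is always in [0, 100].
#' This is the long-acting-injectable analogue of the medication possession
#' ratio.
#'
#' @inheritParams classify_persistence
#' @param horizon_days Analysis horizon in days (default 731 = 24 months).
#' @return MCR as a percentage in `[0, 100]` (full precision; round at the
#'   reporting boundary).
#' @examples
#' h <- injection_history("p1", c(0, 183, 366, 549), 731)
#' compute_mcr(h)                     # 100
#' compute_mcr(injection_history("p2", 0, 731))  # 100 * 183/731
#' @export
compute_mcr <- function(history, policy = window_policy(),
                        horizon_days = 731L) {
  stopifnot(inherits(history, "injection_history"),
            inherits(policy, "window_policy"))
  horizon_days <- as.integer(horizon_days)
  if (is.na(horizon_days) || horizon_days <= 0L)
    stop("horizon_days must be positive", call. = FALSE)
  if (history$observation_end_day <= 0L)
    stop("observation_end_day must be positive to compute an MCR",
         call. = FALSE)
  denom <- min(horizon_days, history$observation_end_day)
  dur <- policy$nominal_interval_days
  starts <- history$injection_days
  covered <- 0L
  cursor <- 0L  # end of the union accumulated so far
  for (d in starts) {
    s <- max(d, cursor)
    e <- min(d + dur, denom)
    if (e > s) covered <- covered + (e - s)
    cursor <- max(cursor, min(d + dur, denom))
    if (cursor >= denom) break
  }
  100 * covered / denom
}

#' Summarize a binomial proportion with a 95% confidence interval
#'
#' Produces the `n/N (%)` summaries used throughout the reporting tables:
#' the percentage is rounded to one decimal at this reporting boundary, and
#' the 95% CI is the Wilson score interval by default (well-behaved near 0
#' and 1); a Wald interval is available for comparability.
#'
#' @param n_success Number of successes (e.g. persistent patients).
#' @param n_total Denominator (the complete-case "N1"-style count); must be
#'   positive.
#' @param conf_level Confidence level (default 0.95).
#' @param method `"wilson"` (default) or `"wald"`.
#' @return A one-row data frame of class `proportion_summary` with columns
#'   `n_success`, `n_total`, `proportion_percent`, `ci95_low`, `ci95_high`
#'   (percentages, one decimal, CI clipped to \[0, 100\]).
#' @examples
#' summarize_proportion(70, 101)   # 69.3%
#' @export
summarize_proportion <- function(n_success, n_total, conf_level = 0.95,
                                 method = c("wilson", "wald")) {
  method <- match.arg(method)
  n_success <- as.integer(n_success)
  n_total <- as.integer(n_total)
  if (anyNA(c(n_success, n_total)) || n_total <= 0L)
    stop("n_total must be a positive count", call. = FALSE)
  if (n_success < 0L || n_success > n_total)
    stop("n_success must satisfy 0 <= n_success <= n_total", call. = FALSE)
  p <- n_success / n_total
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (method == "wilson") {
    z2 <- z^2
    centre <- (p + z2 / (2 * n_total)) / (1 + z2 / n_total)
    half <- z * sqrt(p * (1 - p) / n_total + z2 / (4 * n_total^2)) /
      (1 + z2 / n_total)
    lo <- centre - half
    hi <- centre + half
  } else {
    half <- z * sqrt(p * (1 - p) / n_total)
    lo <- p - half
    hi <- p + half
  }
  out <- data.frame(
    n_success = n_success,
    n_total = n_total,
    proportion_percent = round(100 * p, 1),
    ci95_low = round(100 * max(0, lo), 1),
    ci95_high = round(100 * min(1, hi), 1)
  )
  class(out) <- c("proportion_summary", class(out))
  out
}

#' Per-patient outcome table
#'
#' Applies the persistence/adherence classifications and the MCR to every
#' history in a cohort, yielding the per-patient table behind all stratified
#' summaries.
#'
#' @param histories A list of [injection_history()] objects (or a
#'   `synthetic_cohort`, whose `histories` element is used).
#' @inheritParams compute_mcr
#' @param required_injections Injections required for the persistence /
#'   adherence flags (default 4).
#' @return A data frame with columns `patient_id`, `persistent_24m`,
#'   `adherent_24m`, `mcr_percent`, `n_injections`.
#' @export
patient_outcomes <- function(histories, policy = window_policy(),
                             horizon_days = 731L, required_injections = 4L) {
  if (inherits(histories, "synthetic_cohort")) histories <- histories$histories
  stopifnot(length(histories) > 0L)
  rows <- lapply(histories, function(h) {
    data.frame(
      patient_id = h$patient_id,
      persistent_24m = classify_persistence(h, policy, required_injections),
      adherent_24m = classify_adherence(h, policy, required_injections),
      mcr_percent = compute_mcr(h, policy, horizon_days),
      n_injections = length(h$injection_days)
    )
  })
  do.call(rbind, rows)
}

#' Sensitivity grid over alternative gap windows
#'
#' Recomputes the persistence and adherence proportions under the study's
#' alternative windows: 6 months + {4, 6, 8, 12} weeks for persistence and
#' 6 months +/- {4, 6, 8, 12} weeks for adherence. Because a wider window can
#' only reclassify patients toward the outcome, each proportion is
#' non-decreasing in its window size.
#'
#' @inheritParams patient_outcomes
#' @param base_policy Policy supplying the nominal interval; the allowance /
#'   tolerance columns of the grid override its window fields.
#' @param weeks Window sizes in weeks (default `c(4, 6, 8, 12)`).
#' @return A data frame with one row per (metric, window): columns `metric`
#'   (`"persistence"` or `"adherence"`), `window_weeks`, `window_days`,
#'   `n_success`, `n_total`, `proportion_percent`, `ci95_low`, `ci95_high`.
#' @export
sensitivity_grid <- function(histories, base_policy = window_policy(),
                             weeks = c(4L, 6L, 8L, 12L),
                             horizon_days = 731L, required_injections = 4L) {
  if (inherits(histories, "synthetic_cohort")) histories <- histories$histories
  if (length(histories) == 0L) stop("empty cohort", call. = FALSE)
  n <- length(histories)
  rows <- list()
  for (w in weeks) {
    pol_p <- window_policy(base_policy$nominal_interval_days,
                           persistence_allowance_days = 7L * w,
                           adherence_tolerance_days =
                             base_policy$adherence_tolerance_days)
    n_pers <- sum(vapply(histories, classify_persistence, logical(1),
                         policy = pol_p,
                         required_injections = required_injections))
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(metric = "persistence", window_weeks = w,
                 window_days = 7L * w),
      summarize_proportion(n_pers, n))
  }
  for (w in weeks) {
    pol_a <- window_policy(base_policy$nominal_interval_days,
                           persistence_allowance_days =
                             base_policy$persistence_allowance_days,
                           adherence_tolerance_days = 7L * w)
    n_adh <- sum(vapply(histories, classify_adherence, logical(1),
                        policy = pol_a,
                        required_injections = required_injections))
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(metric = "adherence", window_weeks = w,
                 window_days = 7L * w),
      summarize_proportion(n_adh, n))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Categorize an MMAS-8 score
#'
#' The 8-item Morisky Medication Adherence Scale score (0-8) is categorized
#' as high adherence for a score of 8, medium for 6-7, and low for less
#' than 6.
#'
#' @param score Numeric vector of scores in `[0, 8]`; `NA` passes through.
#' @return Factor with levels `low`, `medium`, `high`.
#' @export
categorize_mmas <- function(score) {
  if (any(score < 0 | score > 8, na.rm = TRUE))
    stop("MMAS-8 scores must lie in [0, 8]", call. = FALSE)
  out <- ifelse(is.na(score), NA_character_,
                ifelse(score >= 8, "high",
                       ifelse(score >= 6, "medium", "low")))
  factor(out, levels = c("low", "medium", "high"))
}
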