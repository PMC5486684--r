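#' Gap-window policy for injection classification
#'
#' A `window_policy` parameterizes every persistence/adherence classification
#' and the MCR. The nominal inter-dose interval is 6 months, operationalized
#' as 183 days; weeks convert to days as 7 days each. Persistence allows a
#' one-sided grace period after the nominal interval (default 8 weeks);
#' adherence requires the gap to fall inside a symmetric tolerance band
#' around the nominal interval (default +/- 4 weeks).
#'
#' @param nominal_interval_days Nominal dosing interval in days (default 183,
#'   the 6-month operationalization used throughout).
#' @param persistence_allowance_days One-sided grace period in days appended
#'   to the nominal interval for persistence (default 56 = 8 weeks).
#' @param adherence_tolerance_days Symmetric tolerance in days around the
#'   nominal interval for adherence (default 28 = 4 weeks). Must be smaller
#'   than the nominal interval.
#' @return An object of class `window_policy`.
#' @examples
#' window_policy()                              # study defaults
#' window_policy(persistence_allowance_days = 7 * 12)  # +12-week sensitivity
#' @export
window_policy <- function(nominal_interval_days = 183L,
                          persistence_allowance_days = 56L,
                          adherence_tolerance_days = 28L) {
  nominal_interval_days <- as.integer(nominal_interval_days)
  persistence_allowance_days <- as.integer(persistence_allowance_days)
  adherence_tolerance_days <- as.integer(adherence_tolerance_days)
  if (any(is.na(c(nominal_interval_days, persistence_allowance_days,
                  adherence_tolerance_days))))
    stop("window_policy fields must be non-missing integers", call. = FALSE)
  if (nominal_interval_days <= 0L || persistence_allowance_days <= 0L ||
      adherence_tolerance_days <= 0L)
    stop("window_policy fields must all be positive", call. = FALSE)
  if (adherence_tolerance_days >= nominal_interval_days)
    stop("adherence_tolerance_days must be < nominal_interval_days",
         call. = FALSE)
  structure(
    list(nominal_interval_days = nominal_interval_days,
         persistence_allowance_days = persistence_allowance_days,
         adherence_tolerance_days = adherence_tolerance_days),
    class = "window_policy"
  )
}

#' @export
print.window_policy <- function(x, ...) {
  cat(sprintf(
    "<window_policy> nominal %d d, persistence +%d d, adherence +/-%d d\n",
    x$nominal_interval_days, x$persistence_allowance_days,
    x$adherence_tolerance_days))
  invisible(x)
}

#' One patient's injection record
#'
#' Dates are integer day offsets from the first injection, which is day 0 by
#' construction; calendar dates exist only at the file I/O boundary. The
#' observation end marks the end of follow-up or withdrawal and can never
#' precede the last recorded injection.
#'
#' @param patient_id Opaque patient identifier (coerced to character).
#' @param injection_days Strictly increasing integer day offsets; the first
#'   must be 0.
#' @param observation_end_day End of observation as a day offset;
#'   `>= max(injection_days)`.
#' @return An object of class `injection_history`.
#' @export
injection_history <- function(patient_id, injection_days, observation_end_day) {
  injection_days <- as.integer(injection_days)
  observation_end_day <- as.integer(observation_end_day)
  if (length(injection_days) < 1L || anyNA(injection_days))
    stop("injection_days must be a non-empty integer vector", call. = FALSE)
  if (injection_days[1L] != 0L)
    stop("first injection must be at day 0 (patient ", patient_id, ")",
         call. = FALSE)
  if (length(injection_days) > 1L && any(diff(injection_days) <= 0L))
    stop("injection_days must be strictly increasing (patient ",
         patient_id, ")", call. = FALSE)
  if (is.na(observation_end_day) ||
      observation_end_day < injection_days[length(injection_days)])
    stop("observation_end_day must be >= last injection day (patient ",
         patient_id, ")", call. = FALSE)
  structure(
    list(patient_id = as.character(patient_id),
         injection_days = injection_days,
         observation_end_day = observation_end_day),
    class = "injection_history"
  )
}

#' @export
print.injection_history <- function(x, ...) {
  cat(sprintf("<injection_history> %s: %d injection(s) at day %s; end %d\n",
              x$patient_id, length(x$injection_days),
              paste(x$injection_days, collapse = ", "),
              x$observation_end_day))
  invisible(x)
}
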