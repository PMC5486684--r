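# Cohort serialization. Internally all dates are integer day offsets from
# the patient's first injection; ISO-8601 calendar dates exist only in the
# files, anchored at a shared origin date recorded in the sidecar schema.

COHORT_ORIGIN <- as.Date("2012-01-01")

#' Write a cohort to delimited text files
#'
#' Produces three files under `dir`: `injections.csv` (one row per injection:
#' `patient_id`, 1-based `injection_seq`, ISO-8601 `injection_date`),
#' `covariates.csv` (one row per patient: `patient_id`, `stratum`, covariate
#' columns, `observation_end_date`), and `schema.json` (sidecar declaring
#' the origin date, stratum labels, and each covariate's type and category
#' levels).
#'
#' @param cohort A `synthetic_cohort` (from [generate_cohort()] or
#'   [read_cohort()]).
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of file paths.
#' @seealso [read_cohort()]
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  inj <- do.call(rbind, lapply(cohort$histories, function(h) {
    data.frame(patient_id = h$patient_id,
               injection_seq = seq_along(h$injection_days),
               injection_date = format(COHORT_ORIGIN + h$injection_days))
  }))
  cov <- cohort$covariates
  end_days <- vapply(cohort$histories, function(h) h$observation_end_day,
                     integer(1))
  cov$observation_end_day <- NULL
  cov$observation_end_date <- format(COHORT_ORIGIN + end_days)

  cov_schema <- lapply(setdiff(names(cov),
                               c("patient_id", "stratum",
                                 "observation_end_date")), function(nm) {
    col <- cov[[nm]]
    if (is.logical(col)) list(name = nm, type = "binary")
    else if (is.factor(col)) list(name = nm, type = "categorical",
                                  levels = as.list(levels(col)))
    else list(name = nm, type = "numeric")
  })
  schema <- list(origin_date = format(COHORT_ORIGIN),
                 strata = as.list(levels(cov$stratum)),
                 covariates = cov_schema)

  paths <- c(injections = file.path(dir, "injections.csv"),
             covariates = file.path(dir, "covariates.csv"),
             schema = file.path(dir, "schema.json"))
  utils::write.csv(inj, paths[["injections"]], row.names = FALSE)
  cov_out <- cov
  for (nm in names(cov_out))
    if (is.factor(cov_out[[nm]])) cov_out[[nm]] <- as.character(cov_out[[nm]])
  utils::write.csv(cov_out, paths[["covariates"]], row.names = FALSE)
  jsonlite::write_json(schema, paths[["schema"]], auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(paths)
}

#' Read a cohort from delimited text files
#'
#' Inverse of [write_cohort()]: validates the files (see errors below) and
#' reconstructs a `synthetic_cohort` with day offsets relative to each
#' patient's first injection. The `truth` element is `NULL` for cohorts read
#' from disk.
#'
#' Validation errors: missing columns, duplicate `(patient_id,
#' injection_seq)` rows, non-consecutive sequence numbers, unordered or
#' duplicate injection dates, covariate ids not matching injection ids, and
#' categorical values absent from the schema's declared levels.
#'
#' @param dir Directory containing `injections.csv`, `covariates.csv`, and
#'   `schema.json`.
#' @return A `synthetic_cohort`.
#' @export
read_cohort <- function(dir) {
  paths <- c(injections = file.path(dir, "injections.csv"),
             covariates = file.path(dir, "covariates.csv"),
             schema = file.path(dir, "schema.json"))
  for (p in paths)
    if (!file.exists(p)) stop("missing cohort file: ", p, call. = FALSE)
  schema <- jsonlite::read_json(paths[["schema"]], simplifyVector = TRUE)
  inj <- utils::read.csv(paths[["injections"]], stringsAsFactors = FALSE)
  cov <- utils::read.csv(paths[["covariates"]], stringsAsFactors = FALSE)

  need_inj <- c("patient_id", "injection_seq", "injection_date")
  if (!all(need_inj %in% names(inj)))
    stop("malformed injections file: needs columns ",
         paste(need_inj, collapse = ", "), call. = FALSE)
  if (!all(c("patient_id", "observation_end_date") %in% names(cov)))
    stop("malformed covariates file: needs patient_id and ",
         "observation_end_date", call. = FALSE)
  if (anyDuplicated(cov$patient_id))
    stop("duplicate patient ids in covariates file", call. = FALSE)
  if (anyDuplicated(inj[c("patient_id", "injection_seq")]))
    stop("duplicate (patient_id, injection_seq) rows in injections file",
         call. = FALSE)

  inj$injection_date <- as.Date(inj$injection_date)
  cov$observation_end_date <- as.Date(cov$observation_end_date)
  if (anyNA(inj$injection_date) || anyNA(cov$observation_end_date))
    stop("unparseable dates in cohort files", call. = FALSE)

  # schema-driven covariate typing and level validation
  cov_specs <- schema$covariates
  if (is.data.frame(cov_specs))
    cov_specs <- split(cov_specs, seq_len(nrow(cov_specs)))
  for (spec in cov_specs) {
    nm <- spec$name
    if (!nm %in% names(cov))
      stop("covariate '", nm, "' declared in schema but absent from file",
           call. = FALSE)
    if (spec$type == "binary") {
      cov[[nm]] <- as.logical(cov[[nm]])
    } else if (spec$type == "categorical") {
      lv <- unlist(spec$levels)
      bad <- setdiff(stats::na.omit(unique(cov[[nm]])), lv)
      if (length(bad))
        stop("covariate '", nm, "' has value(s) outside declared levels: ",
             paste(bad, collapse = ", "), call. = FALSE)
      cov[[nm]] <- factor(cov[[nm]], levels = lv)
    }
  }
  if (!is.null(schema$strata))
    cov$stratum <- factor(cov$stratum, levels = unlist(schema$strata))

  if (!setequal(unique(inj$patient_id), cov$patient_id))
    stop("patient ids differ between injections and covariates files",
         call. = FALSE)

  ord <- order(match(inj$patient_id, cov$patient_id), inj$injection_seq)
  inj <- inj[ord, ]
  histories <- lapply(split(inj, factor(inj$patient_id,
                                        levels = cov$patient_id)),
                      function(d) {
    if (!identical(d$injection_seq, seq_len(nrow(d))))
      stop("injection_seq for patient ", d$patient_id[1L],
           " is not consecutive from 1", call. = FALSE)
    days <- as.integer(d$injection_date - d$injection_date[1L])
    if (nrow(d) > 1L && any(diff(days) <= 0L))
      stop("injection dates for patient ", d$patient_id[1L],
           " are not strictly increasing", call. = FALSE)
    end_date <- cov$observation_end_date[match(d$patient_id[1L],
                                               cov$patient_id)]
    injection_history(d$patient_id[1L], days,
                      as.integer(end_date - d$injection_date[1L]))
  })
  names(histories) <- NULL
  # histories are ordered by cov$patient_id, so this aligns row-wise
  cov$observation_end_day <- vapply(histories,
                                    function(h) h$observation_end_day,
                                    integer(1))
  cov$observation_end_date <- NULL
  structure(list(histories = histories, covariates = cov, truth = NULL),
            class = "synthetic_cohort")
}
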