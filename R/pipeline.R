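#' Pipeline run configuration
#'
#' Bundles everything one end-to-end run needs: either a simulation config
#' (synthetic cohort) or an input directory of cohort files, the gap-window
#' policy, stepwise thresholds, analysis horizon, strata to analyze, and the
#' output directory.
#'
#' @param out_dir Output directory for the report bundle.
#' @param sim A [simulation_config()], or `NULL` to read files.
#' @param input_dir Directory with cohort files (see [read_cohort()]);
#'   required when `sim` is `NULL`.
#' @param policy A [window_policy()].
#' @param thresholds A [selection_thresholds()].
#' @param horizon_days Analysis horizon (default 731).
#' @param required_injections Injections required for persistence/adherence
#'   (default 4).
#' @param strata Stratum labels to analyze (`NULL` = all present).
#' @param candidates Candidate covariate columns for the stepwise model
#'   (`NULL` = all eligible covariate columns in the data).
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir, sim = NULL, input_dir = NULL,
                       policy = window_policy(),
                       thresholds = selection_thresholds(),
                       horizon_days = 731L, required_injections = 4L,
                       strata = NULL, candidates = NULL) {
  if (is.null(sim) && is.null(input_dir))
    stop("run_config needs either a simulation config or an input_dir",
         call. = FALSE)
  if (is.null(sim) && !dir.exists(input_dir))
    stop("input_dir does not exist: ", input_dir, call. = FALSE)
  if (as.integer(horizon_days) <= 0L)
    stop("horizon_days must be positive", call. = FALSE)
  structure(
    list(out_dir = out_dir, sim = sim, input_dir = input_dir,
         policy = policy, thresholds = thresholds,
         horizon_days = as.integer(horizon_days),
         required_injections = as.integer(required_injections),
         strata = strata, candidates = candidates),
    class = "run_config"
  )
}

mean_ci <- function(x) {
  m <- mean(x)
  se <- stats::sd(x) / sqrt(length(x))
  z <- stats::qnorm(0.975)
  c(mean = m, ci95_low = m - z * se, ci95_high = m + z * se)
}

default_candidates <- function(covariates) {
  skip <- c("patient_id", "stratum", "observation_end_day",
            "mmas8_score", "n_concomitant_meds")
  cands <- setdiff(names(covariates), skip)
  # derived categorizations usable as candidates
  cands
}

#' Run the full simulate/metrics/model pipeline
#'
#' Generates (or reads) a cohort, computes per-patient outcomes, per-stratum
#' persistence/adherence proportions with 95% CIs, MCR means with 95% CIs,
#' the sensitivity-window grid, and one stepwise logistic model per stratum,
#' writing a deterministic report bundle: `outcomes.csv`, `summary.csv`,
#' `sensitivity.csv`, `model_<stratum>.json`, `table2_<stratum>.csv`,
#' `forest_<stratum>.csv`, `config.json`, and `manifest.json` (config hash,
#' seed, package version, file list). Identical configs produce
#' byte-identical bundles.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory `cohort`, `outcomes`,
#'   `summary`, `sensitivity`, `models`, and the bundle `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  cohort <- if (!is.null(config$sim)) generate_cohort(config$sim)
            else read_cohort(config$input_dir)
  cov <- cohort$covariates
  strata <- config$strata
  if (is.null(strata)) strata <- levels(droplevels(factor(cov$stratum)))
  unknown <- setdiff(strata, unique(as.character(cov$stratum)))
  if (length(unknown))
    stop("unknown stratum label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)

  outcomes <- patient_outcomes(cohort$histories, config$policy,
                               config$horizon_days,
                               config$required_injections)
  outcomes$stratum <- as.character(cov$stratum[match(outcomes$patient_id,
                                                     cov$patient_id)])

  summary_rows <- list()
  sens_rows <- list()
  models <- list()
  for (s in strata) {
    in_s <- outcomes$stratum == s
    if (!any(in_s)) stop("empty stratum: ", s, call. = FALSE)
    n_s <- sum(in_s)
    pers <- summarize_proportion(sum(outcomes$persistent_24m[in_s]), n_s)
    adh <- summarize_proportion(sum(outcomes$adherent_24m[in_s]), n_s)
    mcr <- mean_ci(outcomes$mcr_percent[in_s])
    summary_rows[[s]] <- data.frame(
      stratum = s, n = n_s,
      persistent_n = pers$n_success,
      persistence_percent = pers$proportion_percent,
      persistence_ci_low = pers$ci95_low,
      persistence_ci_high = pers$ci95_high,
      adherent_n = adh$n_success,
      adherence_percent = adh$proportion_percent,
      adherence_ci_low = adh$ci95_low,
      adherence_ci_high = adh$ci95_high,
      mcr_mean = round(mcr[["mean"]], 1),
      mcr_ci_low = round(mcr[["ci95_low"]], 1),
      mcr_ci_high = round(mcr[["ci95_high"]], 1)
    )
    grid <- sensitivity_grid(cohort$histories[in_s], config$policy,
                             horizon_days = config$horizon_days,
                             required_injections =
                               config$required_injections)
    grid <- cbind(stratum = s, grid)
    sens_rows[[s]] <- grid

    cov_s <- cov[as.character(cov$stratum) == s, , drop = FALSE]
    out_s <- outcomes[match(cov_s$patient_id, outcomes$patient_id), ]
    cands <- config$candidates
    if (is.null(cands)) cands <- default_candidates(cov)
    cands <- cands[vapply(cands, function(v) {
      col <- cov_s[[v]][!is.na(cov_s[[v]])]
      length(unique(as.character(col))) >= 2L
    }, logical(1))]
    models[[s]] <- list(
      stepwise = stepwise_select(out_s$persistent_24m, cov_s, cands,
                                 config$thresholds),
      outcome = out_s$persistent_24m, data = cov_s
    )
  }

  summary_df <- do.call(rbind, summary_rows); rownames(summary_df) <- NULL
  sens_df <- do.call(rbind, sens_rows); rownames(sens_df) <- NULL

  paths <- c(outcomes = file.path(config$out_dir, "outcomes.csv"),
             summary = file.path(config$out_dir, "summary.csv"),
             sensitivity = file.path(config$out_dir, "sensitivity.csv"),
             config = file.path(config$out_dir, "config.json"),
             manifest = file.path(config$out_dir, "manifest.json"))
  out_ser <- outcomes
  out_ser$mcr_percent <- round(out_ser$mcr_percent, 1)
  utils::write.csv(out_ser, paths[["outcomes"]], row.names = FALSE)
  utils::write.csv(summary_df, paths[["summary"]], row.names = FALSE)
  utils::write.csv(sens_df, paths[["sensitivity"]], row.names = FALSE)

  model_paths <- character(0)
  for (s in names(models)) {
    sw <- models[[s]]$stepwise
    tag <- gsub("[^A-Za-z0-9]+", "_", s)
    mp <- file.path(config$out_dir, paste0("model_", tag, ".json"))
    tp <- file.path(config$out_dir, paste0("table2_", tag, ".csv"))
    fp <- file.path(config$out_dir, paste0("forest_", tag, ".csv"))
    or_ser <- sw$or_table
    num <- vapply(or_ser, is.numeric, logical(1))
    or_ser[num] <- lapply(or_ser[num], function(x) signif(x, 10))
    jsonlite::write_json(
      list(stratum = s, selected = sw$selected,
           coefficients = as.list(signif(sw$coefficients, 10)),
           or_table = or_ser, n_complete_cases = sw$n_complete_cases,
           trace = transform(sw$trace, p_value = signif(p_value, 10)),
           thresholds = unclass(sw$thresholds)),
      mp, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    t2 <- table2_report(models[[s]]$outcome, models[[s]]$data, sw)
    utils::write.csv(t2, tp, row.names = FALSE)
    forest <- sw$or_table[, c("term", "covariate", "odds_ratio",
                              "ci_low", "ci_high", "p_value")]
    forest$odds_ratio <- round(forest$odds_ratio, 2)
    forest$ci_low <- round(forest$ci_low, 2)
    forest$ci_high <- round(forest$ci_high, 2)
    forest$p_value <- signif(forest$p_value, 3)
    utils::write.csv(forest, fp, row.names = FALSE)
    model_paths <- c(model_paths, mp, tp, fp)
  }

  cfg_json <- serialize_run_config(config)
  writeLines(cfg_json, paths[["config"]])
  manifest <- list(
    package = "dosegap",
    version = as.character(utils::packageVersion("dosegap")),
    seed = if (!is.null(config$sim)) config$sim$seed else NA,
    config_md5 = unname(tools::md5sum(paths[["config"]])),
    files = sort(basename(c(paths[setdiff(names(paths), "manifest")],
                            model_paths)))
  )
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(cohort = cohort, outcomes = outcomes, summary = summary_df,
                 sensitivity = sens_df, models = models,
                 paths = c(paths, model_paths)))
}

serialize_run_config <- function(config) {
  ser <- list(
    policy = unclass(config$policy),
    thresholds = unclass(config$thresholds),
    horizon_days = config$horizon_days,
    required_injections = config$required_injections,
    strata = config$strata,
    candidates = config$candidates,
    input_dir = config$input_dir
  )
  if (!is.null(config$sim)) {
    sim <- unclass(config$sim)
    sim$strata <- as.list(sim$strata)
    sim$true_log_odds <- as.list(sim$true_log_odds)
    ser$sim <- sim
  }
  jsonlite::toJSON(ser, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                   null = "null")
}

#' Validate cohort input files
#'
#' Itemizes violations instead of stopping at the first problem: missing or
#' malformed columns, duplicate patient ids, duplicate or non-consecutive
#' injection sequence numbers, unordered or duplicate injection dates
#' (zero-day gaps), categorical values outside the schema's declared levels,
#' and MMAS-8 scores outside \[0, 8\].
#'
#' @param dir Directory containing `injections.csv`, `covariates.csv`,
#'   `schema.json`.
#' @return An object of class `validation_report`: a data frame with
#'   columns `file`, `context`, `message` (zero rows when everything
#'   passes); attribute `ok`.
#' @export
validate_inputs <- function(dir) {
  violations <- list()
  note <- function(file, context, message)
    violations[[length(violations) + 1L]] <<-
      data.frame(file = file, context = context, message = message)

  paths <- c(injections = file.path(dir, "injections.csv"),
             covariates = file.path(dir, "covariates.csv"),
             schema = file.path(dir, "schema.json"))
  for (nm in names(paths))
    if (!file.exists(paths[[nm]]))
      note(basename(paths[[nm]]), "-", "file missing")
  if (length(violations)) return(validation_report(violations))

  schema <- tryCatch(jsonlite::read_json(paths[["schema"]],
                                         simplifyVector = TRUE),
                     error = function(e) {
                       note("schema.json", "-",
                            paste("unparseable JSON:", conditionMessage(e)))
                       NULL
                     })
  inj <- utils::read.csv(paths[["injections"]], stringsAsFactors = FALSE)
  cov <- utils::read.csv(paths[["covariates"]], stringsAsFactors = FALSE)

  need_inj <- c("patient_id", "injection_seq", "injection_date")
  miss <- setdiff(need_inj, names(inj))
  if (length(miss))
    note("injections.csv", "-",
         paste("missing column(s):", paste(miss, collapse = ", ")))
  if (!"patient_id" %in% names(cov))
    note("covariates.csv", "-", "missing column: patient_id")
  if (length(violations)) return(validation_report(violations))

  dup <- cov$patient_id[duplicated(cov$patient_id)]
  for (d in unique(dup))
    note("covariates.csv", d, "duplicate patient id")
  dup_inj <- duplicated(inj[c("patient_id", "injection_seq")])
  for (i in which(dup_inj))
    note("injections.csv", inj$patient_id[i],
         paste0("duplicate injection_seq ", inj$injection_seq[i]))

  inj$injection_date <- as.Date(inj$injection_date)
  for (i in which(is.na(inj$injection_date)))
    note("injections.csv", inj$patient_id[i], "unparseable injection_date")

  for (pid in unique(inj$patient_id)) {
    d <- inj[inj$patient_id == pid, ]
    d <- d[order(d$injection_seq), ]
    if (!identical(as.integer(d$injection_seq), seq_len(nrow(d))))
      note("injections.csv", pid, "injection_seq not consecutive from 1")
    dates <- d$injection_date[!is.na(d$injection_date)]
    if (length(dates) > 1L) {
      gaps <- as.integer(diff(dates))
      if (any(gaps == 0L))
        note("injections.csv", pid, "duplicate injection date (0-day gap)")
      if (any(gaps < 0L))
        note("injections.csv", pid, "injection dates out of order")
    }
  }

  if (!is.null(schema)) {
    cov_specs <- schema$covariates
    if (is.data.frame(cov_specs))
      cov_specs <- split(cov_specs, seq_len(nrow(cov_specs)))
    for (spec in cov_specs) {
      nm <- spec$name
      if (!nm %in% names(cov)) {
        note("covariates.csv", nm, "covariate declared in schema but absent")
        next
      }
      if (identical(spec$type, "categorical")) {
        lv <- unlist(spec$levels)
        bad <- setdiff(stats::na.omit(unique(cov[[nm]])), lv)
        for (b in bad)
          note("covariates.csv", nm,
               paste0("value '", b, "' outside declared levels"))
      }
    }
  }
  if ("mmas8_score" %in% names(cov)) {
    bad <- which(!is.na(cov$mmas8_score) &
                   (cov$mmas8_score < 0 | cov$mmas8_score > 8))
    for (i in bad)
      note("covariates.csv", cov$patient_id[i],
           paste0("MMAS-8 score ", cov$mmas8_score[i], " outside [0, 8]"))
  }
  validation_report(violations)
}

validation_report <- function(violations) {
  df <- if (length(violations)) do.call(rbind, violations)
        else data.frame(file = character(0), context = character(0),
                        message = character(0))
  rownames(df) <- NULL
  structure(df, ok = nrow(df) == 0L,
            class = c("validation_report", class(df)))
}

#' @export
print.validation_report <- function(x, ...) {
  if (attr(x, "ok")) cat("validation passed: no violations\n")
  else {
    cat(sprintf("validation failed: %d violation(s)\n", nrow(x)))
    print(as.data.frame(x))
  }
  invisible(x)
}
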