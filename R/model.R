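#' Stepwise selection thresholds
#'
#' Entry requires a p-value at or below `p_enter` (default 0.25); an
#' in-model covariate is removed when its p-value exceeds `p_stay`
#' (default 0.30). Individual covariates in the final model are flagged
#' significant at `p_significant` (default 0.05).
#'
#' @param p_enter,p_stay,p_significant Probabilities in (0, 1).
#' @return An object of class `selection_thresholds`.
#' @export
selection_thresholds <- function(p_enter = 0.25, p_stay = 0.30,
                                 p_significant = 0.05) {
  vals <- c(p_enter = p_enter, p_stay = p_stay,
            p_significant = p_significant)
  if (any(vals <= 0) || any(vals >= 1))
    stop("selection thresholds must lie in (0, 1)", call. = FALSE)
  if (p_enter > p_stay)
    warning("p_enter > p_stay can cycle; a step limit guards termination")
  structure(as.list(vals), class = "selection_thresholds")
}

# Build an intercept + treatment-coded design matrix for `vars` on `data`.
# Factors contribute one dummy per non-reference level (block); logicals a
# single TRUE indicator; numerics a single column. `assign` maps columns to
# variables for block tests.
build_design <- function(data, vars) {
  n <- nrow(data)
  X <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  assign <- "(Intercept)"
  for (v in vars) {
    col <- data[[v]]
    if (is.null(col)) stop("unknown covariate: ", v, call. = FALSE)
    if (is.logical(col)) {
      X <- cbind(X, as.numeric(col))
      colnames(X)[ncol(X)] <- paste0(v, "TRUE")
      assign <- c(assign, v)
    } else if (is.factor(col) || is.character(col)) {
      f <- if (is.factor(col)) droplevels(col) else factor(col)
      lv <- levels(f)
      if (length(lv) < 2L)
        stop("degenerate covariate (single level): ", v, call. = FALSE)
      for (l in lv[-1L]) {
        X <- cbind(X, as.numeric(f == l))
        colnames(X)[ncol(X)] <- paste0(v, l)
        assign <- c(assign, v)
      }
    } else {
      if (length(unique(col)) < 2L)
        stop("degenerate covariate (single value): ", v, call. = FALSE)
      X <- cbind(X, as.numeric(col))
      colnames(X)[ncol(X)] <- v
      assign <- c(assign, v)
    }
  }
  list(X = X, assign = assign)
}

#' Fit a logistic regression by maximum likelihood
#'
#' IRLS fit (via `stats::glm.fit`, binomial logit link) with convergence
#' tolerance 1e-8 and at most 100 iterations, wrapped with explicit failure
#' modes: a constant outcome, a rank-deficient design, and complete or
#' quasi-complete separation each raise an informative error rather than
#' returning silently enormous estimates. Separation is flagged when the
#' fit fails to converge or any coefficient exceeds 15 in absolute value
#' while some fitted probabilities are numerically 0 or 1.
#'
#' @param outcome Logical (or 0/1) response vector.
#' @param design Numeric matrix of coded covariates (no intercept column;
#'   one is added), or `NULL` for an intercept-only model.
#' @return An object of class `logit_fit`: `coefficients`, `vcov`, `loglik`,
#'   `n`, `df_model` (non-intercept parameters), `fitted`, `converged`.
#' @export
fit_logistic <- function(outcome, design = NULL) {
  y <- as.numeric(outcome)
  if (anyNA(y) || !all(y %in% c(0, 1)))
    stop("outcome must be logical or 0/1 without missing values",
         call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("outcome is constant: need at least one observation per class",
         call. = FALSE)
  if (is.null(design)) {
    X <- matrix(1, length(y), 1L, dimnames = list(NULL, "(Intercept)"))
  } else {
    design <- as.matrix(design)
    if (nrow(design) != length(y))
      stop("design and outcome lengths differ", call. = FALSE)
    if (is.null(colnames(design)))
      colnames(design) <- paste0("x", seq_len(ncol(design)))
    X <- cbind("(Intercept)" = 1, design)
  }
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient after coding", call. = FALSE)
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-8,
                                                maxit = 100L)))
  beta <- fit$coefficients
  mu <- fit$fitted.values
  degenerate_mu <- any(mu < 1e-8 | mu > 1 - 1e-8)
  if (!fit$converged || (max(abs(beta)) > 15 && degenerate_mu))
    stop("separation detected: logistic fit is non-convergent or has ",
         "diverging coefficients", call. = FALSE)
  w <- mu * (1 - mu)
  xtwx <- crossprod(X * sqrt(w))
  vcov <- tryCatch(chol2inv(chol(xtwx)), error = function(e)
    stop("information matrix is singular", call. = FALSE))
  dimnames(vcov) <- list(colnames(X), colnames(X))
  mu_c <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  ll <- sum(y * log(mu_c) + (1 - y) * log(1 - mu_c))
  structure(
    list(coefficients = beta, vcov = vcov, loglik = ll, n = length(y),
         df_model = ncol(X) - 1L, fitted = mu, converged = fit$converged),
    class = "logit_fit"
  )
}

#' @export
print.logit_fit <- function(x, ...) {
  cat(sprintf("<logit_fit> n = %d, df = %d, logLik = %.3f\n",
              x$n, x$df_model, x$loglik))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Likelihood-ratio p-value for nested logistic models
#'
#' Applies a chi-squared test with degrees of freedom equal to the parameter
#' difference to twice the log-likelihood difference. Both models must be
#' fitted on identical observations; identical models give p = 1.
#'
#' @param model_small,model_large Nested [fit_logistic()] fits (small within
#'   large) on the same complete cases.
#' @return The LR p-value.
#' @export
lr_pvalue <- function(model_small, model_large) {
  stopifnot(inherits(model_small, "logit_fit"),
            inherits(model_large, "logit_fit"))
  if (model_small$n != model_large$n)
    stop("models are fitted on different observation sets", call. = FALSE)
  if (model_small$df_model > model_large$df_model)
    stop("models are not nested (small has more parameters)", call. = FALSE)
  stat <- 2 * (model_large$loglik - model_small$loglik)
  ddf <- model_large$df_model - model_small$df_model
  if (ddf == 0L) {
    if (abs(stat) > 1e-6)
      stop("models have equal dimension but different likelihoods: ",
           "not nested", call. = FALSE)
    return(1)
  }
  if (stat < 0) {
    if (stat < -1e-6)
      stop("larger model has lower likelihood: models are not nested ",
           "or not fitted on the same cases", call. = FALSE)
    stat <- 0
  }
  stats::pchisq(stat, df = ddf, lower.tail = FALSE)
}

# Rows of `data` complete for `vars` (explicit factor levels like "missing"
# or "n/a" count as data; only true NA is missing).
complete_rows <- function(data, vars) {
  if (!length(vars)) return(seq_len(nrow(data)))
  ok <- rep(TRUE, nrow(data))
  for (v in vars) ok <- ok & !is.na(data[[v]])
  which(ok)
}

fit_on <- function(outcome, data, vars, rows) {
  des <- if (length(vars)) build_design(data[rows, , drop = FALSE], vars)
         else NULL
  fit <- fit_logistic(outcome[rows],
                      if (is.null(des)) NULL else des$X[, -1L, drop = FALSE])
  fit$assign <- if (is.null(des)) "(Intercept)" else des$assign
  fit
}

#' Stepwise covariate selection for a logistic model
#'
#' Alternating forward/backward stepwise selection. Forward step: among
#' candidates not in the model, the one with the smallest entry p-value
#' joins if that p-value is at or below `p_enter` (ties broken by candidate
#' order). Backward step: the in-model covariate with the largest p-value is
#' removed if it exceeds `p_stay`. Steps alternate until neither changes the
#' model. Entry/stay p-values are likelihood-ratio tests by default (Wald
#' optionally); multi-level factors enter and leave as one block with a
#' multi-df test. The procedure is deterministic given the candidate order.
#'
#' Complete cases follow the iterative "N1" rule by default: each test uses
#' patients with data for all currently selected covariates plus (for entry)
#' the candidate, and the reported `n_complete_cases` is recomputed for the
#' final selected set. `complete_case = "fixed"` restricts once, up front,
#' to patients complete for every candidate.
#'
#' Because `p_enter < p_stay` cannot by itself cycle forever, a step limit
#' of `2 * length(candidates)^2 + 2` plus a visited-model check guarantees
#' termination; on a detected cycle the best model seen (by log-likelihood)
#' is returned. Candidates degenerate on their complete cases (a single
#' observed level) or causing separation are skipped for that step.
#'
#' @param outcome Logical response (e.g. 24-month persistence), aligned with
#'   `data` rows.
#' @param data Data frame of candidate covariates (logical, factor, or
#'   numeric columns).
#' @param candidates Character vector of column names to consider, in the
#'   order that breaks ties.
#' @param thresholds A [selection_thresholds()].
#' @param complete_case `"iterative"` (default) or `"fixed"`.
#' @param test `"lr"` (default) or `"wald"` for entry/stay decisions.
#' @return An object of class `stepwise_result`: `selected` (ordered names),
#'   `fit` (final [fit_logistic()] on the selected complete cases),
#'   `coefficients`, `or_table` (level, OR, Wald 95% CI, Wald p,
#'   significance), `n_complete_cases`, `trace` (data frame of step, action,
#'   covariate, p_value), `thresholds`.
#' @export
stepwise_select <- function(outcome, data, candidates,
                            thresholds = selection_thresholds(),
                            complete_case = c("iterative", "fixed"),
                            test = c("lr", "wald")) {
  complete_case <- match.arg(complete_case)
  test <- match.arg(test)
  stopifnot(inherits(thresholds, "selection_thresholds"))
  outcome <- as.logical(outcome)
  if (length(outcome) != nrow(data))
    stop("outcome and data lengths differ", call. = FALSE)
  keep <- !is.na(outcome)
  data <- data[keep, , drop = FALSE]
  outcome <- outcome[keep]
  missing_cols <- setdiff(candidates, names(data))
  if (length(missing_cols))
    stop("unknown candidate(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)

  fixed_rows <- if (complete_case == "fixed")
    complete_rows(data, candidates) else NULL
  if (complete_case == "fixed" && !length(fixed_rows))
    stop("no complete cases across the candidate set", call. = FALSE)
  rows_for <- function(vars) {
    if (complete_case == "fixed") fixed_rows else complete_rows(data, vars)
  }

  block_p <- function(vars_small, var_add, rows) {
    # p-value for adding var_add's block to vars_small on the given rows
    tryCatch({
      large <- fit_on(outcome, data, c(vars_small, var_add), rows)
      if (test == "lr") {
        small <- fit_on(outcome, data, vars_small, rows)
        lr_pvalue(small, large)
      } else {
        idx <- which(large$assign == var_add)
        b <- large$coefficients[idx]
        V <- large$vcov[idx, idx, drop = FALSE]
        stat <- drop(t(b) %*% solve(V, b))
        stats::pchisq(stat, df = length(idx), lower.tail = FALSE)
      }
    }, error = function(e) NA_real_)
  }

  selected <- character(0)
  trace <- list()
  step <- 0L
  step_limit <- 2L * length(candidates)^2 + 2L
  visited <- character(0)
  best <- NULL

  note_state <- function(vars) {
    rows <- rows_for(vars)
    fit <- tryCatch(fit_on(outcome, data, vars, rows),
                    error = function(e) NULL)
    if (!is.null(fit) &&
        (is.null(best) || fit$loglik / fit$n > best$ll_per_n))
      best <<- list(vars = vars, ll_per_n = fit$loglik / fit$n)
    key <- paste(sort(vars), collapse = "|")
    cycled <- key %in% visited
    visited <<- c(visited, key)
    cycled
  }
  note_state(selected)

  repeat {
    changed <- FALSE
    # forward
    pool <- setdiff(candidates, selected)
    if (length(pool)) {
      pvals <- vapply(pool, function(cand) {
        rows <- rows_for(c(selected, cand))
        if (length(rows) < 2L) return(NA_real_)
        block_p(selected, cand, rows)
      }, numeric(1))
      if (any(!is.na(pvals))) {
        best_i <- which.min(pvals)  # ties: first in candidate order
        if (pvals[best_i] <= thresholds$p_enter) {
          selected <- c(selected, pool[best_i])
          step <- step + 1L
          trace[[step]] <- data.frame(step = step, action = "enter",
                                      covariate = pool[best_i],
                                      p_value = unname(pvals[best_i]))
          changed <- TRUE
        }
      }
    }
    # backward
    if (length(selected)) {
      rows <- rows_for(selected)
      stay_p <- vapply(selected, function(v) {
        tryCatch({
          full <- fit_on(outcome, data, selected, rows)
          small <- fit_on(outcome, data, setdiff(selected, v), rows)
          if (test == "lr") lr_pvalue(small, full)
          else {
            idx <- which(full$assign == v)
            b <- full$coefficients[idx]
            V <- full$vcov[idx, idx, drop = FALSE]
            stats::pchisq(drop(t(b) %*% solve(V, b)), df = length(idx),
                          lower.tail = FALSE)
          }
        }, error = function(e) NA_real_)
      }, numeric(1))
      if (any(!is.na(stay_p)) &&
          max(stay_p, na.rm = TRUE) > thresholds$p_stay) {
        worst <- which.max(stay_p)
        step <- step + 1L
        trace[[step]] <- data.frame(step = step, action = "remove",
                                    covariate = selected[worst],
                                    p_value = unname(stay_p[worst]))
        selected <- setdiff(selected, selected[worst])
        changed <- TRUE
      }
    }
    if (!changed) break
    if (note_state(selected) || step >= step_limit) {
      # cycle or step cap: fall back to the best model seen
      selected <- best$vars
      break
    }
  }

  rows <- rows_for(selected)
  final <- fit_on(outcome, data, selected, rows)
  or_table <- wald_or_table(final, thresholds$p_significant)
  trace <- if (length(trace)) do.call(rbind, trace)
    else data.frame(step = integer(0), action = character(0),
                    covariate = character(0), p_value = numeric(0))
  structure(
    list(selected = selected, fit = final,
         coefficients = final$coefficients, or_table = or_table,
         n_complete_cases = length(rows), trace = trace,
         thresholds = thresholds, complete_case = complete_case,
         test = test, candidates = candidates),
    class = "stepwise_result"
  )
}

# Wald odds ratios, 95% CIs and p-values for the non-intercept terms.
wald_or_table <- function(fit, p_significant = 0.05) {
  coefs <- fit$coefficients
  se <- sqrt(diag(fit$vcov))
  keep <- names(coefs) != "(Intercept)"
  z <- stats::qnorm(0.975)
  p <- 2 * stats::pnorm(-abs(coefs / se))
  data.frame(
    term = names(coefs)[keep],
    covariate = fit$assign[keep],
    log_odds = unname(coefs[keep]),
    odds_ratio = unname(exp(coefs[keep])),
    ci_low = unname(exp(coefs[keep] - z * se[keep])),
    ci_high = unname(exp(coefs[keep] + z * se[keep])),
    p_value = unname(p[keep]),
    significant = unname(p[keep] <= p_significant)
  )
}

#' @export
print.stepwise_result <- function(x, ...) {
  cat(sprintf("<stepwise_result> %d selected of %d candidate(s); N1 = %d\n",
              length(x$selected), length(x$candidates), x$n_complete_cases))
  if (length(x$selected)) {
    cat("selected:", paste(x$selected, collapse = ", "), "\n")
    print(transform(x$or_table,
                    odds_ratio = round(odds_ratio, 2),
                    ci_low = round(ci_low, 2), ci_high = round(ci_high, 2),
                    log_odds = round(log_odds, 3),
                    p_value = signif(p_value, 3)))
  }
  invisible(x)
}

significance_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p <= 0.001, "***",
                ifelse(p <= 0.01, "**", ifelse(p <= 0.05, "*", ""))))
}

#' Per-level persistence breakdown for selected covariates
#'
#' Builds the per-level `n/N1 (%)` breakdown: for each level of each
#' selected covariate, the number of persistent patients and the level's
#' complete-case denominator (patients with data for all selected
#' covariates), the percentage (one decimal), the Wald p-value of the
#' level's contrast in the final model, and significance stars
#' (`*` p <= 0.05, `**` p <= 0.01, `***` p <= 0.001; the reference level
#' carries no star).
#'
#' @param outcome Logical response aligned with `data`.
#' @param data Covariate data frame used for the fit.
#' @param result A [stepwise_select()] result.
#' @return Data frame with columns `covariate`, `level`, `reference`, `n`,
#'   `N1`, `percent`, `p_value`, `stars`.
#' @export
table2_report <- function(outcome, data, result) {
  stopifnot(inherits(result, "stepwise_result"))
  outcome <- as.logical(outcome)
  keep <- !is.na(outcome)
  data <- data[keep, , drop = FALSE]
  outcome <- outcome[keep]
  rows <- complete_rows(data, result$selected)
  data <- data[rows, , drop = FALSE]
  outcome <- outcome[rows]
  out <- list()
  for (v in result$selected) {
    col <- data[[v]]
    if (is.logical(col)) {
      f <- factor(ifelse(col, "Yes", "No"), levels = c("No", "Yes"))
      term_for <- function(l) if (l == "Yes") paste0(v, "TRUE") else NA
    } else if (is.factor(col) || is.character(col)) {
      f <- droplevels(as.factor(col))
      term_for <- function(l) paste0(v, l)
    } else {
      stop("table2_report supports logical or categorical covariates; '",
           v, "' is numeric", call. = FALSE)
    }
    for (i in seq_along(levels(f))) {
      l <- levels(f)[i]
      in_level <- !is.na(f) & f == l
      if (!any(in_level))
        stop("level '", l, "' of covariate '", v,
             "' is absent from the complete-case data", call. = FALSE)
      is_ref <- i == 1L
      p <- NA_real_
      if (!is_ref) {
        term <- term_for(l)
        hit <- match(term, result$or_table$term)
        if (!is.na(hit)) p <- result$or_table$p_value[hit]
      }
      out[[length(out) + 1L]] <- data.frame(
        covariate = v, level = l, reference = is_ref,
        n = sum(outcome[in_level]), N1 = sum(in_level),
        percent = round(100 * mean(outcome[in_level]), 1),
        p_value = p,
        stars = if (is_ref) "" else significance_stars(p)
      )
    }
  }
  if (!length(out))
    return(data.frame(covariate = character(0), level = character(0),
                      reference = logical(0), n = integer(0),
                      N1 = integer(0), percent = numeric(0),
                      p_value = numeric(0), stars = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
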