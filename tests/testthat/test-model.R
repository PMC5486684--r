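test_that("single-covariate logistic OR equals the 2x2 cross-product ratio", {
  # persistent/fall cell counts printed in the covariate table (Germany):
  # 70/101 persistent among fallers, 341/452 among non-fallers
  d <- expand_2x2(70, 101 - 70, 341, 452 - 341)
  fit <- fit_logistic(d$outcome, cbind(exposure = as.numeric(d$data$exposure)))
  or_closed <- (70 * (452 - 341)) / ((101 - 70) * 341)
  expect_equal(unname(exp(fit$coefficients["exposure"])), or_closed,
               tolerance = 1e-6)
  # a second arbitrary table
  d2 <- expand_2x2(13, 9, 184, 29)
  fit2 <- fit_logistic(d2$outcome,
                       cbind(exposure = as.numeric(d2$data$exposure)))
  expect_equal(unname(exp(fit2$coefficients["exposure"])),
               (13 * 29) / (9 * 184), tolerance = 1e-6)
})

test_that("fit_logistic rejects degenerate and separated problems", {
  expect_error(fit_logistic(rep(TRUE, 20), cbind(x = rnorm(20))),
               "constant")
  # perfect predictor: quasi-complete separation
  y <- c(rep(TRUE, 25), rep(FALSE, 25))
  x <- cbind(x = as.numeric(y))
  expect_error(fit_logistic(y, x), "separation")
  # rank-deficient design
  z <- rnorm(50)
  expect_error(fit_logistic(rep(c(TRUE, FALSE), 25), cbind(a = z, b = 2 * z)),
               "rank deficient")
})

test_that("lr_pvalue behaves at its boundaries", {
  set.seed(12)
  y <- runif(200) < 0.6
  x <- cbind(x = rnorm(200))
  m0 <- fit_logistic(y, NULL)
  m1 <- fit_logistic(y, x)
  expect_equal(lr_pvalue(m1, m1), 1)
  expect_gt(lr_pvalue(m0, m1), 0)
  expect_error(lr_pvalue(m1, m0), "nested")
  y2 <- y[1:100]
  expect_error(lr_pvalue(fit_logistic(y2, NULL), m1), "different")
})

test_that("LR p-values are uniform under the null and tiny under a strong effect", {
  set.seed(2024)
  pvals <- replicate(300, {
    y <- runif(400) < 0.7
    x <- cbind(x = as.numeric(runif(400) < 0.5))
    lr_pvalue(fit_logistic(y, NULL), fit_logistic(y, x))
  })
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.001)

  # true OR 0.3 at n = 2000: overwhelming evidence
  set.seed(77)
  x <- runif(2000) < 0.4
  p <- plogis(1.2 + log(0.3) * x)
  y <- runif(2000) < p
  pv <- lr_pvalue(fit_logistic(y, NULL),
                  fit_logistic(y, cbind(x = as.numeric(x))))
  expect_lt(pv, 1e-6)
})

test_that("stepwise_select enters strong covariates and skips empty input", {
  co <- generate_cohort(two_cov_config(n = 2000, seed = 3))
  out <- patient_outcomes(co)
  res <- stepwise_select(out$persistent_24m, co$covariates,
                         c("fall_12m", "null_cov"))
  expect_true("fall_12m" %in% res$selected)
  expect_equal(res$trace$action[1], "enter")
  expect_lte(res$trace$p_value[1], 0.25)
  expect_equal(res$n_complete_cases, 2000)

  empty <- stepwise_select(out$persistent_24m, co$covariates, character(0))
  expect_identical(empty$selected, character(0))
  expect_equal(nrow(empty$trace), 0)
  expect_named(empty$coefficients, "(Intercept)")
})

test_that("stepwise_select is deterministic and its trace replays to the final model", {
  co <- generate_cohort(two_cov_config(n = 1500, seed = 8))
  out <- patient_outcomes(co)
  cands <- c("fall_12m", "null_cov")
  r1 <- stepwise_select(out$persistent_24m, co$covariates, cands)
  r2 <- stepwise_select(out$persistent_24m, co$covariates, cands)
  expect_identical(r1$coefficients, r2$coefficients)
  expect_identical(r1$trace, r2$trace)

  # replaying the enter/remove actions reproduces the coefficients
  selected <- character(0)
  for (i in seq_len(nrow(r1$trace))) {
    a <- r1$trace[i, ]
    selected <- if (a$action == "enter") c(selected, a$covariate)
                else setdiff(selected, a$covariate)
  }
  expect_setequal(selected, r1$selected)
  rows <- which(stats::complete.cases(co$covariates[selected]))
  des <- model.matrix(~ ., data = co$covariates[rows, selected,
                                                drop = FALSE])
  refit <- fit_logistic(out$persistent_24m[rows], des[, -1, drop = FALSE])
  expect_equal(sort(unname(refit$coefficients)),
               sort(unname(r1$coefficients)), tolerance = 1e-8)
})

test_that("multi-level factors enter and leave as one block", {
  set.seed(5)
  n <- 1200
  grp <- factor(sample(c("<65", "65-<75", ">=75"), n, replace = TRUE,
                       prob = c(0.3, 0.4, 0.3)),
                levels = c("<65", "65-<75", ">=75"))
  eta <- qlogis(0.8) + (grp == ">=75") * log(0.4)
  y <- runif(n) < plogis(eta)
  res <- stepwise_select(y, data.frame(age_group = grp), "age_group")
  expect_identical(res$selected, "age_group")
  # one selected covariate, two contrasts in the OR table
  expect_equal(nrow(res$or_table), 2)
  expect_true(all(res$or_table$covariate == "age_group"))
})

test_that("iterative complete cases recompute N1 per selected set", {
  co <- generate_cohort(two_cov_config(n = 1000, seed = 13))
  out <- patient_outcomes(co)
  cov <- co$covariates
  cov$fall_12m[1:100] <- NA  # missing data on the strong covariate
  res <- stepwise_select(out$persistent_24m, cov,
                         c("fall_12m", "null_cov"))
  if (identical(res$selected, "fall_12m"))
    expect_equal(res$n_complete_cases, 900)
  fixed <- stepwise_select(out$persistent_24m, cov,
                           c("fall_12m", "null_cov"),
                           complete_case = "fixed")
  expect_equal(fixed$n_complete_cases,
               sum(stats::complete.cases(cov[c("fall_12m", "null_cov")])))
})

test_that("table2_report gives per-level counts, percentages, and stars", {
  d <- expand_2x2(70, 31, 341, 111)
  d$data$exposure <- factor(ifelse(d$data$exposure, "Yes", "No"),
                            levels = c("No", "Yes"))
  res <- stepwise_select(d$outcome, d$data, "exposure")
  expect_identical(res$selected, "exposure")
  t2 <- table2_report(d$outcome, d$data, res)
  expect_equal(t2$n, c(341, 70))
  expect_equal(t2$N1, c(452, 101))
  expect_equal(t2$percent, c(75.4, 69.3))
  expect_true(t2$reference[1])
  expect_identical(t2$stars[1], "")          # reference level: never starred
  wald_p <- res$or_table$p_value[1]
  expect_identical(t2$stars[2],
                   if (wald_p <= 0.05) "*" else "")
  # logical covariates work the same way
  d2 <- expand_2x2(40, 19, 110, 23)
  res2 <- stepwise_select(d2$outcome, d2$data, "exposure")
  t22 <- table2_report(d2$outcome, d2$data, res2)
  expect_equal(t22$percent, c(round(100 * 110 / 133, 1),
                              round(100 * 40 / 59, 1)))
  expect_error(table2_report(d2$outcome,
                             transform(d2$data, exposure = rnorm(133 + 59)),
                             res2),
               "numeric")
})

test_that("selection thresholds validate and warn on inverted order", {
  expect_error(selection_thresholds(p_enter = 0), "\\(0, 1\\)")
  expect_error(selection_thresholds(p_stay = 1), "\\(0, 1\\)")
  expect_warning(selection_thresholds(p_enter = 0.4, p_stay = 0.2),
                 "cycle")
})
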