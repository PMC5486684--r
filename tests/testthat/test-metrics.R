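test_that("persistence classification honors the inclusive gap window", {
  pol <- window_policy()  # limit 183 + 56 = 239
  cases <- list(
    list(gaps = c(183, 183, 183), expect = TRUE),   # on schedule
    list(gaps = c(239, 239, 239), expect = TRUE),   # boundary inclusive
    list(gaps = c(183, 183, 240), expect = FALSE),  # 1 day past the window
    list(gaps = c(240, 183, 183), expect = FALSE),  # early gap also counts
    list(gaps = c(183, 183), expect = FALSE)        # only 3 injections
  )
  for (cs in cases)
    expect_identical(classify_persistence(make_history(cs$gaps), pol),
                     cs$expect)
  # extra injections past the fourth are ignored by the classification
  expect_true(classify_persistence(make_history(c(183, 183, 183, 500),
                                                end = 1100), pol))
  expect_error(classify_persistence(make_history(c(183, 183, 183)), pol,
                                    required_injections = 1),
               "required_injections")
})

test_that("adherence classification honors the symmetric inclusive band", {
  pol <- window_policy()  # band [155, 211]
  cases <- list(
    list(gaps = c(183, 183, 183), expect = TRUE),
    list(gaps = c(211, 211, 211), expect = TRUE),   # upper bound inclusive
    list(gaps = c(155, 155, 155), expect = TRUE),   # lower bound inclusive
    list(gaps = c(154, 183, 183), expect = FALSE),  # 1 day too early
    list(gaps = c(183, 212, 183), expect = FALSE)   # 1 day too late
  )
  for (cs in cases)
    expect_identical(classify_adherence(make_history(cs$gaps), pol),
                     cs$expect)
})

test_that("MCR matches hand-derived values and stays in [0, 100]", {
  pol <- window_policy()
  expect_equal(compute_mcr(make_history(c(183, 183, 183), end = 731), pol),
               100)
  expect_equal(compute_mcr(injection_history("p", 0L, 731L), pol),
               100 * 183 / 731)
  # overlapping coverage is not double-counted: union [0, 283) over 366 days
  expect_equal(compute_mcr(injection_history("p", c(0L, 100L), 366L), pol,
                           horizon_days = 366),
               100 * 283 / 366)
  # early re-injection cannot push the MCR above 100
  h <- injection_history("p", c(0L, 10L, 20L, 30L), 200L)
  expect_lte(compute_mcr(h, pol), 100)
  expect_error(compute_mcr(make_history(183), pol, horizon_days = 0),
               "horizon_days")
})

test_that("interval-union MCR equals the day-grid oracle on random histories", {
  set.seed(42)
  pol <- window_policy()
  for (i in 1:100) {
    h <- random_history(paste0("r", i))
    denom <- min(731L, h$observation_end_day)
    expect_equal(compute_mcr(h, pol), mcr_daygrid(h, pol),
                 tolerance = 1 / denom)
  }
})

test_that("proportion summaries reproduce printed n/N percentages", {
  # n/N pairs printed in the persistence covariate table
  expect_equal(summarize_proportion(70, 101)$proportion_percent, 69.3)
  expect_equal(summarize_proportion(40, 59)$proportion_percent, 67.8)
  expect_equal(summarize_proportion(13, 22)$proportion_percent, 59.1)
  expect_equal(summarize_proportion(16, 28)$proportion_percent, 57.1)
  # degenerate numerator: CI lower bound clamps at 0
  s <- summarize_proportion(0, 50)
  expect_equal(s$proportion_percent, 0)
  expect_equal(s$ci95_low, 0)
  # Wilson bounds stay in [0, 100] near the top too
  s2 <- summarize_proportion(50, 50)
  expect_lte(s2$ci95_high, 100)
  # Wald option is offered and differs from Wilson away from 0.5
  expect_false(identical(summarize_proportion(5, 50, method = "wald"),
                         summarize_proportion(5, 50)))
  expect_error(summarize_proportion(5, 0), "positive")
  expect_error(summarize_proportion(6, 5), "n_success")
})

test_that("sensitivity grid is monotone and saturates for on-schedule cohorts", {
  on_schedule <- lapply(1:20, function(i)
    make_history(c(183, 183, 183), id = paste0("s", i)))
  grid <- sensitivity_grid(on_schedule)
  expect_true(all(grid$proportion_percent == 100))
  expect_setequal(grid$window_weeks, c(4, 6, 8, 12))

  set.seed(99)
  cfg <- simulation_config(
    n_patients = 400, gap_jitter = jitter_spec("late_mixture"),
    baseline_continuation_logit = stats::qlogis(0.95), seed = 11)
  co <- generate_cohort(cfg)
  g <- sensitivity_grid(co$histories)
  for (m in c("persistence", "adherence")) {
    p <- g$proportion_percent[g$metric == m][order(g$window_weeks[g$metric == m])]
    expect_true(all(diff(p) >= 0))
  }
  # heavy-tail late component actually separates the windows
  pers <- g[g$metric == "persistence", ]
  expect_gt(pers$proportion_percent[pers$window_weeks == 12],
            pers$proportion_percent[pers$window_weeks == 4])
})

test_that("window monotonicity: enlarging the allowance never flips to non-persistent", {
  set.seed(7)
  histories <- lapply(1:200, function(i) random_history(paste0("m", i)))
  for (w in list(c(4, 6), c(6, 8), c(8, 12))) {
    p_small <- window_policy(persistence_allowance_days = 7 * w[1])
    p_large <- window_policy(persistence_allowance_days = 7 * w[2])
    flips <- vapply(histories, function(h)
      classify_persistence(h, p_small) && !classify_persistence(h, p_large),
      logical(1))
    expect_false(any(flips))
  }
})

test_that("adherent implies persistent when tolerance <= allowance", {
  set.seed(8)
  pol <- window_policy()
  histories <- lapply(1:200, function(i) random_history(paste0("a", i)))
  bad <- vapply(histories, function(h)
    classify_adherence(h, pol) && !classify_persistence(h, pol), logical(1))
  expect_false(any(bad))
})

test_that("12-month persistence exceeds 24-month persistence (attrition)", {
  co <- generate_cohort(default_simulation_config(n_patients = 500,
                                                  seed = 21))
  pol <- window_policy()
  r12 <- mean(vapply(co$histories, classify_persistence, logical(1),
                     policy = pol, required_injections = 2))
  r24 <- mean(vapply(co$histories, classify_persistence, logical(1),
                     policy = pol, required_injections = 4))
  expect_gt(r12, r24)
})

test_that("MMAS-8 categorization follows the score cutpoints", {
  expect_equal(as.character(categorize_mmas(c(8, 7, 6, 5.5, 5, 0))),
               c("high", "medium", "medium", "low", "low", "low"))
  expect_true(is.na(categorize_mmas(NA)))
  expect_error(categorize_mmas(9), "\\[0, 8\\]")
  expect_error(categorize_mmas(-1), "\\[0, 8\\]")
})

test_that("history and policy constructors reject invalid inputs", {
  expect_error(injection_history("p", c(5, 200), 400), "day 0")
  expect_error(injection_history("p", c(0, 100, 100), 400),
               "strictly increasing")
  expect_error(injection_history("p", c(0, 100), 50), "observation_end_day")
  expect_error(window_policy(adherence_tolerance_days = 200),
               "adherence_tolerance_days")
  expect_error(window_policy(persistence_allowance_days = -1), "positive")
})
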