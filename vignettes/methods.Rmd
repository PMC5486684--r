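---
title: "Methods: gap-window metrics, stepwise persistence models, and the cohort simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gap-window metrics, stepwise persistence models, and the cohort simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical definitions the package
implements, the design choices made where the definitions left room, and
what the synthetic-data generator does and does not emulate. It states no
empirical result that the test suite does not itself compute.

## Setting

Postmenopausal women on 6-monthly subcutaneous osteoporosis therapy are
observed for 24 months (731 days) from their first injection, which
defines day 0. Four injections are scheduled at a nominal 183-day
interval. The analysis classifies each patient's medication-taking
behavior from the sequence of inter-injection gaps and models which
baseline characteristics are associated with remaining on therapy.

All dates are integer day offsets from the first injection. Calendar
dates (ISO-8601) exist only in the input/output files, anchored at an
origin date recorded in the sidecar schema. This removes time-zone and
leap-year ambiguity from every metric.

## Gap-window metrics

**Persistence (24 months).** All four injections received and every
consecutive gap among them at most `183 + 56` days (6 months + 8 weeks of
allowance for practical re-scheduling delays). Two choices deserve note:

- *Boundary inclusivity.* "Within 6 months + 8 weeks" is read as
  `gap <= 239`, inclusive; the same inclusivity applies to both adherence
  bounds. "Within" conventionally includes its bound; both windows are
  configurable through `window_policy()`.
- *All gaps, not only the last.* A patient late for her second injection
  was already non-persistent at 12 months, so the 24-month flag requires
  every gap among injections 1–4 in window, not only the third-to-fourth
  gap. The alternative (conditioning only on the final gap) can be
  recovered by classifying with `required_injections = 2` on a history
  truncated to the last two injections, but is deliberately not the
  default.

**Adherence.** Every consecutive gap inside `[183 - 28, 183 + 28]`,
inclusive — a two-sided band motivated by the drug's pharmacokinetic
coverage. Whenever the adherence tolerance does not exceed the
persistence allowance (defaults: 28 &le; 56), adherence implies
persistence; the test suite asserts this as a property.

**Medication coverage ratio.** Each injection covers 183 days; the MCR is
the length of the union of `[d, d + 183)` over injection days `d`,
intersected with `[0, T)`, as a percentage of `T = min(731, observation
end)`. Computing a union (not a sum) caps the MCR at 100 even under early
re-injection. Two decisions:

- *Denominator.* `min(731, observation_end_day)`: completers are measured
  against the full 24 months, early withdrawals against their actual
  observation time. The source definition does not say which was used;
  using actual observation time avoids penalizing withdrawal with
  mechanically zero coverage.
- *Extra injections.* Injections beyond the fourth contribute coverage but
  are ignored by the persistence/adherence flags, which are defined on the
  scheduled four.

The implementation is a linear sweep over sorted injection days; the test
suite checks it against a brute-force day-enumeration oracle on 1,000
random histories (equality within `1/T`).

**Proportion summaries.** Reported as `n/N (%)` with the percentage
rounded to one decimal *at the reporting boundary only*; internal values
keep full precision. The 95% CI is the Wilson score interval — the CI
method behind the reference figures is unstated, and Wilson is
well-behaved near 0 and 1 where treatment-persistence proportions live; a
Wald interval is available via `method = "wald"` for comparability.

**Sensitivity grid.** Persistence is recomputed at allowances of +4, +6,
+8, +12 weeks and adherence at tolerances of ±4, ±6, ±8, ±12 weeks. By
set inclusion each proportion is non-decreasing in its window; the tests
assert this on a 5,000-patient heavy-tail cohort.

**MMAS-8.** Only the score-to-category rule is implemented: 8 → high,
6–7 → medium, < 6 → low; scores outside [0, 8] are validation errors.

## Stepwise logistic model

Per country stratum, 24-month persistence is regressed on baseline
covariates with alternating forward/backward stepwise selection:

- **Entry**: among candidates not in the model, the smallest p-value
  enters if &le; 0.25 (ties broken by candidate order, making the
  procedure deterministic).
- **Stay**: the largest in-model p-value is removed if > 0.30.
- **Test statistic**: the source names only thresholds, not a statistic.
  Entry/stay use the likelihood-ratio test (standard for stepwise
  selection, and exact for the multi-df block case); per-covariate
  significance and OR confidence intervals in the final model use Wald
  statistics, matching conventional forest-plot reporting. Wald
  entry/stay is available via `test = "wald"`.
- **Blocks**: a multi-level factor (e.g. age group `<65`, `65-<75`,
  `>=75`) enters and leaves as one block with a multi-df test; reference
  levels are the first factor level (the "No"/youngest categories).
- **Complete cases ("N1")**: recomputed iteratively — each entry test uses
  patients complete for the selected set plus the candidate, and the
  reported N1 is the complete-case count for the final selected set.
  Explicit levels such as `"n/a"` or `"missing"` count as data when the
  covariate declares them as categories; only true `NA` is missing. A
  simpler fixed-denominator variant (`complete_case = "fixed"`) restricts
  once to patients complete for every candidate.
- **Termination**: with entry threshold 0.25 below stay threshold 0.30 the
  usual argument for termination holds, but pathological configurations
  (user-supplied inverted thresholds, collinear candidates) can cycle. A
  step limit of `2 * K^2 + 2` plus a visited-model-set check guarantees
  termination; on a detected cycle the best model seen by per-observation
  log-likelihood is returned (per-observation, because the iterative N1
  rule means successive models need not share an observation count).
- **Failure modes**: a constant outcome, a rank-deficient design, and
  (quasi-)complete separation raise explicit errors; a candidate causing
  separation or degenerate on its complete cases is skipped for that step
  rather than silently entered with a huge coefficient. The fit itself is
  IRLS (convergence `1e-8`, at most 100 iterations).

The per-level report (`table2_report()`) gives `n/N1 (%)` for every level
of each selected covariate with significance stars from the final model's
Wald p-values (`*` &le; 0.05, `**` &le; 0.01, `***` &le; 0.001);
reference levels are never starred.

## The synthetic cohort generator

The generator encodes the observed study design as its stated world:
~1,500 patients in four country strata (fractions 579/300/299/301 of
1,479), a first injection at day 0, up to four injections, a 731-day
window, and baseline covariate prevalences in the range of the observed
baseline table (e.g. recent fall 18%, any chronic condition 83%, current
smoker 12%, MMAS-8 mean 6.7).

**Continuation model.** Discontinuation is a discrete hazard: before each
scheduled injection `k = 2..4` the patient continues with probability
`plogis(b0 + x'beta)`; once she stops, no further injections occur. The
default `b0 = qlogis(0.93)` gives a baseline 24-month all-four rate of
`0.93^3 ≈ 0.80`, inside the observed 75.1–86.0% persistence range, and
per-step effects remain interpretable as odds ratios. For a single binary
covariate with default jitter, persistence is *exactly* "all three
continuation draws succeed", so the induced 24-month odds ratio has a
closed form the tests use as truth. Default effects: recent fall OR 0.6,
above-median comorbidity OR 0.8, immobility OR 0.6, age &ge; 75 OR 0.75,
prior-therapy failure OR 1.3 per step.

**Gap jitter.** Received injections are delayed by a draw from a
truncated normal (mean 0, sd 10 days, truncated to [−28, +56]) around the
183-day schedule — so a continuing patient is always persistent and
usually adherent, and non-persistence is attributable to discontinuation.
No distributional information on real gap lengths exists; these values
are stipulated, not data-derived. The `late_mixture` family adds a
uniform [57, 120]-day late component with probability 0.15, creating
continuing-but-non-persistent patients so window-sensitivity behavior can
be tested. Gaps are truncated below at 1 day; an injection falling after
day 731 is not recorded (the visit never happens inside the observation
window), which only matters under the heavy-tail option.

**Reproducibility.** One global seed drives a per-patient substream
(`seed * 48271 + patient index`, mod 2^31 − 1), so identical configs give
identical cohorts and re-ordering patients does not perturb one another's
draws.

**What a green test does not establish.** The generator has no mortality,
no primary non-adherence (never-starters), no switching or re-initiation
episodes, no within-country site effects, and covariates are drawn
independently (no age–comorbidity correlation). Green property tests
establish that the *pipeline* is correct under the stated world, not that
the stated world matches any real population.

## Acceptance testing

Because the underlying patient-level data are unavailable, acceptance
combines (1) exact worked-example arithmetic on printed counts
(`70/101 → 69.3%`, `32/1480 → 2.2%`, …), (2) oracle equivalence (day-grid
MCR; the 2×2 cross-product odds ratio `(70·111)/(31·341)` recovered by
the logistic fit to `1e-6`), (3) window monotonicity on a heavy-tail
cohort, (4) parameter recovery — 200 replicates at n = 2,000 with a
per-step OR 0.4 covariate and a null covariate: the mean estimated OR is
compared with the closed-form induced OR within 2 Monte-Carlo standard
errors, the strong covariate must be selected in &ge; 99% of replicates,
and the null covariate's entry rate is compared with the ≈ 25% implied by
the 0.25 entry threshold — and (5) byte-identical fixed-seed pipeline
runs. The recovery comparison is made on the odds-ratio scale; on the
log-odds scale the mean estimate carries the logistic MLE's well-known
small O(1/n) away-from-zero bias, which at these settings sits near the
edge of a 2-SE band.

## Known limitations

- Proportion CIs and the stepwise test statistic are reasoned choices,
  not reproductions of the (unstated) original software's methods; both
  offer the obvious alternative behind a flag.
- The MCR denominator convention for early withdrawals is a documented
  choice (actual observation time), since the source is silent.
- No multiple-testing correction across strata, no imputation, no
  penalized alternatives — matching the scope of the analysis being
  implemented, not a recommendation.
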