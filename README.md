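# dosegap

Medication-taking analysis for long-acting injectable therapy: persistence,
adherence, and the medication coverage ratio (MCR) for 6-monthly
subcutaneous osteoporosis treatment, plus country-stratified stepwise
logistic regression of the baseline factors associated with staying on
therapy over 24 months.

## The problem

Osteoporosis therapy only prevents fractures while it is taken. For oral
bisphosphonates, fewer than a third of patients remain on treatment after
two years; 6-monthly injectables change the picture, but quantifying
medication-taking behavior for an injectable requires gap-based
definitions rather than refill counts:

- **Persistence** — the next injection arrives within a permissible gap of
  the previous one: gap &le; 183 + 56 days (6 months + 8 weeks). A patient
  is persistent at 24 months when all four scheduled injections satisfy
  this, i.e. for injections at days `t1 < t2 < t3 < t4`,
  `t_{k+1} - t_k <= 239` for k = 1..3.
- **Adherence** — the stricter two-sided criterion
  `|t_{k+1} - t_k - 183| <= 28` (6 months &plusmn; 4 weeks), motivated by
  the drug's pharmacokinetic coverage window.
- **MCR** — each injection covers 183 days; the MCR is
  `100 * |union of [t_k, t_k + 183) ∩ [0, T)| / T` with
  `T = min(731, observation end)`. The interval union means early
  re-injection never double-counts coverage. It is the injectable analogue
  of the medication possession ratio.

Baseline factors associated with 24-month persistence are explored per
country with stepwise multivariable logistic regression: a covariate
enters the model when its likelihood-ratio p-value is &le; 0.25 and stays
while its p-value is &le; 0.3; final-model effects are reported as Wald
odds ratios with 95% CIs, significant at p &le; 0.05. Multi-level
covariates enter and leave as one block. The complete-case denominator
("N1") is recomputed for the currently selected covariate set.

Because patient-level data of this kind cannot be shared, the package
includes a discrete-hazard cohort simulator: before each scheduled
injection, continuation is a Bernoulli draw with probability
`plogis(b0 + x' beta)`, received injections are jittered around the
183-day schedule, and every stage of the pipeline is testable end to end
with known truth.

## Worked example

```r
library(dosegap)

# One patient: injections at days 0, 190, 378, 560; followed 731 days
h <- injection_history("patient-007",
                       injection_days = c(0, 190, 378, 560),
                       observation_end_day = 731)
classify_persistence(h)   # TRUE  (every gap <= 239 days)
classify_adherence(h)     # TRUE  (every gap within 183 +/- 28)
round(compute_mcr(h), 1)  # 98.4  (% of 731 days covered)

# n/N (%) summary with a Wilson 95% CI
summarize_proportion(70, 101)
#>   n_success n_total proportion_percent ci95_low ci95_high
#> 1        70     101               69.3     59.7      77.5

# A synthetic 1500-patient cohort with known effects, and its analysis
cohort   <- generate_cohort(default_simulation_config(n_patients = 1500,
                                                      seed = 1))
outcomes <- patient_outcomes(cohort)
summarize_proportion(sum(outcomes$persistent_24m), nrow(outcomes))
#>   n_success n_total proportion_percent ci95_low ci95_high
#> 1      1175    1500               78.3     76.2      80.3

stepwise_select(outcomes$persistent_24m, cohort$covariates,
                c("fall_12m", "mwci_gt_median", "immobility_12m",
                  "age_group", "reason_failed_prior", "smoking"))
#> <stepwise_result> 4 selected of 6 candidate(s); N1 = 1500
#> selected: fall_12m, age_group, reason_failed_prior, immobility_12m
#>                      term           covariate log_odds odds_ratio ci_low
#> 1            fall_12mTRUE            fall_12m   -0.633       0.53   0.39
#> 2         age_group65-<75           age_group   -0.278       0.76   0.54
#> 3           age_group>=75           age_group   -0.504       0.60   0.43
#> 4 reason_failed_priorTRUE reason_failed_prior    0.183       1.20   0.91
#> 5      immobility_12mTRUE      immobility_12m   -0.294       0.75   0.48
#>   ci_high  p_value significant
#> 1    0.72 4.03e-05        TRUE
#> ...
```

The per-patient 24-month persistence rate (78.3%) is the share of patients
who received all four injections with every gap inside the 239-day window;
the simulator's generating model (recent fall, older age, immobility
lowering per-step continuation odds; prior-therapy failure raising them)
is what the stepwise model recovers, with `fall_12m` (OR 0.53) and age
&ge; 75 (OR 0.60) significant at p &le; 0.05.

The full pipeline — simulate (or read delimited cohort files), classify,
summarize by stratum, sensitivity-window grid, per-stratum stepwise models
— runs as one call (`run_pipeline(run_config(...))`) or from the command
line:

```sh
Rscript inst/scripts/dosegap run --out-dir out/ --seed 1 --n-patients 1500
Rscript inst/scripts/dosegap validate --input cohort_dir/   # exit 2 on violations
```

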