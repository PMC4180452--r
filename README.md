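# lifeyears

Life-expectancy estimates for older adults from a 12-item mortality point
score, via the Gompertz law of mortality.

Mortality-risk indexes tell a clinician "28% chance of dying within 4
years"; guidelines for preventive interventions (cancer screening, intensive
blood-pressure control) are instead phrased against the patient's *remaining
life expectancy*. `lifeyears` bridges the two for community-dwelling adults
aged 50 and over: it scores the 12 Lee-index items (age band, sex, diabetes,
cancer, lung disease, heart failure, BMI < 25, current smoking, and four
functional limitations) into 15 risk groups (0–13 and 14+ points), models
each group's survival with a shared-shape Gompertz proportional-hazards
model, and reports median life expectancy with confidence and prediction
intervals.

## The model

Each risk group `g` is treated as a subpopulation whose hazard grows
exponentially after baseline, per the Gompertz law:

    h_g(t) = λ_g · exp(γ t),   λ_g = exp(β₀ + β_g)

with one shared shape γ (1/years; ln 2 / γ is the hazard-doubling time) and
a categorical proportional-hazards effect of the risk group. Survival is
S_g(t) = exp(−(λ_g/γ)(e^{γt} − 1)), and the time to mortality fraction p is
the closed-form inverse

    t_p = (1/γ) · ln(1 − (γ/λ_g) · ln(1 − p)).

The model is fitted to right-censored follow-up by maximum likelihood
(profile likelihood in γ; per-group rates are closed-form given γ), or
*reconstructed* from a published quantile table when microdata are
unavailable: the (t25, median) pair of every group constrains γ through a
rate-free quantile-ratio equation, and rates follow exactly from the
medians. Diagnostics cover Kaplan–Meier comparison curves, Harrell's
concordance, fixed-horizon Hosmer–Lemeshow calibration, and AIC/BIC
comparison against Weibull and exponential alternatives. A synthetic-cohort
generator with the published cohort compositions provides ground truth for
every statistical claim in the test suite.

## Worked example

Score a 77-year-old man with heart failure who has difficulty walking
several blocks:

```r
library(lifeyears)

patient <- data.frame(
  age_years = 77, male = TRUE, diabetes = FALSE, cancer = FALSE,
  lung_disease = FALSE, heart_failure = TRUE, bmi_under_25 = FALSE,
  current_smoker = FALSE, difficulty_bathing = FALSE,
  difficulty_finances = FALSE, difficulty_walking_blocks = TRUE,
  difficulty_push_pull = FALSE)
score_profiles(patient)[, c("age_years", "points", "group")]
#> # A tibble: 1 × 3
#>   age_years points group
#>       <dbl>  <int> <fct>
#> 1        77     10 10
```

Age 75–79 contributes 4 points, male sex 2, heart failure 2, difficulty
walking 2: 10 points. The published quantile table bundled with the package
re-calibrates the full model without microdata:

```r
fit <- reconstruct_gompertz(published_le_quantiles())
round(fit$shape, 4)              # shared shape: hazard doubles every ~6.2 y
#> [1] 0.1123
predict_life_expectancy(fit, groups = "10")
#> # A tibble: 1 × 5
#>   group   t25   t50   t75 extrapolated
#>   <fct> <dbl> <dbl> <dbl> <lgl>
#> 1 10     3.77   7.3  11.3 TRUE
```

His predicted median life expectancy is 7.3 years; a quarter of similar
patients die within 3.8 years and a quarter survive past 11.3 (flagged
`extrapolated` because that exceeds the 10-year follow-up the model was
validated on). With individual-level data (here a synthetic cohort with the
published development-cohort composition), the full table adds bootstrap
95% CIs on each quantile and a 50% prediction interval for an individual's
survival time:

```r
cohort <- sample_cohort(hrs_cohort_spec("development"), seed = 2024)
tab <- life_expectancy_table(cohort, B = 200, seed = 2024)
dplyr::select(tab, group, t50, t50_low, t50_high, pi_low, pi_high)
#> # A tibble: 15 × 6
#>    group   t50 t50_low t50_high pi_low pi_high
#>    <fct> <dbl>   <dbl>    <dbl>  <dbl>   <dbl>
#>  1 0     33.6    30.6     38.1   26.3    40.2
#>  2 1     32.7    29.7     36.9   25.5    39.1
#>  3 2     30.9    28.4     33.7   23.4    37.1
#> #  ... 15 rows; medians fall monotonically to 3.7 y for the 14+ group
glance(fit_parametric(cohort))
#> # A tibble: 1 × 10
#>   family   shape  logLik    AIC    BIC    df  nobs n_events converged source
#>   <chr>    <dbl>   <dbl>  <dbl>  <dbl> <int> <int>    <int> <lgl>     <chr>
#> 1 gompertz 0.114 -11457. 22945. 23063.    16 11701     3052 TRUE      mle
```

`validate_fit()` returns Harrell's c, Hosmer–Lemeshow tests per horizon and
predicted-vs-observed curve data (`autoplot()` draws them); `tidy()` and
`glance()` give broom-style summaries of any fit. A command-line wrapper
with `score`, `simulate`, `fit`, `predict`, `validate` and `recalibrate`
subcommands is installed at
`system.file("cli", "lifeyears", package = "lifeyears")`.

## Scope

The package estimates survival quantiles (median LE), not mean residual
life; it does not handle left truncation, interval censoring, competing
risks, survey weights, or access to the restricted HRS/ELSA microdata.
Estimates are calibrated to the US cohort the point score was developed in —
external cohorts with different baseline mortality need re-calibration via
`reconstruct_gompertz()` on their own quantile table (the English validation
cohort's lower mortality is the canonical example).
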