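---
title: "From mortality points to life expectancy: the Gompertz model behind lifeyears"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From mortality points to life expectancy: the Gompertz model behind lifeyears}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifeyears)
library(dplyr)
```

## The problem

Mortality-risk indexes for older adults answer "what is this person's chance
of dying within x years?", but clinical guidance for preventive interventions
is phrased in terms of *life expectancy* (LE): screen when the patient's
remaining LE exceeds the intervention's lag time to benefit. `lifeyears`
converts a 12-item mortality point score for community-dwelling adults aged
50+ (age band, sex, five comorbidity/behaviour items, four functional items;
0–26 points, collapsed into the 15 risk groups 0, 1, ..., 13, 14+) into
median life expectancy and survival quantiles per risk group, with the
uncertainty statements a clinician needs.

## The model

Adult mortality hazards grow exponentially with age (the Gompertz law of
mortality: the death rate doubles over a fixed interval, empirically about
every 7–9 years in developed-world populations). Treating each risk-point
group as a subpopulation, the hazard of group $g$ at $t$ years after baseline
is

$$h_g(t) = \lambda_g e^{\gamma t}, \qquad \lambda_g = e^{\beta_0 + \beta_g},$$

a proportional-hazards model with one shared shape $\gamma$ (1/years) and a
categorical effect of the risk group on the rate (14 log hazard ratios
against the 0-point group). Cumulative hazard and survival are closed-form,

$$H_g(t) = \frac{\lambda_g}{\gamma}\left(e^{\gamma t} - 1\right), \qquad
  S_g(t) = e^{-H_g(t)},$$

and so is the time at which mortality reaches a fraction $p$:

$$t_p = \frac{1}{\gamma}\ln\!\left(1 - \frac{\gamma}{\lambda_g}\ln(1-p)\right).$$

$t_{0.5}$ is the group's median LE; $t_{0.25}$ and $t_{0.75}$ bracket the
central half of individual experience. The exponential distribution is the
$\gamma \to 0$ limit; all code paths take that limit through series branches
(`expm1`/`log1p` with explicit small-argument expansions) rather than by
thresholding formulas that cancel catastrophically.

The key structural assumption is that exponential hazard growth estimated
within the observed follow-up (about 10 years) continues beyond it; medians
of the low-risk groups are 20–35 years, i.e. strong extrapolations, and every
output flags quantiles beyond the validated horizon as `extrapolated`.

## Fitting

With right censoring, the log-likelihood is

$$\ell = \sum_{\text{deaths}} \left[\ln \lambda_{g_i} + \gamma t_i\right]
  - \sum_{\text{all}} \frac{\lambda_{g_i}}{\gamma}\left(e^{\gamma t_i}-1\right).$$

Because the covariate is categorical, the rate MLEs given $\gamma$ are
closed-form — deaths over "generalised exposure",
$\hat\lambda_g(\gamma) = d_g / \sum_{i \in g} t_i \,\phi(\gamma t_i)$ with
$\phi(x) = (e^x - 1)/x$ — so `fit_parametric()` maximises the resulting
one-dimensional profile likelihood in $\gamma$ on a fixed bracket
($[-1, 1.5]$ per year, i.e. hazard-doubling times from about six months up,
far wider than any human population) with `optimize()` at tolerance 1e-10.
This is deterministic, has no starting-value sensitivity, and agrees with a
general-purpose Gompertz regression fit to machine precision (checked in the
test suite against an independent implementation). The shape's standard
error comes from the profile-likelihood curvature. Design notes:

* $\gamma$ is unconstrained; a negative estimate (decaying hazard) is legal
  but warned about, because mortality then plateaus at $1 - e^{\lambda/\gamma}$
  and deeper quantiles do not exist (`gompertz_quantile()` raises a
  "plateau" error rather than returning a number).
* Deaths recorded at exactly $t = 0$ are offset by half a day (0.0014 y) so
  the density term stays finite; the offset is logged.
* A group with exposure but no observed deaths keeps rate 0 with a warning;
  its quantiles are `Inf` rather than a guess.
* Weibull (proportional-hazards form, $h = \lambda\alpha t^{\alpha-1}$) and
  exponential fits use the same profile machinery, and
  `compare_families()` ranks the three by AIC/BIC ($k$ counts the shape plus
  one rate per group: 16 parameters for the full 15-group Gompertz model).
  Gamma, log-logistic and log-normal families are out of scope here; with
  grouped categorical covariates the three implemented families are the ones
  whose profile structure is closed-form, and the published family
  comparison is qualitatively settled by Gompertz vs Weibull vs exponential.

## Uncertainty: confidence vs prediction intervals

`bootstrap_le()` resamples individuals with replacement (1000 replicates by
default, matching the published analysis; tests and examples use fewer) and
refits; `ci_from_bootstrap()` takes percentile intervals of each group's
quantiles. The published work says only "bootstrap methods" — percentile is
the simplest defensible reading and is recorded in the output metadata.
Failed replicates are dropped and counted, with a warning above 10%.

A 95% CI bounds the group's *population* median; an individual patient needs
a *prediction* interval. `prediction_interval()` pools, over bootstrap
replicates, `draws = 100` individual survival times simulated from each
replicate's fitted group distribution, and reports central quantiles (50% by
default) of the pool — sampling uncertainty and between-individual
variability combined. When all replicates coincide this collapses to the
model's own $[t_{25}, t_{75}]$, which is also its lower bound in width up to
Monte-Carlo error; the construction used for the published intervals was not
fully specified, so only such qualitative behaviour is asserted in tests.

## Re-calibration from published quantile tables

Where only a published quantile table is available (the intended
re-calibration route for new populations), `reconstruct_gompertz()` recovers
the model: each group's $(t_{25}, t_{50})$ pair constrains the shared shape
through the rate-free ratio equation

$$\frac{e^{\gamma t_{50}} - 1}{e^{\gamma t_{25}} - 1}
  = \frac{\ln 0.5}{\ln 0.75} \approx 2.4094,$$

and $\gamma$ is chosen by least squares on the log of this ratio across all
supplied groups — each group weighted equally on that scale, so the
heavily-rounded short-time rows of the top groups do not dominate. Rates
then follow exactly from the medians,
$\lambda_g = \gamma \ln 2 / (e^{\gamma t_{50,g}} - 1)$. On a noiseless table
generated from a true shared-shape model the reconstruction is exact; on the
bundled published table it gives $\gamma \approx 0.1123$ per year (hazard
doubling every $\ln 2/\gamma \approx 6.2$ years) and reproduces every
published time-to-75%-mortality within 0.11 years:

```{r reconstruction}
fit <- reconstruct_gompertz(published_le_quantiles())
fit$shape
predict_life_expectancy(fit)
```

## Validation diagnostics

`validate_fit()` bundles the standard checks:

* **Kaplan–Meier curves** (`km_curves()`, via the survival package) against
  the model's predicted curves, exported in long format by
  `export_curves()` and drawn by `autoplot()`.
* **Harrell's c** (`harrells_c()`): over usable pairs (the shorter follow-up
  ends in death; a death tied in time with a censoring is usable, two tied
  deaths are not), the fraction where the higher point score dies first,
  score ties counting 1/2. The point score itself is the predictor — any
  monotone transform, such as predicted LE with reversed sign, gives the
  same value. The implementation sweeps event times with per-score-level
  tallies ($O(n \log n)$ given the 15 score levels) and is tested against
  exhaustive pair enumeration.
* **Hosmer–Lemeshow at fixed horizons** (`hosmer_lemeshow()`): per group,
  observed deaths by horizon $h$ are $n_g(1 - \hat S_{KM,g}(h))$ — the KM
  estimate respects censoring — and expected deaths are
  $n_g(1 - S_{model,g}(h))$, compared by
  $X^2 = \sum_g (O_g - E_g)^2 / (E_g(1 - E_g/n_g))$ on $G-2$ degrees of
  freedom when the model was fitted to the same cohort and $G$ when it is
  external to it. The exact variant behind the published p-values is not
  stated anywhere we can check, so results are method-consistent rather than
  bit-identical; groups with expected deaths below 1 are merged into their
  lower-risk neighbour with a warning. Under the external-model null this
  statistic holds its size (rejection rate ≈ α in the test suite's
  simulations), and halving all rates is detected at p < 0.001 essentially
  always at realistic cohort sizes.

## The synthetic-cohort generator

Real HRS/ELSA microdata are access-restricted, so `sample_cohort()` provides
cohorts with known truth. `hrs_cohort_spec()` carries the published
composition: exact per-group counts (development n = 11701, validation
n = 8009, ELSA n = 7042), the reconstructed group-level Gompertz model as
the default truth, and administrative censoring at the published follow-up
(10 years for HRS, 8 for ELSA). Survival times are inverse-CDF draws;
optional uniform-(0, horizon) dropout (off by default) adds
non-administrative censoring. All randomness flows from one integer seed.

Two things the generator deliberately does *not* emulate: survey weights and
household clustering, and any within-group heterogeneity — every subject in
a group shares the group's exact hazard. The latter matters for
interpretation: on such model-perfect cohorts the point score discriminates
*better* than on real data (simulated development-cohort Harrell's c ≈ 0.82
vs 0.79 observed on the real cohort), so passing discrimination tests here
demonstrates correctness of the machinery, not real-world performance. The
factor-level mode (`mode = "factor"`) draws the 12 items independently from
published marginal prevalences and scores them; since only marginals are
matched, the joint score distribution differs from the printed one, and
score-level mode is the default everywhere.

## Problem sizes and numerical choices

Defaults mirror the published analysis (B = 1000 bootstrap replicates,
10-year horizon, 15 groups). The test suite exercises the same machinery at
reduced sizes chosen as the smallest that leave the statistical properties
clearly visible: bootstraps of 40–80 replicates on cohorts of 1500–6000 for
interval behaviour, 50 replicates of n = 10000–20000 for parameter recovery
and family selection, 400 replicates of n = 8009 for the calibration test's
size. Two honest limits of model-perfect simulation at these sizes are
documented above and asserted as such in the tests: simulated discrimination
sits ~0.03 above the published c, and group medians that extrapolate 3–4×
beyond the censoring horizon carry sampling errors above 5% at n = 20000.

Tie-break and degenerate-input conventions are centralised: censorings tied
with a death remain at risk for it (KM) and are usable comparators for it
(concordance); all-censored cohorts are a likelihood error, not a silent
zero; quantile requests outside a decaying hazard's attainable range raise a
plateau error; point scores of 14 or more pool into the `"14+"` group both in
scoring and when cohort files supply `points` instead of `group`.
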