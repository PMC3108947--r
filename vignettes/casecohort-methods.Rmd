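---
title: "Case-cohort risk prediction: models, weights and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case-cohort risk prediction: models, weights and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cchpredict)
```

## The problem

Population-based cohorts of ten thousand or more participants make it
prohibitively expensive to assay a full biomarker panel on everyone. The
case-cohort design measures the panel on a random subcohort plus all
incident cases of the endpoints of interest. This package implements the
complete analysis chain for such a design with two endpoints — incident
type 2 diabetes and incident coronary events — and quantifies how much a
panel of 13 inflammation-related serum biomarkers adds to risk
prediction over basic (age, sex, survey) and cardiometabolic adjustment
sets.

## Weighted Cox model

`cch_cox()` maximizes the weighted log partial likelihood

$$\ell_w(\beta) = \sum_{i:\,\delta_i=1} w_i\Big[x_i'\beta -
\log \sum_{j \in R(t_i)} w_j e^{x_j'\beta}\Big]$$

with Breslow handling of tied failure times. Two classical risk-set
schemes are provided:

* **Prentice** (default): subcohort members are at risk over their full
  follow-up with weight 1; cases outside the subcohort enter the risk
  set only just before their own failure (entry at $t_i - \varepsilon$,
  $\varepsilon = 10^{-8}$ years). This is the standard pseudo-likelihood
  for case-cohort hazard estimation.
* **Barlow**: subcohort members carry the inverse sampling fraction
  $1/\alpha_s$ of their survey-by-sex stratum; a subcohort case's weight
  drops to 1 at its own failure (implemented by internal time
  splitting), and outside cases contribute their own risk set with
  weight 1.

Because the pseudo-likelihood is not a true likelihood, model-based
variances are invalid; `cch_cox()` reports the **robust sandwich
variance** built from per-subject weighted score residuals. With every
sampling fraction equal to 1 both schemes reduce to ordinary Cox
regression, and the fitter then agrees with a reference implementation
to machine precision (this is enforced in the test suite).

Newton-Raphson converges when the maximum absolute score drops below
1e-8 or the relative log-likelihood change falls below 1e-10, within 100
iterations. The linear predictor is recentred at its maximum before
exponentiation: without this, a single high-leverage biomarker outlier
(log-normal tails make standardized values of 30+ possible in bootstrap
resamples) makes the risk-set sums lose all precision. For the same
reason, delayed-entry rows are added to their single risk set by direct
lookup rather than as a difference of two prefix sums. Coefficients
whose magnitude escapes beyond 20 on the model's standardized scale are
reported as monotone-likelihood failures (complete separation) rather
than returned.

## Weight conventions

Three distinct weightings coexist and are easy to conflate:

1. **Risk-set weights** (above) — used only inside the partial
   likelihood.
2. **Cohort-representative analysis weights** (`weight` column of the
   sample): every case has inclusion probability 1 and gets weight 1;
   subcohort non-cases get $1/\alpha_s$. These drive the weighted
   Kaplan-Meier, the descriptive statistics by case status, and the
   discrimination measures.
3. **Subcohort design weights** $1/\alpha_s$ for every subcohort member
   — the subcohort alone is a stratified random sample of the cohort,
   so these are used where a cohort-representative *sub*sample is
   needed: the z-transform moments and the Spearman correlation matrix.

The z-transformation standardizes each biomarker by the weighted
subcohort mean and SD (n−1 denominator), so hazard ratios are per 1 SD
and comparable across biomarkers regardless of unit; the scaling is
stored in the fit and reapplied to new data at prediction time.

## Absolute risk and discrimination at 10 years

Ten-year risk is $p_i = 1 - \exp(-H_0(10)\,e^{x_i'\beta})$ with $H_0$
the weighted Breslow baseline cumulative hazard at the mean-covariate,
reference-category profile. Model accuracy is compared by four measures,
all computed under combined design × IPCW weights:

* **AUC(τ)**: the probability that a subject with an event by τ = 10
  years receives a higher predicted risk than an event-free subject.
  Censoring is handled by inverse-probability-of-censoring weighting:
  the censoring distribution $G$ is estimated by weighted Kaplan-Meier
  with the roles of event and censoring exchanged; subjects with an
  event by τ weigh $1/G(T^-)$, subjects event-free past τ weigh
  $1/G(\tau)$, and subjects censored before τ (horizon status
  unobservable) weigh 0 rather than being imputed. The weighted
  Kaplan-Meier estimator itself is exposed (`weighted_km()`), so a
  KM-imputation variant of the horizon status could be added; under
  independent censoring the two approaches agree asymptotically. This
  is the package's one deliberate methodological commitment where
  "adjusting the AUC for censoring" admits more than one estimator, and
  it is therefore stated prominently here. Ties in predicted risk count
  1/2. The implementation is an O(n log n) rank sweep that the test
  suite holds to the O(n²) pairwise definition at 1e-12.
* **ΔAUC** between nested models on identical subjects and weights.
* **IDI**: difference of discrimination slopes (mean predicted risk in
  cases minus controls), interpretable as a difference in explained
  variation.
* **NRI** over the risk categories 0–3%, 3.1–8%, 8.1–15%, >15%
  (right-closed intervals, so exactly 3% falls in the lowest category,
  matching the printed labels at rounding resolution); sensitivity
  grids (2/5/10% and 5/10/20%) are built in. Reclassification tables by
  case status are returned alongside the index.
* **pseudo-ΔAIC** = AIC(old) − AIC(new) on the weighted likelihood with
  `|Δ| > 10` flagged "essential". It is meaningful only comparatively
  between models on the same sample.

## Bootstrap confidence intervals

`bootstrap_ci()` resamples subjects with replacement independently
within each case-status × stratum cell, preserving cell sizes — the
minimal scheme that respects both the all-cases rule and the stratified
subcohort. Design weights are recomputed on every replicate and the
statistic refits its models, so z-transform moments are re-estimated and
standardization uncertainty propagates into the interval. CIs are
empirical percentile intervals (type-7 quantiles); replicates that fail
(e.g. separation in a resample) are dropped and counted, with more than
5% failures treated as an error. The default is B = 999; B = 99 is used
as a fast mode where many intervals are computed in simulation studies.

## The synthetic cohort generator

No individual-level data ship with the package; `simulate_cohort()`
produces cohorts with the statistical structure the analysis assumes,
and its defaults are fixed study conditions, not tuning knobs:

* n = 13,427 subjects, three survey strata, half male, ages 25–74;
* 13 log-normal biomarkers with a mild positive exchangeable log-scale
  correlation (0.20) plus stronger biologically paired entries and a
  weakly negatively correlated adiponectin; log-normality is the
  minimal skewness model consistent with reporting geometric means with
  antilogged SEs;
* a latent adiposity factor loading on BMI and on leptin, CRP,
  sE-selectin (positive) and adiponectin (negative) with
  variance-preserving loadings, so the cardiometabolic model genuinely
  explains part of the biomarker signal;
* Weibull proportional-hazards endpoints with standardized hazard
  ratios spanning 0.33 (adiponectin-like protective) to about 1.7, and
  a shared normal frailty (SD 0.3) linking the two endpoints, since the
  two case sets arise in one overlapping population;
* the baseline Weibull scale is calibrated at simulation time (by root
  finding on the realized linear predictors) so the latent 10-year
  cumulative incidence hits the configured targets — 10% for diabetes,
  7% for coronary events — exactly by construction;
* censoring = administrative horizon 18.2 years minus a uniform 10-year
  entry stagger, plus exponential loss to follow-up at 0.034/year,
  chosen analytically so the mean follow-up is about 10.6 years;
* categorical covariates enter the hazard by dummy coding with the
  first listed level (never/none/no/low/female) as reference; survey
  has no hazard effect (no calendar-time trends are modelled).

What it does **not** emulate: assay measurement error, fasting status
effects, left truncation, competing risks, and non-proportional
hazards. Passing tests on these cohorts therefore demonstrate that the
estimators are correct under the design's own assumptions — not that
real biomarker panels will show any particular increment.

## Pipeline and model registry

`run_full_analysis()` reproduces the full table structure per endpoint:
model a (age, sex, survey), b (a + 13 biomarkers), c (a +
cardiometabolic factors), d (c + 13 biomarkers), per-biomarker single
additions under both adjustment sets, and a significant-subset panel
(biomarkers with robust-Wald p < 0.05 for their own coefficient in the
fully adjusted single-biomarker model). The cardiometabolic set is
endpoint-specific: parental diabetes for the diabetes endpoint versus
parental myocardial infarction plus prevalent diabetes for the coronary
endpoint. `sensitivity_suite()` re-runs with biomarker exclusions
(e.g. dropping the four markers a multiplex assay would measure),
alternative NRI grids (re-scored on stored predictions without
refitting), and covariate substitutions such as waist circumference for
BMI.

One subcohort is drawn per design seed and shared by both endpoints:
subjects receive uniform random keys once, and each endpoint takes the
lowest-keyed eligible (non-prevalent) subjects per stratum — with equal
exclusion sets the subcohorts coincide exactly, mirroring a single
drawn subcohort used for both outcomes.

## Numerical and design choices

* Breslow ties everywhere (simplest consistent with the weighted
  likelihood); average ranks for Spearman ties.
* Two-sided Wald tests from robust SEs; significance at 0.05.
* Degenerate inputs fail loudly: constant covariates, non-positive
  times, missing analysis values, non-positive-definite correlation
  matrices (reported with the offending eigenvalue), fewer than two
  events, risk horizons beyond follow-up.
* Determinism: a cohort is bitwise reproducible from its seed; the
  pipeline writes byte-identical CSVs on re-runs with the same seeds.
* Problem sizes in the shipped simulation studies (cohorts of 4,000 to
  20,000 subjects, 30 to 200 replicates, B = 99 to 199 bootstrap
  replicates) were chosen to give Monte-Carlo error comfortably inside
  the asserted bounds.

## Known limitations

* The IPCW AUC assumes censoring independent of covariates within the
  weighted sample; covariate-dependent censoring would need a censoring
  model.
* The pseudo-AIC has no absolute interpretation under weighting.
* Prentice-scheme robust variances are mildly conservative in small
  subcohorts.
* The NRI inherits its known sensitivity to category placement; the
  alternative grids are provided for exactly that reason.
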