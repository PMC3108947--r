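# cchpredict

Incremental predictive value of biomarker panels in stratified
**case-cohort** survival studies.

In a case-cohort design, a random subcohort is drawn from a large
population-based cohort (here with survey- and sex-specific sampling
fractions) and all incident cases of each endpoint are added. Expensive
biomarker panels are then measured only on this subset. Valid analysis
has to undo the deliberate over-representation of cases: `cchpredict`
provides the whole chain for two endpoints (incident type 2 diabetes and
incident coronary events) —

* a seeded **synthetic cohort generator**: 13 mutually correlated,
  right-skewed (log-normal) inflammation-related biomarkers, seven
  cardiometabolic risk factors, and two Weibull proportional-hazards
  endpoints with staggered entry, administrative censoring at 18.2 years
  and loss to follow-up;
* **stratified subcohort sampling** with design weights
  (Horvitz–Thompson: cases weight 1, subcohort non-cases `1/alpha_s`),
  weighted descriptive statistics and Spearman correlation matrices;
* a **weighted Cox proportional-hazards fitter** (`cch_cox()`) with
  Prentice and Barlow risk-set schemes, Breslow ties, robust sandwich
  variance from per-subject score residuals, z-transformed (per-SD)
  hazard ratios, pseudo-AIC, and the Breslow baseline cumulative hazard
  for absolute 10-year risk;
* **censoring-adjusted discrimination measures** at a 10-year horizon:
  AUC(τ) with inverse-probability-of-censoring weights, ΔAUC, the
  integrated discrimination improvement (IDI), and the category-based net
  reclassification index (NRI, default categories 0–3%, 3.1–8%, 8.1–15%,
  >15%) with full reclassification tables;
* **design-aware bootstrap percentile confidence intervals** (resampling
  within case-status × stratum cells, refitting every model per
  replicate).

## The model

For subject *i* with covariate vector *x*, the hazard is
λ(t|x) = λ₀(t)·exp(x'β), fitted by maximizing the weighted log partial
likelihood

ℓ_w(β) = Σ_events w_i [ x_i'β − log Σ_{j∈R(t_i)} w_j exp(x_j'β) ],

with risk sets R(t) built per the case-cohort weighting scheme (under
Prentice, cases outside the subcohort enter only just before their own
failure). Ten-year risk is p_i = 1 − exp(−H₀(10)·exp(x_i'β)) with H₀ the
weighted Breslow baseline; discrimination between two nested models is
summarized by AUC(10), ΔAUC, IDI (difference of discrimination slopes)
and NRI, all computed with combined design × IPCW weights so that
subjects censored before the horizon do not bias the comparison.

## Worked example

```r
library(cchpredict)

cohort <- simulate_cohort(sim_config(n_subjects = 6000, seed = 11))
design <- sampling_design(fraction = 0.134, scheme = "prentice", seed = 2)
res <- run_full_analysis(cohort = cohort, design = design, verbose = FALSE)
print(res)
```

```
Case-cohort prediction analysis (tau = 10 years)

Endpoint: diabetes - 643 cases
 biomarker  auc1 delta_auc1  auc2 delta_auc2
      none 0.622         NA 0.759         NA
     all13 0.822      0.199 0.845     0.0859
    subset 0.820      0.198 0.843     0.0846

Endpoint: coronary - 500 cases
 biomarker  auc1 delta_auc1  auc2 delta_auc2
      none 0.721         NA 0.782         NA
     all13 0.752     0.0313 0.801     0.0186
    subset 0.748     0.0273 0.799     0.0167
```

Reading: `auc1` is the 10-year AUC with the basic adjustment (age, sex,
survey; row `none` is the basic model itself), `auc2` with the
cardiometabolic adjustment added. Row `all13` adds the full biomarker
panel, `subset` only the biomarkers individually significant after full
adjustment. On this synthetic cohort the panel raises the diabetes AUC
substantially over the basic model (ΔAUC ≈ 0.20) but much less over the
cardiometabolic model (ΔAUC ≈ 0.09), and least of all for coronary
events over the cardiometabolic model (ΔAUC ≈ 0.02) — the qualitative
pattern such panels show in practice. Single fits are available
directly:

```r
smp <- draw_subcohort(cohort, design, "diabetes")
fit <- cch_cox(smp, model_spec("m1", c("age", "sex", "survey", "adiponectin"),
                               z_terms = "adiponectin", endpoint = "diabetes"))
hazard_ratios(fit)       # HR per 1 SD, robust 95% CI, Wald p
predict(fit, smp, tau = 10)  # absolute 10-year risks
```

## Vignette

`vignettes/casecohort-methods.Rmd` documents the statistical model, the
weighting conventions, what the synthetic generator does and does not
emulate, and the package's numerical choices.
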