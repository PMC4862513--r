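# isavupk

Population pharmacokinetics of the antifungal **isavuconazole** in
subjects with mild or moderate hepatic impairment: a tested R
implementation of the published hepatic-impairment population model, its
Monte-Carlo steady-state simulations, and the estimation/validation
machinery around it.

Isavuconazole is cleared almost entirely by hepatic metabolism, so liver
disease lowers its clearance and raises exposure. The question the
underlying analysis answers is whether the labelled regimen (200 mg every
8 h for 2 days, then 200 mg once daily) needs adjustment in Child–Pugh A/B
impairment; the answer hinges on how much steady-state trough
concentrations rise.

## The model

Disposition is a linear two-compartment model (clearance CL, central
volume Vc, intercompartmental clearance Q, peripheral volume Vp) with
first-order elimination; intravenous doses enter as zero-order 2-h
infusions (exact bi-exponential solution) and oral doses through a
Weibull-type absorption function

    ka(t) = KAMAX * [1 - exp(-(RA * t)^GAM1)]

integrated numerically (compiled adaptive Runge–Kutta). The covariate
model sets CL and Q by hepatic group and scales Vp linearly in BMI:

    CL = {2540, 1550, 1326} ml/h   (healthy, mild, moderate)
    Q  = {33678, 38800, 63554} ml/h
    Vp = 410000 ml * [1 + 0.058 * (BMI - 27)]

with log-normal between-subject variability on all seven structural
parameters and additive residual error on the log scale. These reference
values ship as `theta_reference()` and as a flat YAML config in
`inst/extdata/`.

The package provides, per module:

* **Kinetic core** — `conc_iv_infusion()`, `conc_oral_weibull()`,
  `superpose()`, `steady_state_trough()`, `steady_state_profile()`,
  `regimen()` / `clinical_regimen()`.
* **Covariates** — `theta_table()` / `theta_reference()`,
  `typical_params()`, YAML round-trip via `read_theta()` / `write_theta()`.
* **Population simulation** — `sample_population()`, `simulate_regimen()`,
  `apply_residual_error()`, `trough_summary()`.
* **NCA** — `fit_lambda_z()`, `auc_last()`, `nca()`, `nca_dataset()`.
* **Estimation & validation** — `fit_individual()`, `fit_dataset()`,
  `two_stage_population()`, `stepwise_covariate_selection()`,
  `bootstrap_ci()`, `npde()`, with broom-style `tidy()`/`glance()`
  methods.
* **Synthetic studies** — `study_spec()`, `generate_cohort()`,
  `generate_study_dataset()` emulate the two phase-1 studies (96 matched
  subjects, 21 samples to 480 h) so everything runs without external
  data.
* **Plots** — `plot_profiles()`, `plot_troughs()`, `plot_npde()`.

See the methods vignette (`vignettes/isavuconazole-hepatic-poppk.Rmd`)
for the modelling decisions and their rationale.

## Worked example

Simulate 2,000 virtual healthy subjects and 2,000 with moderate
impairment under the clinical regimen and summarise steady-state troughs:

```r
library(isavupk)

theta <- theta_reference()
healthy  <- sample_population(theta, "healthy",  n = 2000, seed = 101)
moderate <- sample_population(theta, "moderate", n = 2000, seed = 103)

trough_summary(healthy, clinical_regimen())
#> # A tibble: 1 x 7
#>   hepatic_group     n  mean    sd median   min    max
#>   <chr>         <int> <dbl> <dbl>  <dbl> <dbl>  <dbl>
#> 1 healthy        2000 3148. 1545.  2885.  518. 13358.

trough_summary(moderate, clinical_regimen())
#> # A tibble: 1 x 7
#>   hepatic_group     n  mean    sd median   min    max
#>   <chr>         <int> <dbl> <dbl>  <dbl> <dbl>  <dbl>
#> 1 moderate       2000 6532. 3041.  5943. 1439. 23566.
```

The mean trough roughly doubles in moderate impairment (6,532 vs
3,148 ng/ml here, a 2.1-fold ratio) — the same order as the published
simulation (6,068 vs 3,500 ng/ml, 1.73-fold), whose healthy row sits ~10%
above what the published parameters reproduce; see the vignette for the
analysis of that discrepancy.

A single subject's profile and NCA:

```r
p <- typical_params(data.frame(hepatic_group = "moderate", bmi = 27))
times <- c(0.5, 1, 2, 3, 4, 6, 8, 10, 24, 48, 72, 96, 120, 144, 168,
           216, 288, 360, 432, 480)
prof <- data.frame(time = times, conc = conc_iv_infusion(p, 100, 2, times))
nca(prof)
#> # A tibble: 1 x 8
#>   lambda_z n_points_used adjusted_r2 auc_last auc_inf auc_pct_ext c_last t_last
#>      <dbl>         <int>       <dbl>    <dbl>   <dbl>       <dbl>  <dbl>  <dbl>
#> 1  0.00283             3           1     56.2    75.3        25.4   54.1    480
```

With 480-h sampling, a typical moderate-impairment subject leaves ~25% of
the AUC beyond the last sample (`auc_pct_ext` = 25.4) — the truncation
bias that motivated population modelling over NCA for these studies.

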