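# pbliv

Instrumental-variable estimation of the acute effect of **locally
generated air pollution on daily deaths**, using planetary boundary layer
(PBL) height and wind speed as instruments.

## The idea

Conventional time-series mortality regressions are associational: any
omitted predictor of daily deaths that co-varies with pollution biases
them. But local pollutant concentrations are partly driven by ventilation:
for the same emissions, concentrations rise when the boundary layer is
shallow (less vertical dilution) and winds are light (less horizontal
transport). Within month-by-year strata and temperature deciles, day-to-day
variation in PBL height and wind speed is an implausible direct cause of
death — so the meteorology-driven share of pollution variation is
effectively randomized with respect to behavioral and biological
confounders, measured or not.

With daily deaths $Y_t$, pollutant $A_t$, and instruments $Z_t$ (PBL and
wind at lags 0 and 1), the outcome model is
$\log E(Y_t) = \theta_0 + a\,\theta_1 + \Phi_t$ and the first stage is
$A_t = f(Z_t) + \eta_t$, estimated by radial-kernel support-vector
regression tuned by 10-fold cross-validated $R^2$. Regressing deaths on
the lag-averaged calibrated instrument in a stratified quasi-Poisson model
recovers $\theta_1$ even in the presence of unmeasured confounders, and is
reported as the percent change in daily deaths per interquartile-range
(IQR) increase, $100(e^{b_1 \cdot IQR} - 1)$.

The pipeline ships with:

- `generate_panel()` — a synthetic-city generator with a known causal
  effect and an explicit unmeasured-confounder pathway (naive regression
  is biased ~2x; the IV estimate is not), calibrated to realistic urban
  scales (≈56 deaths/day, PM2.5 ≈10 μg/m³, PBL ≈770 m);
- `assign_strata()` / `orthogonalize()` — month-by-year and
  temperature-decile stratification;
- `fit_instrument()` — the cross-fitted SVR first stage with a
  weak-instrument guard;
- `fit_iv_model()` / `subset_low_concentration()` — the quasi-Poisson
  second stage and the low-concentration (≤30 μg/m³) sensitivity analysis;
- `granger_test()` / `exclusion_test()` — falsification checks for omitted
  confounding (association with *future* exposure) and for violations of
  the exclusion restriction (association conditional on the pollutant);
- `attributable_deaths()` — health-impact translation
  $N\,(RR-1)/RR$;
- `run_pipeline()` and a thin CLI (`inst/scripts/pbliv`) orchestrating all
  stages with one seed.

## Worked example

```r
library(pbliv)

res <- run_pipeline(run_config(
  sim  = sim_config(n_days = 3652, seed = 1),   # ten-year synthetic city
  grid = svr_grid(cost = c(0.1, 1, 10), gamma = c(0.05, 0.25, 1)),
  seed = 1
))
res
#> <pipeline_result> pollutant: pm25
#>   first stage: CV R2 = 0.410 (training 0.434), IQR = 2.683
#>   IV:    1.41% per IQR (95% CI 0.92, 1.91)
#>   naive: 3.67% per IQR
#>   low-concentration subset: 0.77% per IQR
#>   Granger forward: -0.23% (p = 0.36); exclusion p = 0.00
#>   attributable deaths: 2838.4
res$truth$theta_per_iqr_true
#> [1] 0.9172383
```

Reading the output: the first stage predicts about 41% of the
stratum-residualized PM2.5 variance from PBL/wind, with training and
cross-validated R² close (no overfitting). The simulation's true effect is
0.92% per IQR; this replicate's IV estimate is 1.41% (the CI covers the
truth; across 200 seeded replicates the mean IV estimate is within
Monte-Carlo error of the truth), while the naive regression of deaths on
observed PM2.5 returns 3.67% — the unmeasured-confounder bias the
instrument removes. The Granger forward term is null (no evidence of
omitted confounding of the *instrument*). The exclusion p-value is small
here because this simulation has strong pollutant–mortality confounding,
which contaminates the mediator-conditioning test (see the methods
vignette); under full mediation it is calibrated.

The one computation whose inputs are fully printable — the attributable
burden for 204,386 deaths over ten years at a 0.90% increase per IQR:

```r
attributable_deaths(204386, 0.90)
#> <impact_estimate>
#>   RR per IQR = 1.00900, attributable fraction = 0.00892
#>   attributable deaths = 1823.1 of 204386 total
```

## Documentation

The methods vignette (`vignettes/methods.Rmd`) describes the model and its
assumptions, the first-stage cross-fitting rationale, the synthetic-city
generative equations and what they do and do not emulate, and the
validation protocol with its problem sizes.
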