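# ptarmiganRSF

Resource selection functions (RSF) for willow ptarmigan (*Lagopus lagopus*)
estimated from line-transect distance-sampling surveys.

Wildlife managers planning harvest quotas or habitat interventions in
Norwegian alpine areas need to know *which* habitat ptarmigan select in late
summer. Survey programmes walk systematically spaced transects (500-m grid
interval) with pointing dogs and record each bird encounter with its
perpendicular distance to the line. This package turns such data — or
faithful synthetic replicas of it — into a validated habitat-suitability
map, implementing every stage:

1. **Synthetic surveys** (`make_landscape()`, `layout_transects()`,
   `simulate_survey()`): spatially autocorrelated vegetation / elevation /
   timberline rasters, systematic transects, and observations generated with
   known selection coefficients, per-area density heterogeneity, and
   half-normal detection decay — so the whole pipeline is testable with a
   ground truth.
2. **Quality control** (`apply_qc()`): discard observations outside the
   200-m line-buffer and observations whose reported distance deviates more
   than 30 m from the geometric one, with a step-by-step accounting ledger.
3. **Detection-adjusted availability** (`generate_availability()`): 3
   uniform points per km of effort in each buffer, a half-normal detection
   function `g(d) = exp(-d²/2σ²)` fitted to the used distances, and
   rejection thinning (`keep iff P < g(d)`) so available points share the
   observations' distance distribution.
4. **Model fitting** (`fit_rsf()`): mixed-effects logistic regression of
   used vs. available locations with a random intercept per survey area;
   covariates are 16 vegetation classes, deviation from the regional
   timberline, slope, and aspect, standardized to zero mean / unit SD.
5. **Selection** (`candidate_set()`, `select_model()`): AIC over a
   24-model grid with the parsimony rule (ΔAIC < 2 ⇒ smallest K wins).
6. **Validation and mapping** (`cv_boyce()`, `spatial_block_cv()`,
   `map_rsf()`, `summarize_bin_coverage()`): 5-fold and leave-one-region-out
   cross-validation via Spearman correlation between 10-quantile RSF bin
   rank and used counts; raster-wide prediction
   `w(x) = exp(β₁x₁ + … + βₙxₙ)` scaled to (0, 1], binned 1 (low) to 10
   (high relative probability of selection).

The model core in standard notation: for location *x* with covariates
standardized as fitted,

```
logit P(used | x, area a) = α + β'x + b_a ,   b_a ~ N(0, σ²_area)
w(x) = exp(β'x)            (no intercepts: relative selection only)
```

## Worked example

```r
library(ptarmiganRSF)

cfg <- pipeline_config(seed = 1)   # default synthetic study conditions
out <- run_pipeline(cfg)           # ~1 min: 24 candidate models, 5-fold CV, map

out$ledger          # step-by-step accounting of every filtering action
out$detection       # fitted half-normal detection scale
out$selection       # AIC table over the candidate models
out$fit             # selected mixed logistic fit
out$cv$per_fold     # Spearman rho per cross-validation fold
out$coverage        # % of map / buffers / used locations per RSF bin
```

With seed 1 this prints:

```
> out$ledger
                                   action used surveys available transects areas
1                           Imported data 2789     148        NA        37     8
2          Removed used locations > 200 m 2787     148        NA        37     8
3 Removed used locations > 30-m deviation 2475     148        NA        37     8
4  Removed surveys without used locations 2475     148        NA        37     8
5              Generated random locations   NA      NA     11100        37     8
6               Adjusted random locations   NA      NA      4123        37     8
7     Removed non-habitat (final dataset) 2475      NA      4077        NA    NA
> out$detection
half-normal detection: sigma = 59.61 m (n = 2475, logLik = -11899.86, truncated at 200 m)
> out$fit
Used-available mixed logistic fit (Vegetation + Timberline + Timberline^2 + Slope + Slope^2)
  n used = 2475, n available = 4077, K = 21, AIC = 7990.46
  random-intercept variance (survey area) = 0.1908
> out$cv$per_fold
 fold       rho      p_value
    1 0.9515152 2.279855e-05
    2 0.9419357 4.634781e-05
    3 0.9665698 5.248116e-06
    4 0.9240164 1.329527e-04
    5 0.9240164 1.329527e-04
```

Read: the deviation filter removed 312 of 2787 in-buffer observations
(reported distances carry 20-m error by design); the fitted detection scale
(59.6 m) matches the simulation truth (60 m); AIC over the 24-model grid
selects the parsimonious structure (vegetation + quadratic timberline
deviation + quadratic slope, K = 21, ΔAIC = 0); and every cross-validation
fold shows a strong positive rank correlation — used locations concentrate
in high-ranked RSF bins, i.e. the fitted map is predictive. The simulation
truth behind the default config is the published coefficient set, so
`out$fit$beta` can be compared term by term with
`truth_on_standardized_scale(cfg$truth, out$fit$std_params)`.

`recovery_experiment()` wraps this loop over many replicates and reports
per-coefficient bias, RMSE and CI coverage.

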