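# spadgdd

Phenology-aligned diagnosis of rice nitrogen status from multi-leaf SPAD
(chlorophyll meter) readings.

SPAD-based nitrogen diagnosis is confounded by crop development: leaf
greenness and tissue nitrogen both change nonlinearly over the season, so a
rule calibrated at one stage drifts at another. This package implements a
complete, testable pipeline that treats the problem as physiological
time alignment:

* **Thermal time.** Growing degree days from daily temperature extremes,
  `GDD = sum_d max(0, (Tmax_d + Tmin_d)/2 - Tbase)` with `Tbase = 10` C,
  accumulated from sowing to sampling.
* **Nitrogen indices.** The critical nitrogen dilution curve
  `Nc = 3.44 DM^-0.44` (% N, DM in t/ha) and the nitrogen nutrition index
  `NNI = PNC / Nc` (< 1 deficient, > 1 surplus).
* **Feature formulations.** SPAD at leaf positions LFT1-LFT5 (counted from
  the top of the canopy) combined with GDD four ways - SPAD only,
  SPAD x GDD products, additive SPAD + GDD, and additive plus products -
  plus seven field-protocol reductions down to `{one leaf, GDD}`.
* **Leakage-safe grouped cross-validation.** 10-fold splits by field
  experiment (no experiment in both training and validation), fold-local
  median imputation and standardisation, four model families (PLS, SVR,
  random forest, XGBoost) with fixed hyperparameters; R2 / RMSE / MAE per
  fold, summarised as mean +/- SD.
* **Phenology diagnostics.** Pearson correlation and OLS slope of pooled
  out-of-fold residuals against GDD, contrasted between formulations with
  and without explicit GDD terms.
* **Out-of-fold attribution.** Exact path-dependent TreeSHAP for tree
  ensembles (C++ kernel for random forests, xgboost's own contributions
  for boosted trees), global importance normalised to 100% per
  target-model combination, and per-sample mid-canopy shares
  (LFT2 + LFT3 + LFT4 = 100%).
* **Importance dynamics.** LOWESS smoothing (span 0.25, tricube, degree 1,
  220-point grid) of the shares along GDD, group-bootstrap confidence
  bands (800 replicates), and the LFT2-LFT3 crossover GDD with a bootstrap
  95% interval.
* **Synthetic study panel.** A 20-experiment field-trial generator with
  N-rate gradients, growth-linked N dilution, canopy-stratified leaf N
  status, stage-dependent leaf sensitivities with a configurable
  ground-truth importance crossover, and realistic LFT5 missingness - so
  the entire pipeline is exercisable and testable without field data.

## Worked example

```r
library(spadgdd)

# a synthetic multi-experiment panel (~1150 observations, 20 experiments)
ds  <- generate_dataset(generator_config())
obs <- ds$observations

# compare SPAD-only (A) against additive SPAD + GDD (C) for plant N
fmA <- build_formulation(obs, "A", target = "PNC")
fmC <- build_formulation(obs, "C", target = "PNC")
rf  <- model_spec("RF", seed = 42)
cvA <- run_grouped_cv(fmA, rf)
cvC <- run_grouped_cv(fmC, rf)
cvA
#> <spad_cv> formulation_A / PNC / RF: R2 0.351 +/- 0.086, RMSE 0.734, MAE 0.529 (10 folds)
cvC
#> <spad_cv> formulation_C / PNC / RF: R2 0.847 +/- 0.027, RMSE 0.354, MAE 0.262 (10 folds)

residual_trend(cvA)
#> <residual_trend> r = -0.652, slope = -1.12e-03 per C d (n = 1155)
residual_trend(cvC)
#> <residual_trend> r = -0.011, slope = -9.17e-06 per C d (n = 1155)
```

Adding GDD to the SPAD set raises out-of-fold R2 from 0.35 to 0.85 and
collapses the residual trend along thermal time: the SPAD-only model makes
stage-dependent directional errors (underpredicting early, overpredicting
late, r = -0.65), while the additive model's residuals are flat in GDD
(r = -0.01). The attribution stage then asks *which* leaves carry the
signal and when:

```r
at  <- oof_attributions(fmC, rf)
sh  <- midcanopy_shares(at)
dyn <- group_bootstrap(sh, dynamics_config(seed = 99))
dyn$crossover
#> <crossover_estimate> 1169.5 C d (95% CI 1084.8-1253.9; 800/800 replicates crossed)
```

the thermal time at which the smoothed LFT3 importance share overtakes the
LFT2 share, with its group-bootstrap confidence interval - on this panel
the generator's ground-truth crossover is 1100 C d, recovered within the
interval.

## Package layout

| Path | Contents |
| --- | --- |
| `R/thermal_time.R` | GDD computation and weather I/O |
| `R/nitrogen.R` | critical N dilution curve, NNI |
| `R/simulate.R` | synthetic multi-experiment generator |
| `R/features.R` | formulation and protocol feature sets |
| `R/models.R`, `R/cv.R` | model families, grouped CV engine |
| `R/diagnostics.R` | residual-vs-GDD trends |
| `R/attribution.R`, `src/treeshap.cpp` | out-of-fold TreeSHAP and normalisations |
| `R/dynamics.R` | LOWESS, group bootstrap, crossover |
| `R/pipeline.R` | observation schema, run config, orchestration |
| `vignettes/methods.Rmd` | models, assumptions, design choices |
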