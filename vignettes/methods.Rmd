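---
title: "Phenology-aligned SPAD nitrogen diagnosis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenology-aligned SPAD nitrogen diagnosis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Chlorophyll-meter (SPAD) readings are the workhorse of in-season rice
nitrogen diagnosis, but they conflate two signals: the crop's nitrogen
status and its developmental stage. Leaf greenness and tissue nitrogen both
change nonlinearly over the season (growth-linked N dilution, leaf ageing,
senescence-driven remobilisation), so a diagnostic rule calibrated at one
stage drifts at another. This package treats that drift as a physiological
time-alignment problem: express every observation on a thermal-time axis
(growing degree days, GDD) and let GDD enter the diagnostic model as an
explicit predictor alongside SPAD readings taken at several leaf positions
(LFT1, the newest fully expanded leaf, down to LFT5).

The package provides the full analysis chain:

1. **Thermal time** (`daily_gdd()`, `cumulative_gdd()`): daily increments
   `max(0, (Tmax + Tmin)/2 - Tbase)` with `Tbase = 10` C, summed from sowing
   to sampling with both endpoints included. The sowing-to-sampling window
   is inclusive on both ends; the convention is documented because
   published descriptions rarely state it, and a one-day difference is
   negligible against field-scale GDD (~10-25 C d per day). No upper
   temperature cutoff is applied, and GDD accumulates across transplanting
   without reset.
2. **Nitrogen indices** (`critical_n()`, `nni()`): the critical N dilution
   curve `Nc = 3.44 DM^-0.44` (% N, DM in t/ha) and the nitrogen nutrition
   index `NNI = PNC / Nc`. The bare power law is applied for all `DM > 0`;
   several CNDC frameworks clamp the curve below 1 t/ha, and that clamp is
   deliberately not applied here because the published curve is stated
   without it. Status labels use the exact threshold 1 (below: deficient,
   above: surplus), with equality mapped to optimal.
3. **Feature formulations** (`build_formulation()`): A = SPAD only,
   B = SPAD x GDD products, C = SPAD + GDD additive, D = B and C combined;
   and seven measurement protocols (`build_protocol()`) from the full
   six-feature set down to single-leaf `{LFTk, GDD}` sets.
4. **Grouped cross-validation** (`plan_group_folds()`, `run_grouped_cv()`):
   10-fold splits by experiment so that no field experiment contributes to
   both training and validation, with fold-local median imputation and
   (for PLS/SVR) fold-local standardisation.
5. **Diagnostics and interpretation** (`residual_trend()`,
   `oof_attributions()`, `midcanopy_shares()`, `group_bootstrap()`):
   residual-versus-GDD trends, out-of-fold Shapley attributions for tree
   ensembles, and LOWESS-smoothed mid-canopy importance dynamics with a
   group-bootstrap crossover estimate.

## Model families and fixed hyperparameters

Four families span the linear/nonlinear and single/ensemble axes: PLS
(latent-variable linear regression, 3 components by default, capped at the
feature count), SVR (radial basis kernel, `C = 10`, `epsilon = 0.1`,
`gamma = 1/(p Var(X))`), random forest (500 trees, fixed seed, all
features considered at every split - the regression-forest convention of
the scikit-learn lineage; with only 2-11 individually strong predictors,
restricting the per-split candidate set would starve the trees of the GDD
variable and flatten steep covariate trends) and
gradient-boosted trees (800 rounds, learning rate 0.05, depth 6, row and
column subsampling 0.8, L2 lambda 1, fixed seed). Hyperparameters are fixed
once and reused for every target and feature set, so that differences
between formulations reflect the features, not tuning. PLS and SVR are
scale-sensitive and are fitted on fold-standardised features; tree
ensembles see original scales.

PLS is fitted through mixOmics, SVR through e1071, forests through
randomForest and boosting through xgboost; the model layer only pins their
hyperparameters and seeds.

## Leakage control

All preprocessing is fitted on the training split of each fold only:
medians for imputation, means/SDs for standardisation. The attribution
engine reuses exactly the same preprocessing path, so cross-validated
predictions and out-of-fold attributions come from identical fold models.
Missing SPAD x GDD products are imputed as columns in their own right
rather than recomputed from an imputed SPAD value, which would fabricate a
product the model never saw.

## Out-of-fold attribution

For tree ensembles the package computes exact path-dependent Shapley
contributions (TreeSHAP): conditional expectations follow each tree's own
cover weights, with no background dataset, removing a free parameter that
the path-dependent dialect does not need. For random forests the kernel is
implemented in C++ (`src/treeshap.cpp`) and validated in the test suite
against brute-force subset enumeration and against xgboost's own
`predcontrib`, which is also the production route for boosted models. Node
cover for forests is obtained by routing the fold's training rows through
each tree; every attribution satisfies local accuracy (base value plus
contributions equals the model prediction) to numerical precision.

Global importance is the mean absolute contribution per feature, rescaled
to sum to 100% within a target-model combination. Per-sample mid-canopy
shares rescale `|LFT2| + |LFT3| + |LFT4|` to 100%; rows whose three
contributions are all exactly zero are dropped and counted rather than
assigned equal shares, which would fabricate importance.

## Importance dynamics and the crossover

Shares are smoothed along GDD with a pinned LOWESS dialect: degree-1 local
regression over the `ceil(0.25 n)` nearest rows, tricube weights, no
robustness iterations, evaluated on a 220-point equally spaced grid
spanning the observed GDD range. The span keeps roughly a stage-and-a-half
of data in each neighbourhood; robustness iterations are disabled because
they over-smooth genuine transitions. Duplicate GDD values share
neighbourhoods with ties broken by row order after a stable sort.
Uncertainty comes from resampling experiments (groups) with replacement,
800 replicates, re-smoothing each replicate on the same grid; attributions
are never recomputed inside the bootstrap. Pointwise bands and the
crossover interval use the 2.5th/97.5th percentiles. The LFT2-LFT3
crossover is the first zero or strict sign change of the difference curve,
linearly interpolated between grid points; replicates whose curves never
cross are excluded from the interval and reported. The full-data curves
provide the point estimate (the bootstrap distribution is reported
alongside, so either convention can be read off).

## The synthetic study panel

Real multi-experiment field data cannot be redistributed with the package,
so `generate_dataset()` creates a panel with the statistical structure the
analysis assumes: 20 experiments across five climates (mean annual
temperature 15.1-17.5 C), mid-May to late-June sowings, 2-4 N rates within
0-300 kg N/ha, three replicates, five samplings per plot spanning roughly
650-2000 C d (about 1150 observations). Daily weather is a seasonal
sinusoid plus Gaussian noise; sampling dates are found by accumulating GDD
through the package's own thermal-time code.

The generative chain is: logistic dry-matter growth in thermal time scaled
by a saturating N-supply factor; a standardised plot N-status latent `z`
driven by the N rate; canopy stratification `z_l = sqrt(1 - s^2) z +
s eta_l` giving each leaf position a partly idiosyncratic status; plant N
concentration from a generative dilution law `PNC = supply a DM^-b`
evaluated at the stratum-average status, with coefficients (3.9, 0.40)
that deliberately differ from the analysis curve (3.44, 0.44) so NNI
recovery is not circular, clamped so the implied NNI stays within 0.5-1.3;
a linear PNC-to-LNC link with positive intercept (leaves are N-richer than
whole plants); and per-leaf SPAD `baseline_l(GDD) + gamma_l(GDD) z_l +
noise_l`. Default rates and noise levels were calibrated once against
published descriptive statistics of a comparable panel (mean LNC about
3.0%, PNC about 2.0%, NNI about 0.95, SPAD dispersion increasing toward
lower leaves) and are not revisited. Plots are sampled within a couple of
days of each nominal stage date, so thermal-time support is spread rather
than clustered at five points.

Three structural choices matter for interpretation:

* **Stationary status units.** The nitrogen signal in SPAD is expressed in
  SDs of the stage-local N spread rather than absolute LNC. Dilution
  compresses absolute differences over the season; without
  standardisation, season-varying signal variance and leaf-specific level
  trajectories make every leaf a partial GDD proxy, and tree models shift
  attribution mass between leaves for reasons unrelated to nitrogen
  sensitivity.
* **Canopy stratification.** Whole-plant N is the average of the leaf
  strata, so each leaf holds target-relevant information that no other
  leaf can substitute. With a single shared latent, near-noiseless leaves
  become interchangeable proxies and tree ensembles split attribution
  among them arbitrarily - the importance crossover would then be a
  model artefact rather than a property of the data.
* **Symmetry at the crossover.** LFT2 and LFT3 share one baseline, one
  baseline slope and one noise SD, and their sensitivity trajectories are
  mirrored sigmoids in GDD (LFT2 declining from 2.3 to 0.7 SPAD per status
  SD, LFT3 rising over the same range, logistic scale 90 C d), equal at
  1100 C d by default. The two leaves are therefore statistically
  exchangeable exactly at `crossover_gdd_true`, which is what makes that
  parameter a recoverable ground truth, and the sigmoid shape concentrates
  the redistribution in a window around the crossover - two plateaus with
  a sharp transition, the regime a first-sign-change estimator is built
  for - instead of spreading it over the whole season where slow drifts in
  fitted-model credit would dominate the crossing location.

LFT1/LFT5 have weak flat sensitivities, LFT4 an intermediate flat one by
default (a late-season ramp is available via `gamma4_slope`). Noise SDs
rise from LFT1 to LFT5, mimicking the field observation that lower, older
leaves are more heterogeneous; they are plot-level SDs of a three-reading
leaf average, hence around one SPAD unit for mid-canopy leaves. LFT5 is
absent before 800 C d (not yet expanded) and missing with linearly ramping
probability beyond 1650 C d (senescence), concentrating missingness at the
GDD extremes.

What the generator does *not* emulate: cultivar-specific dilution curves,
spatial field heterogeneity, weather shocks, measurement drift between
operators, or any correlation structure beyond the shared leaf-N latent.
Passing tests on this panel therefore demonstrate that the pipeline's
machinery is correct and that its estimands are recoverable under the
stated structure - not that real rice data will show the same effect sizes.

Randomness is organised in per-stage substreams (weather, biomass,
nitrogen, SPAD, missingness) derived from one master seed, so enlarging a
later stage (say, adding replicates) does not perturb earlier draws.

## Numerical choices and degenerate inputs

* Fold planning is a deterministic balanced-greedy assignment (groups by
  decreasing size, each to the lightest fold, ties to the lowest index), so
  fold membership is reproducible across machines and libraries.
* `r2` uses the validation fold's own observed mean in the total sum of
  squares; out-of-fold `r2` can therefore be negative, which is meaningful
  and preserved.
* Constant residuals report a zero trend with an explicit flag instead of
  failing; a constant GDD column is an error because the regressor is
  degenerate.
* LOWESS neighbourhoods with zero x-spread fall back to the weighted mean;
  the tricube weight of the farthest neighbour is exactly zero.
* Bootstrap replicates with fewer than three usable rows (or a single
  distinct GDD) are skipped and counted.
* All user-facing failures are typed conditions (`spadgdd_error_*`), so
  callers can dispatch on class rather than message text.

## Problem sizes

The package's own test and acceptance runs use the default panel
(~1150 observations, 20 experiments), 10-fold grouped CV, 500-tree forests
and 800 bootstrap replicates - the same orders of magnitude as the analyses
the pipeline is designed for, chosen so a complete run finishes in minutes
on a single core.

## Known limitations

* The crossover estimator inherits LOWESS boundary bias near the ends of
  the GDD range; crossovers within roughly half a span of the boundary are
  less reliable.
* The group bootstrap resamples experiments with fixed attributions (the
  stated procedure); it therefore understates uncertainty contributed by
  refitting the models themselves, and the 95% crossover interval can be
  slightly anti-conservative.
* Attribution-based importance quantifies how fitted models use correlated
  predictors; it is explanatory, not causal.
* The residual-trend diagnostic is a pooled linear association; it will
  not flag non-monotone stage-dependent bias that integrates to zero slope.
* PLS components and SVR constants are fixed defaults, not tuned optima;
  they are exposed in `model_spec()` for users who need different settings.
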