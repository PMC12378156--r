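---
title: "Two-stage canopy-closure estimation: models, assumptions and design choices"
author: "canopyscale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage canopy-closure estimation: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopyscale)
```

## The estimation problem

Forest canopy closure (FCC) — the proportion of ground covered by the
vertical projection of tree crowns, a value in [0, 1] — is expensive to
measure in the field but central to forest inventory. Spaceborne
photon-counting LiDAR provides dense strips of ~100 m footprint segments
with rich per-segment statistics (canopy-height summaries, photon counts,
apparent surface reflectance, ancillary tree-cover percentages), yet only a
handful of field plots are ever co-located with footprints. `canopyscale`
implements the resulting two-stage estimator:

1. **Footprint stage.** A small plot sample (54 plots in the emulated
   campaign) trains a nonparametric regressor — k-nearest-neighbours (KNN),
   random-forest regression (RFR) or gradient-boosted regression trees
   (GBRT) — from segment features to FCC. Hyperparameters are tuned by
   Gaussian-process Bayesian optimization against leave-one-out
   cross-validated RMSE, and the tuned winner predicts FCC for every forest
   footprint.
2. **Regional stage.** The footprint predictions, now thousands of
   pseudo-observations, train a geographically weighted regression (GWR) on
   wall-to-wall raster covariates (vegetation indices, SAR backscatter
   transforms, GLCM textures, terrain), yielding a continuous FCC map with
   local diagnostics.

A seeded synthetic-scene generator supplies every input, so the full chain
is testable with no downloads and known ground truth.

## The GWR model

At location $(u_i, v_i)$ the response follows the spatially varying
coefficient (SVC) model

$$y_i = a_0(u_i, v_i) + \sum_k a_k(u_i, v_i)\, x_{ik} + \epsilon_i ,$$

estimated at each location by weighted least squares,
$\hat a(i) = (X^\top W_i X)^{-1} X^\top W_i y$, with kernel weights
decaying in the distance $d_{ij}$ between observations. Two kernels are
provided: Gaussian $w = \exp(-d^2/\theta^2)$ and bisquare
$w = (1 - (d/\theta)^2)^2$ for $d < \theta$ (0 beyond). The bandwidth is
either a fixed distance $\theta$ (meters) or adaptive: $\theta_i$ is the
distance to the $k$-th nearest training point, with $k$ the tunable. The
pipeline default is **adaptive bisquare** — the configuration actually used
in operational runs of this estimator — while the Gaussian/fixed form is
retained because it is the textbook presentation and is what the package's
closed-form kernel tests exercise.

Bandwidth selection minimizes the corrected Akaike criterion of the linear
smoother,

$$\mathrm{AICc} = 2n\ln\hat\sigma + n\ln 2\pi +
  n\,\frac{n + \mathrm{tr}(S)}{n - 2 - \mathrm{tr}(S)},
  \qquad \hat\sigma = \sqrt{\mathrm{RSS}/n},$$

where $\mathrm{tr}(S)$, the hat-matrix trace, counts effective parameters.
No reference formula accompanies the published AICc values this package is
patterned on, so this standard GWR form was adopted and is unit-tested by
hand arithmetic; only *relative* AICc changes are ever compared across
models. The search is golden-section; over adaptive neighbour counts it
rounds to integers with memoized evaluations and breaks ties toward the
smaller bandwidth. A minimizer at a search bound triggers a boundary
warning rather than silent acceptance. Default adaptive search bounds are
$[p+2, n]$; the pipeline raises the lower bound to twice the local
parameter count so every bisquare local system stays overdetermined.

Numerical details: distances are Euclidean in projected meters —
longitude/latitude input is rejected, not silently treated as planar; a
singular local system falls back to a ridge proportional to the system's
scale ($10^{-8}\cdot\overline{\mathrm{diag}(X^\top W X)}$ by default,
escalated until solvable, with one aggregated warning per fit), or errors
if the fallback is disabled; the pipeline additionally standardizes the
regional design columns before fitting — covariates arrive on wildly
different scales (dB, degrees, power-transformed meters) and compact-
support kernels leave few effective observations per local system, so
conditioning matters; reported local coefficients are then on the
standardized scale. Local $R^2$ uses
kernel-weighted totals about the kernel-weighted local mean; predictions at
new locations refit the local system from training data only and are
clamped to [0, 1] because FCC is a proportion.

## Bayesian optimization of the learners

The tuning objective is the LOOCV RMSE — the headline error metric of the
two-stage design. The surrogate is a Gaussian process with Matérn-5/2 ARD
kernel whose hyperparameters are refit by marginal likelihood each
iteration; integer dimensions are relaxed to [0, 1] and rounded, and
categorical dimensions enter the surrogate as indicator columns. Expected
improvement is maximized over a random candidate set enriched with jittered
copies of the best evaluated points; duplicate proposals are perturbed to
the nearest unevaluated configuration, and non-finite objective values are
recorded at a worst-so-far penalty so a single failed fit cannot derail the
run. The conventional full budget for this design is 1000 evaluations per
learner; package examples and tests run desk-scale budgets of 30–50, which
suffice on the small search spaces involved (the KNN space has only 38
configurations).

Default search ranges (all configurable): `n_estimators` 50–1000,
`max_depth` 2–20, `min_samples_leaf` 1–10, `n_neighbors` 2–20, KNN
`weights` in {uniform, distance}. The GBRT learning rate is fixed at 0.1
and not tuned. `min_samples_split` appears in the conventional parameter
vocabulary for tree ensembles but has no equivalent in the backends used
here (`ranger`, `xgboost`); the leaf-size constraint subsumes it and it is
omitted from the default spaces.

## Accuracy metrics and a formula caveat

Four metrics are reported: $R^2$, RMSE, the relative accuracy
$P = (1 - \mathrm{RMSE}/\bar y)\cdot 100\%$, and the mean absolute residual
MAR. The $R^2$ carried in `eval_metrics()$r2` is the sum-of-squares ratio
$\sum(\hat y_i - \bar y)^2 / \sum(y_i - \bar y)^2$ with $\bar y$ the
*observed* mean (using the mean prediction would break the perfect-
prediction identity $R^2 = 1$). Two caveats follow from that definition and
are worth stating plainly:

* the ratio equals the conventional coefficient of determination only for
  least-squares fits; for arbitrary predictors it rewards prediction
  variance, and
* it is therefore **not monotone in fit quality**: an RMSE-minimizing tuner
  legitimately smooths predictions, which can lower the ratio while the fit
  improves.

`eval_metrics()` therefore also returns `r2_score` $= 1 -
\mathrm{RSS}/\mathrm{TSS}$, the quantity standard regression toolkits call
$R^2$. Comparison tables report the ratio form; paired tuned-versus-default
direction checks use `r2_score` (equivalently RMSE), because that is the
comparison a tuner can be expected to win.

## Feature screening

The footprint stage uses a single gate: random-forest impurity importance
(500 seeded trees), normalized to shares summing to 1, keeping variables at
or above 5% — the boundary is inclusive, since observed retained sets
include values within rounding of the threshold. The regional stage chains
three gates in order: Pearson screening (keep $|r| \ge 0.2$ with two-sided
$p < 0.01$; zero-variance covariates are dropped with a reason, not an
error), an iterative worst-first VIF filter (remove the largest VIF until
all $\le 10$; infinite VIFs from exact collinearity are removed first), and
a normality assessment using the D'Agostino $K^2$ omnibus skew/kurtosis
test at $\alpha = 0.05$, with a one-parameter Yeo-Johnson power transform
(maximum-likelihood $\lambda$) applied and retested for failing variables.
Transformed covariates enter the GWR design transformed, and the report
records the $\lambda$.

## The synthetic scene: what it emulates, and what it does not

`generate_scene()` builds a 128×128-cell, 30 m lattice (3.84 km extent)
with reflectance bands, VV/VH backscatter in dB and a DEM, all driven by
smooth latent vegetation/moisture fields plus pixel-scale texture. Three
standardized covariates derived from the bands (NDVI, VV−VH, elevation)
enter a linear SVC model with smooth coefficient surfaces (low-order
harmonics blended with a seeded smooth field), and the true FCC surface is
the clamped linear predictor plus Gaussian noise. Footprints sit on 27
parallel north–south strips at 100 m along-track spacing (~1000 forest
footprints); the six informative segment features are monotone transforms
of true FCC with calibrated noise, beside 44 distractors (half spatially
autocorrelated). All randomness descends from one integer seed through a
documented stream-splitting scheme, so identical configurations are
bit-identical.

Three calibration choices were made once, at design time, and frozen:

* **Plot marginal.** Plot measurements are rank-matched to a Beta
  distribution truncated to [0.20, 0.83]. Moment-matching the *untruncated*
  Beta to mean 0.50 / variance 0.031 gives shapes 3.535/3.535
  (`beta_moment_match()`), but truncation shrinks the SD to ~0.154; the
  default shapes (1.374, 1.561) are instead solved on the truncated
  distribution so the sampled marginal reproduces mean 0.50 and SD 0.176.
  Rank-matching (rather than rejection sampling) preserves the spatial
  association between plots and the scene while pinning the marginal.
* **Footprint-feature noise.** Noise scales were set so that
  default-parameter learners on 54 plots score LOOCV $R^2 \approx$ 0.25–0.6
  and RMSE $\approx$ 0.10–0.16 — the accuracy regime reported for real
  segment features — rather than the near-oracle features a naive generator
  produces. Photon counts are overdispersed (Poisson with lognormal rate
  heterogeneity).
* **SVC identifiability.** Coefficient surfaces vary at roughly half the
  scene extent with amplitudes (intercept ±0.15, NDVI ±0.10, VV−VH ±0.06,
  elevation ±0.055 around means 0.50 / 0.12 / −0.06 / −0.05), the surface
  noise sd is 0.02, and every covariate carries fine-scale variation
  (including 30 m DEM relief) so local regression designs stay well
  conditioned. Under these defaults the AICc-selected adaptive-bisquare GWR
  recovers each true coefficient surface with correlation ≥ 0.9 at the
  default seed; across other seeds the weakest coefficient occasionally
  dips below that.

What the generator does **not** emulate: photon-level physics, radiometric
realism of the optical bands, SAR speckle statistics, terrain-induced
geometric distortion, or any real geography. The generative links between
segment features and FCC are stand-ins — the true physical relations are
not published — so passing tests demonstrate that the *estimation
machinery* behaves correctly under a model where GWR is the right
estimator, not that the pipeline would achieve any particular accuracy on
real imagery.

## Pipeline reporting conventions

Improvement percentages always record their convention, because published
comparison tables mix them: single before/after pairs use
`delta_over_before` (e.g. $R^2$ 0.53→0.70 is +32.08%), while three-learner
averages use per-model relative changes averaged — gains over the *after*
value, error reductions over the *before* value. Map class shares use bins
[0, 0.3), [0.3, 0.6), [0.6, 1] (half-open, last closed) over valid cells
only. Plot validation extracts the nearest map cell (plot radius 8.5 m is
below the 30 m cell size) and reports both $R^2$ variants' inputs — the
ratio-form $R^2$ and the Pearson correlation with its two-sided p-value.

## Problem sizes and determinism

Package tests and examples run the scene at 128×128 (default) or 64×64
cells, BO budgets of 15–50, GWR bandwidth searches over ~15 memoized
evaluations, and 10-seed paired comparisons; the acceptance script runs the
full three-learner pipeline once at budget 50 plus a dense-grid bandwidth
oracle. These sizes were chosen so a complete verification runs on a
laptop-class single core in minutes while keeping every qualitative
property of the full-size design (the documented full budget is 1000
evaluations and regional designs run to tens of thousands of footprints).
Every stochastic step re-derives its seed from the master seed via
`split_seed()`, so reports are reproducible bit-for-bit from the
configuration alone.

## Known limitations

* GWR here is the classical single-bandwidth form; mixed and multiscale
  variants, and residual spatial-autocorrelation tests, are out of scope.
* The GP surrogate refits by full Cholesky each iteration — fine at
  desk-scale budgets, cubic beyond a few hundred evaluations.
* The raster container is a plain in-memory matrix stack with TIFF + JSON
  sidecar export; there is no tiling, reprojection or nodata masking beyond
  what the covariate derivations produce.
* IDVI has no standard published formula; it defaults to `1 + NDVI` and is
  configurable. "MASVI" in common variable lists is treated as MSAVI.
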