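# canopyscale

Two-stage estimation of forest canopy closure (FCC) — the proportion of
ground covered by the vertical projection of tree crowns — from sparse
spaceborne-LiDAR footprints to a wall-to-wall regional map. The package is
aimed at vegetation remote-sensing and forest-inventory work where field
plots are scarce (dozens) but LiDAR footprint segments are plentiful
(thousands), and regional rasters (optical bands, SAR backscatter, a DEM)
are available everywhere.

## What it implements

**Footprint stage.** From a small plot sample, tune and select a
nonparametric regressor (KNN / random forest / gradient-boosted trees) with
Gaussian-process Bayesian optimization (Matérn-5/2 surrogate, expected
improvement), scored by leave-one-out cross-validation with the metrics
R², RMSE, P = (1 − RMSE/ȳ)·100% and MAR. Candidate segment features are
screened by random-forest importance (share ≥ 5%). The tuned winner
predicts FCC for every footprint.

**Regional stage.** The footprint predictions train a geographically
weighted regression

    y_i = a0(u_i, v_i) + Σ_k a_k(u_i, v_i) x_ik + ε_i

fit by locally weighted least squares with Gaussian
(`w = exp(−d²/θ²)`) or bisquare (`w = (1 − (d/θ)²)²`, d < θ) kernels,
fixed-distance or adaptive-neighbour bandwidth, selected by golden-section
search on the corrected AIC of the linear smoother
(`AICc = 2n ln σ̂ + n ln 2π + n(n + trS)/(n − 2 − trS)`). Regional
covariates (12 vegetation indices, VV−VH and VV/VH backscatter transforms,
8 GLCM textures per band at window 5 / 64 gray levels, slope/aspect/
elevation) are screened by Pearson correlation (|r| ≥ 0.2, p < 0.01), an
iterative VIF filter (≤ 10) and an omnibus normality test with optional
power transform. The fitted model predicts the FCC map with local R²,
residual and bandwidth diagnostics.

**Synthetic scenes.** A seeded generator builds the whole input set —
rasters, footprint strips with 6 informative + 44 distractor features, and
a 54-plot sample whose marginal matches field statistics (range
0.20–0.83, mean 0.50, SD 0.176) — with known ground truth, so every stage
is testable offline. See the methods vignette
(`vignettes/canopyscale-methods.Rmd`) for the model, assumptions and
design choices.

## Worked example

```r
library(canopyscale)

cfg <- pipeline_config(scene = scene_config(seed = 7),
                       models = "knn", budget = 25, n_init = 8,
                       map_stride = 2)
rep <- run_pipeline(cfg, out_dir = "demo_out")

rep$best_model
#> [1] "knn"
print(rep$footprint_comparison, digits = 4)
#>   model optimized     r2   rmse p_accuracy     mar
#> 1   knn     FALSE 0.6096 0.1242      74.82 0.09942
#> 2   knn      TRUE 0.4510 0.1192      75.85 0.09856
round(unlist(rep$fcc_distribution), 3)
#>   [0,0.3) [0.3,0.6)   [0.6,1]
#>     0.005     0.812     0.183
round(rep$plot_validation$pearson_r, 4)
#> [1] 0.7615
round(rep$map_truth_r2_score, 4)
#> [1] 0.7029
```

Reading the output: tuning lowers the held-out RMSE of the footprint model
(0.124 → 0.119) and raises P (74.8% → 75.9%); the `r2` column is the
sum-of-squares-ratio form and can move against RMSE (see the metrics
section of the vignette). The map concentrates 81% of cells in the 0.3–0.6
FCC class; map values correlate 0.76 with the held-out plot measurements,
and — because the scene is synthetic — the map explains 70% of the variance
of the *true* closure surface (`map_truth_r2_score`). `demo_out/` receives
the FCC map (TIFF + georeferencing sidecar), footprint predictions (CSV),
the model comparison table (CSV) and the full report (JSON).

A thin command-line wrapper ships in `inst/cli/canopyscale.R`
(`simulate` and `run` subcommands).

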