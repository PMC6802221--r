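# forestdiv

Forest structural metrics from space-borne radar and airborne laser
scanning (ALS), and their links to multi-taxon biodiversity.

Ecologists increasingly ask how much of the biodiversity signal carried
by expensive ALS campaigns can be recovered from freely available
dual-polarisation C-band radar backscatter. Answering that requires a
full chain of well-defined estimators, which this package implements:

* **ALS metrics** (13 per 1-ha plot): vegetation-height statistics
  (H_mean, H_max, H_SD, H_CV), layer penetration ratios — canopy
  `n(h>5)/n`, understory `n(2<h≤5)/n(h≤5)`, regeneration
  `n(0<h≤2)/n(h≤2)`, canopy cover `n(h>2)/n` — foliage height diversity
  `−Σ pᵢ ln pᵢ`, canopy-gap area and edge length (√-transformed, after
  the 50 m² / perimeter–area-ratio 1.5 filters on 8-connected gap
  features), and canopy-surface-model SD and 3-d/flat surface ratio.
* **Radar metrics** (34 per plot): median γ⁰ composites (dB) for
  {VV, VH} × {year, summer, winter}, winter−summer differences, the
  VV−VH difference (dB) and VV/VH ratio (linear power), 9×9 focal
  mean/SD, and grey-level co-occurrence dissimilarity `Σ p(i,j)|i−j|`
  and entropy `−Σ p(i,j) ln p(i,j)` at 32 grey levels.
* **Biodiversity responses**: NMDS of Bray–Curtis dissimilarities
  (Kruskal stress-1, 30 random starts, smallest dimension with
  stress < 0.2), natural-log species richness, SES-MPD =
  (MPD_obs − mean MPD_null)/sd MPD_null against 999 richness-matched
  draws from regional species pools, and Chao–Jost sample coverage
  Ĉ = 1 − (f₁/n)·[(n−1)f₁/((n−1)f₁+2f₂)].
* **Sensor comparison**: canonical correlation analysis with structure
  correlations, Wilks' Λ F-approximations and redundancy indices.
* **Prediction**: component-wise gradient-boosted additive models
  (P-spline base learners, ν = 0.1, mstop tuned on 10–500 by 25
  bootstrap resamples, categorical-ridge region learner as the random
  factor), evaluated by region-stratified 5-fold cross-validation
  (R² = 1 − SSE/SST on held-out plots) and external validation.
* **A synthetic landscape generator** producing point clouds,
  backscatter stacks, phylogenies and communities whose couplings to
  latent maturity and heterogeneity gradients are known, so every stage
  is testable without any downloads.

See `vignettes/forest-structure-biodiversity.Rmd` for the model details
and design decisions.

## Worked example

```r
library(forestdiv)

# a small landscape: 60 plots in 3 regions along latent gradients
states <- generate_plots(n_plots = 60, n_regions = 3, seed = 42)
head(states, 3)
#>    plot_id region  maturity heterogeneity conifer_ratio
#> 1 plot_001     R1 0.9148060     0.6756073     0.3567220
#> 2 plot_002     R2 0.9370754     0.9828172     0.4106351
#> 3 plot_003     R3 0.2861395     0.7595443     0.5734759

# lidar point cloud and its 13 structural metrics for the first plot
pc <- simulate_point_cloud(states[1, ], density = 5, seed = 1)
round(als_metrics(pc), 3)
#>   H_mean  H_max H_SD  H_CV PR_canopy PR_understory PR_regen PR_h2   FHD
#> 1 17.545 30.995 8.13 0.463     0.741             0    0.573 0.741 0.451
#>   Gap_Area_sqrt Gap_Edge_sqrt CSM_SD Surface_ratio
#> 1             0             0  5.916         9.151

# radar backscatter stack and a few of its 34 metrics
stack <- simulate_backscatter(states[1, ], seed = 2)
round(radar_metrics(stack)[, c("VH_winter", "VV_year",
                               "focal_sd_VV_year",
                               "glcm_entropy_VH_year")], 3)
#>   VH_winter VV_year focal_sd_VV_year glcm_entropy_VH_year
#> 1   -22.078 -11.878            1.205                4.182
```

This mature plot (maturity 0.91) shows the expected pattern: tall, closed
canopy (cover 0.74, no surviving gaps) and strongly depressed winter VH
backscatter (−22.1 dB).

```r
# communities on a phylogeny, ordination, and the sensor comparison
tree <- simulate_phylogeny(40, seed = 3)
comm <- simulate_communities(states, tree, seed = 4)
ord  <- nmds(bray_curtis(comm$occurrence), k = 2, n_starts = 10, seed = 5)
round(ord$stress, 3)                       # 0.123  (k = 2 is adequate)
round(cor(ord$points[, 1], states$maturity), 2)   # -0.97

metrics <- landscape_metrics(states, density = 5, seed = 6)
cca <- ccoa(metrics$als, metrics$radar)
round(cca$cor[1:3], 3)                     # 0.999 0.996 0.990
round(cca$wilks$p_value[1], 4)             # 0

# how well does radar predict the first composition axis?
folds <- region_stratified_folds(states$region, k = 5, seed = 7)
cv <- cross_validate(metrics$radar, ord$points[, 1], folds,
                     lapply(colnames(metrics$radar), bl_spline),
                     grid = seq(10, 200, 10), B = 10, seed = 8)
round(c(r2 = cv$mean_r2, rmse = cv$mean_rmse), 3)
#>    r2  rmse
#> 0.916 0.259
```

The first NMDS axis is essentially the maturity gradient (r = −0.97), the
first canonical pair of the two sensor tables recovers it almost
perfectly, and the boosted radar model predicts held-out composition
scores with cross-validated R² ≈ 0.92 — structure-driven composition is
far easier to predict than richness, which is the central qualitative
contrast this pipeline is built to measure.

The full benchmark (250 plots, 5 regions, 60 species, all
response × sensor × model combinations) runs with

```r
report <- run_pipeline(default_benchmark_config(seed = 1),
                       output_dir = "results/benchmark")
report$report
```

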