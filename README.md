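# divscape

Landscape-scale mapping of woody plant diversity hotspots, and their overlap
with the home ranges of an endangered gibbon.

`divscape` is an analysis package for conservation ecologists working at the
reserve scale. Starting from a kilometer-grid plot campaign, it:

1. computes per-plot **species richness** S and the **Shannon–Wiener index**
   H = −Σ pᵢ ln pᵢ (nats) from stem censuses;
2. builds an **anthropogenic disturbance surface** by summing
   distance-decayed interference intensities of villages, factories, roads,
   artificial and economic forests (linear decay I₀·(1 − d/D_max), zero at
   the maximum distance);
3. screens environmental predictors (climate, soil, topography,
   disturbance) with a pairwise-correlation filter (|r| ≤ 0.85), an
   iterative **VIF** filter (VIF = 1/(1−R²ⱼ) < 10) and
   permutation-importance (**%IncMSE**) backward elimination;
4. fits a **random forest** per diversity index (1000 trees, mtry tuned by
   10-fold CV RMSE), with partial-dependence curves and **variance
   partitioning** of CV R² over the four predictor groups by
   inclusion–exclusion;
5. recalibrates the predicted surface through the OLS line of predicted on
   observed, S_fit = a·S_obs + b, applying max[(S_fit − b)/a, 0] per cell,
   and maps residual-based prediction uncertainty in three classes;
6. delineates **hotspots** as the top 10% of cells and overlays them with
   **circular home ranges** (area 1.49 km² ⇒ radius √(A/π) ≈ 688 m;
   an "infrequent" tier adds a buffer ring of one radius).

Because reserve plot data are rarely public, the package ships a
synthetic-landscape generator (Gaussian random fields, a two-tier 391-plot
layout, communities with known richness/evenness drivers) so the entire
pipeline is testable and reproducible end to end. See
`vignettes/diversity-hotspot-mapping.Rmd` for the methods account.

## Worked example

A one-minute demonstration on a small simulated reserve (60×60 cells,
50 plots, both indices):

```r
library(divscape)
res <- run_diversity_pipeline(pipeline_config(), out_dir = "demo_run")
r <- res$results$richness

print(r$model)
#> divscape_model: 50 obs, 9 predictors, ntree=150, mtry=6
#>   5-fold CV: R2=0.711 MAE=7.081 RMSE=11.020
head(r$importance, 4)
#>    predictor    inc_mse crucial
#> 1 climate_01 112.858773    TRUE
#> 4    soil_01 100.087553    TRUE
#> 8     aspect   8.003035   FALSE
#> 3 climate_04   3.659511   FALSE
print(r$hotspots)
#> hotspot_mask: 360 of 3600 valid cells (10.0%) >= 85.07 (q = 0.90)
subset(r$overlap, tier == "frequent")[, c("group", "hotspot_cells", "coverage")]
#>   group hotspot_cells   coverage
#> 1     A            54 0.01883502
#> 3     B           237 0.08266481
#> 5     C           243 0.08475759
#> 7     D           360 0.12556679
#> 9     E           359 0.18954593
```

Reading this: the forest explains 71% of cross-validated richness variance;
the two predictors the simulator actually used to drive richness
(`climate_01`, `soil_01`) are the only ones flagged crucial (%IncMSE > 15);
exactly 10% of cells clear the hotspot threshold of 85.07 species; and
hotspot coverage of the five groups' frequent home ranges varies from 2% to
19%. Every artifact (rasters as ESRI ASCII grids, vectors as GeoJSON,
tables as CSV, a manifest with md5 checksums) lands in `demo_run/`; rerunning
with the same config reproduces identical checksums.

The `analysis/` directory holds the same workflow as numbered narrative
scripts (`01_simulate_landscape.R` … `06_hotspots_homeranges.R`) on a
medium-sized reserve, writing summary tables to `results/` — run them from
the repository root after installing the package.

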