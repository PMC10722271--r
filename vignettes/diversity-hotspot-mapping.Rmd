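---
title: "Mapping woody plant diversity hotspots: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping woody plant diversity hotspots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divscape)
```

divscape maps woody plant diversity across a forest landscape from a
kilometer-grid plot campaign and relates the resulting diversity hotspots to
the circular home ranges of an endangered gibbon. This vignette is the
package's methodological account: the models it fits, the assumptions they
rest on, the parameters that matter, and the choices made where the design
was genuinely open. A synthetic-landscape generator with known ground truth
stands in for field data, so every claim below is one the test suite can
actually check.

## The analysis in one paragraph

Plot censuses give two diversity indices per 20 m plot: species richness
$S$ (number of woody species) and the Shannon–Wiener index
$H = -\sum_i p_i \ln p_i$ in nats, with $p_i$ the proportion of stems in
species $i$. Environmental predictors in four groups — climate, soil,
topography, anthropogenic disturbance — are aligned on a common 20 m grid;
the disturbance layer is an environmental risk surface summing
distance-decayed interference from villages, factories, roads, artificial
and economic forests. Predictors pass a pairwise-correlation filter
($|r| \le 0.85$), an iterative VIF filter (VIF $< 10$) and
permutation-importance backward elimination. A random forest (1000 trees,
mtry tuned by 10-fold CV RMSE) predicts each index across the landscape;
the prediction is recalibrated through the OLS line of predicted on
observed (Sfit $= a\,$Sobs$ + b$, corrected value
$\max[(\text{Sfit}-b)/a,\,0]$); the top 10% of cells are hotspots; hotspot
masks are overlaid with circular home ranges of 1.49 km²
(radius $r=\sqrt{A/\pi} \approx 688$ m) and their one-radius buffer rings.

## The synthetic study system

The generator emulates the structure of a tropical nature-reserve campaign
without reproducing any real pedology or climatology:

* **Predictor rasters.** Climate and soil layers are stationary Gaussian
  random fields: white noise smoothed with a Gaussian kernel
  ($\sigma$ = correlation length / cell size) and z-standardized. The
  default correlation length (800 m on the full-size landscape) makes
  fields smooth at the scale a bioclim or soil product would be, yet
  variable across plots. Elevation is generated the same way, rescaled to
  a 100–1400 m tropical-mountain relief; slope and aspect come from Horn's
  3×3 stencil (aspect of flat cells is −1, a conventional sentinel).
* **Plot layout.** Two tiers mirror a kilometer-grid design: 114 plots on
  1 km nodes across the extent and 277 plots on 0.5 km nodes inside a
  focal zone, 391 in total on the full-size system. Nodes are sampled
  without replacement under the seed; no two plots share a center.
* **Communities.** Per plot, expected log-richness is
  $\ln S = \beta_0 + \boldsymbol\beta_S^\top \mathbf{x}$ at the plot's
  cell; realized richness is Poisson, rejection-truncated to
  $[1, \text{pool}]$ so every community is valid and the mean stays
  interpretable. Abundances follow a geometric series whose dominance
  ratio $k\in(0,1)$ is a logistic function of a second linear predictor,
  so Shannon evenness carries covariate signal with closed-form control
  ($k \to 1$ forces $H \to \ln S$). Stem diameters are drawn log-normally
  for realism but drive nothing downstream.
* **Defaults.** Richness is driven by one climate and one soil field
  (log-scale coefficients 0.5 and 0.4, intercept $\ln 25$); evenness by
  the same pair (0.8 and 0.5, intercept 1). These were fixed once as a
  regime with two genuine drivers among eleven predictors — strong enough
  to be recoverable, weak enough that recovery is not trivial.

What the generator does **not** emulate: spatial non-stationarity,
cross-correlated predictors (fields are independent by construction),
dispersal limitation or other residual spatial autocorrelation in the
communities, and measurement error in plot coordinates. Passing tests
therefore show the pipeline recovers known structure under clean
conditions; they do not certify performance on real field data, where
predictor collinearity and spatial confounding are the norm rather than
the exception.

## The risk surface

Each element type carries a base intensity $I_0$ and maximum distance
$D_{max}$. Four kernels are provided — linear
$I_0\,(1-d/D_{max})$, constant (top-hat), convex and concave power-law
variants $I_0\,(1-d/D_{max})^\gamma$ with $\gamma>1$ or $\gamma<1$ — all
returning $I_0$ at the source and exactly 0 at and beyond $D_{max}$. The
pipeline uses the linear kernel throughout; the power-law forms of the
convex/concave variants are this package's concrete reading of those
kernel names. Distances are measured from cell centers to the nearest
geometry point (zero inside polygons), matching raster semantics at 20 m.
Per-type default $(I_0, D_{max})$ values shipped in
`default_risk_params()` are synthetic placeholders — calibrated values are
site-specific and should be overridden per element or per type.

## Predictor screening

The correlation filter drops, from each offending pair ($|r|>0.85$), the
member with the larger mean absolute correlation to everything else, ties
broken alphabetically — one-member removal, since removing both would
discard information. VIF is computed from the inverse correlation matrix
(equal to $1/(1-R_j^2)$ of the auxiliary regressions, which the tests
verify to 1e−8) and the largest-VIF column is removed until all are below
10. Backward elimination then repeatedly removes the predictor with the
lowest %IncMSE and accepts the removal while 10-fold CV RMSE does not
worsen by more than 1% relative (folds fixed across steps). The tolerance
is configurable; `-Inf` disables elimination entirely. %IncMSE is the
out-of-bag permutation importance: the percent increase of mean per-tree
OOB MSE after permuting one predictor — computed in-package because the
similarly-named column of common forest implementations is a scaled
z-score, not a percent.

## Model fitting, partitioning, calibration

Forests use 1000 trees; mtry candidates (by default a small ladder up to
$p$) are scored by 10-fold CV under one fold assignment, stratified by
response deciles for stability at $n \approx 391$; the minimum-RMSE
candidate is refit on all data. CV $R^2$ is computed from pooled held-out
predictions, so it can be negative for uninformative models — a property
the variance partitioning relies on. Candidates exceeding the predictor
count are skipped with a warning (field studies have reported tuned mtry
values above the predictor count, which is not representable in a standard
forest).

Variance partitioning fits one cross-validated forest per nonempty subset
of the four predictor groups (15 models) and decomposes the full-model CV
$R^2$ by inclusion–exclusion (Möbius inversion over the subset lattice),
so the unique and shared fractions sum to the full-model CV $R^2$ exactly.
Cross-validated rather than in-bag $R^2$ is used because in-bag forest
fits are optimistic enough to scramble the lattice sums. Negative
fractions — a recognized feature of this decomposition — are retained in
the output and only hidden by the 1% display rule of the reporting column.

Bias calibration fits Sfit $= a\,$Sobs $+ b$ by OLS with Sfit the
cross-validated predictions at the plots (in-bag forest predictions are
nearly unbiased by construction and would defeat the correction), then
applies $\max[(\text{value}-b)/a, 0]$ per cell. Clamped cells are set to 0
rather than masked so the hotspot quantile still sees them. Applying the
fitted calibration and its inverse to the training predictions recovers a
regression of slope 1 and intercept 0 against observations whenever
nothing clamps — a tested invariant. $|a|<10^{-8}$ is rejected as a
degenerate calibration.

The residual uncertainty map interpolates absolute CV residuals at the
plots to the grid by inverse-distance weighting (power 2, configurable)
and classifies the surface into terciles — Strongly / Moderately / Less
predictive. IDW and terciles are pragmatic choices where the method was
left open; a constant residual surface degenerates to all cells "Strongly
predictive" by construction.

## Hotspots and home ranges

The hotspot threshold is the 0.90 quantile of valid cells; cells at or
above it are flagged. A value-based rule with ties-in keeps the
delineation reproducible (a count-based rule would need arbitrary
tie-breaking); on distinct-valued surfaces it flags exactly
$\lceil 0.10\,n\rceil$ cells. Home ranges are disks of 1.49 km²
($r = 688$ m) with an infrequent tier of radius $2r$ (buffer of one
radius); cell membership is by center containment, which errs by less
than one cell ring at 20 m — the discretized disk area is within 1% of
$\pi r^2$, a tested bound. The synthetic group layout places four
clustered groups in the focal zone and a fifth far to the east,
mirroring a newly-established distant family group.

## Numerical and degenerate-input conventions

* Identical configuration and seed reproduce every raster, vector, layout,
  community and artifact checksum bit for bit; all stochastic stages take
  explicit seeds.
* Empty plots are an error naming the plot; zero-variance predictors are
  dropped with a warning before correlation; exactly collinear predictors
  are removed deterministically (alphabetically last) with a warning.
* Shannon is implemented with the conventional minus sign, $-\sum p_i\ln
  p_i$ in natural logs, so a monoculture gives 0 and higher values mean
  higher diversity; descriptions of the index that omit the sign print a
  nonpositive quantity and are treated as a typographical convention.
* Tercile class boundaries use a small epsilon so numerically-constant
  surfaces classify as a single (best) class instead of splitting on
  floating-point dust.

## Problem sizes

The packaged analyses run at three scales, chosen so each layer of
checking stays proportionate: a demonstration landscape (60×60 cells,
50 plots, 150-tree forests) for smoke and determinism checks; a medium
reserve (300×200 cells, 140 plots, 500 trees) for the narrative analysis
scripts; and the full-size synthetic study (800×600 cells, 391 plots,
1000 trees, 10-fold CV) for parameter-recovery and acceptance runs.

## Known limitations

* The distance-decay parameters of the risk surface are placeholders;
  conclusions about disturbance on the synthetic system reflect those
  placeholders, not any calibrated disturbance regime.
* Cross-validation is not spatially blocked; with the generator's
  independent fields this is benign, but on real, spatially structured
  data the CV $R^2$ would be optimistic.
* The correlation/VIF filters act on plot-level values only, and the
  elimination path depends on the (seeded) fold assignment near the
  stopping tolerance.
* Richness and Shannon are the only indices computed; functional and
  phylogenetic diversity are out of scope.
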