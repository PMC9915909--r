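# ecolag

Does a region's ecological quality affect how long its residents live —
and with how much delay? `ecolag` is an R package plus analysis workflow
for studying the relationship between a PCA-based **comprehensive
ecological index** (CEI) and **life expectancy** (LE) across a small
panel of contiguous regions, with an explicit *spatiotemporal lag*: LE at
time *t* is related to the ecological conditions of each region's
*neighbours* at an earlier time *t − m*. It is aimed at spatial
epidemiologists and ecologists working with region-by-year panels built
from satellite indicators (NDVI, LAI, GPP, LST, tasseled-cap wetness).

## What it computes

* **CEI** — per-year correlation-matrix PCA of the five standardized
  indicators; components retained until the cumulative variance
  contribution reaches 80%; composite score
  `P = Σ_{i≤n} (k_i/100)·X_i` with `k_i = 100·λ_i/Σλ`.
* **Trends** — Theil–Sen slope `β = median{(x_j−x_i)/(t_j−t_i)}` and the
  tie-corrected Mann–Kendall test (S, Z, two-sided p), per region or per
  raster pixel.
* **Cold/hot spots** — Getis–Ord Gi* z-scores with self-inclusion on
  binary queen-contiguity weights, classified at |z| ≥ 1.65/1.96/2.58.
* **Lagged spatial cross-correlation** — global and local bivariate
  Moran's I, `I = Σ_ij w_ij z_y,i z_x,j / S0` with `y = LE(t)` and
  `x = CEI(t−m)`, permutation pseudo p-values (global and conditional
  local), Moran scatter values, and LISA cluster labels
  (high-high/low-low/high-low/low-high).
* **Spatial weights** — queen/rook contiguity from GeoJSON polygons,
  k-nearest-neighbour and distance bands from centroids, GAL file I/O,
  row standardization.
* **Synthetic studies** — a seeded generator producing spatially
  autocorrelated indicator panels (SAR filter `(I − ρW)⁻¹ε`), a known
  lagged LE-on-CEI dependence, and optional rasters, so the entire chain
  can be validated as a ground-truth recovery exercise.

## Worked example

```r
library(ecolag)

sim <- simulate_study(synthetic_config(seed = 1))   # 16 regions, 2010/15/20
print(sim$pca[["2010"]])
#> correlation-matrix PCA: 5 indicators, 2 component(s) selected
#>                   PC1    PC2    PC3    PC4     PC5
#> eigenvalue      3.715  0.811  0.273  0.136   0.065
#> contribution % 74.304 16.216  5.458  2.728   1.293
#> cumulative %   74.304 90.521 95.979 98.707 100.000

cm <- cross_moran(y = sim$le$values[, "2020"],
                  x_lagged = sim$cei$values[, "2015"],
                  w = sim$weights, n_perm = 999, seed = 1)
print(cm)
#> bivariate Moran's I = 0.4968 (perm. mean -0.0051, pseudo p = 0.001, 999 perms)
#>   clusters: r01=low-low, r20=low-high, r30=high-high, r31=high-high, r32=high-high

lag_recovery_rank(sim)
#>   lag_years mean_abs_I n_designs
#> 2         5  0.4104397         2
#> 1         0  0.2300322         2
```

Reading this output: the first two principal components carry 90.5% of
the indicator variance, so the CEI is their contribution-weighted sum.
LE in 2020 is strongly spatially cross-correlated with the CEI its
neighbours had in 2015 (I ≈ 0.50 against a permutation null centred at
≈ 0, pseudo p = 0.001), and five regions form significant local
clusters. Pooling the designs available at each lag, the 5-year lag
out-scores the contemporaneous design (mean |I| 0.41 vs 0.23) — the
generator's true lag is indeed 5 years.

The same analysis as a step-by-step workflow, writing tables under
`results/`:

```sh
Rscript analysis/01_simulate.R       # synthetic study -> results/data/
Rscript analysis/02_build_cei.R      # per-year PCA + CEI
Rscript analysis/03_trends.R         # Sen/MK per region and variable
Rscript analysis/04_hotspots.R       # Gi* z-scores and categories
Rscript analysis/05_lag_crosscorr.R  # Pearson + lagged Moran + LISA
```

A published 16-city LE table ships as a fixture
(`inst/extdata/le_study_cities.csv`) together with the published per-year
PCA contribution rates, and `read_panel_csv()` / `interpolate_missing()`
ingest such tables directly.

## Layout

```
R/                  implementation (panels, regions, rasters, indicators,
                    CEI/PCA, trends, weights, Gi*, cross-Moran, synthetic
                    generator, pipeline)
analysis/           numbered workflow drivers (thin wrappers over R/)
tests/testthat/     unit, property and acceptance suites with
                    brute-force oracles
scripts/acceptance.R  headline-quantity reproduction
vignettes/          methods vignette (model, assumptions, design choices)
inst/extdata/       small plain-text fixtures
```
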