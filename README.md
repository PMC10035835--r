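# kelpcanopy

Tools for estimating emergent kelp canopy area from multiband
surface-reflectance imagery and analysing its multi-decade dynamics —
long-term trends, and response to and recovery from marine heatwaves. The
package is aimed at coastal remote-sensing and kelp-forest ecologists who
work with Landsat-class archives (30 m pixels, 6 reflectance bands, a
quality-assurance band, quarterly-to-weekly revisit), and at anyone who
wants a fully testable, self-contained implementation of that processing
chain: every stage can be exercised on synthetic scenes with known ground
truth, without downloading a single satellite image.

## The method

The processing chain mirrors the standard Landsat kelp workflow:

1. **Masking.** Clouds come from the QA band; land is any DEM pixel with
   elevation > 0 m; exposed intertidal is identified on a cloud-free
   low-tide reference scene by the Modified Normalized Difference Water
   Index, MNDWI = (green − SWIR)/(green + SWIR), masking pixels with
   MNDWI < 0.1. Pixels adjacent to land whose estimated canopy area has a
   significant negative OLS relationship with tide height are flagged for
   review as residual intertidal artifacts.
2. **Classification.** Spectra are brightness-normalized (each band divided
   by the six-band mean), grouped by k-means (15 clusters) to build a
   training set, and classified by a CART decision tree into kelp canopy,
   seawater, cloud, or land — one classifier per sensor generation.
3. **Unmixing (MESMA).** Each kelp-class pixel spectrum *x* (blue, green,
   red, NIR) is modelled as a two-endmember linear mixture
   *x* ≈ *f*·K + (1 − *f*)·W over a single static kelp endmember K and each
   of 30 per-scene seawater endmembers W. The closed-form least-squares
   fraction

   *f*\* = Σ<sub>b</sub> (x<sub>b</sub> − W<sub>b</sub>)(K<sub>b</sub> − W<sub>b</sub>) / Σ<sub>b</sub> (K<sub>b</sub> − W<sub>b</sub>)²,

   clamped to [0, 1], is evaluated per candidate W and the minimum-RMSE
   model wins. Canopy area = fraction × 900 m².
4. **Aggregation.** Per-pixel quarterly means/standard errors/overpass
   counts; grid-cell sums over potential kelp habitat (pixels with canopy
   detected at least once) with the missing-data rule: a cell-quarter is
   missing when > 25% of its habitat pixels had no cloud-free look. Cells
   with fewer than 500 (10 km scale) or 25 (1 km scale) habitat pixels are
   excluded. Annual value = maximum over quarters (missing when ≥ 2
   quarters are missing); regional value = sum over cells (missing when
   more than half the cells lost more than one quarter).
5. **Statistics.** Annual series are normalized by their maximum and fitted
   with y = β₀ + β₁·year + ε, where ε is a stationary AR(p) process,
   p ∈ {0, 1, 2} chosen by AIC from exact (gap-aware) REML likelihoods.
   Heatwave **response** = 100 × min(2014–2016) / mean(1984–2013);
   **recovery** = 100 × mean(2017–2021) / mean(1984–2013); **recent
   state** = 100 × mean(2014–2021) / mean(1984–2013). Latitudinal patterns
   use Pearson correlations of log(metric + 1) against cell latitude.

A synthetic-scene generator (`scene_domain()`, `dynamics_config()`,
`generate_scene_series()`) produces multi-decade Landsat-like archives —
linear kelp/seawater mixtures, spatially varying seawater, cloud blobs, a
land/intertidal fringe, tides, and annual dynamics with a configurable
trend, AR noise and an imposed heatwave collapse/recovery — with exact
ground truth at every stage.

## Worked example

Simulate a 38-year archive (four 600 m cells, secular decline of
−0.8%/yr, a 2014–2016 collapse to 20% of baseline with recovery to 80%)
and run the full chain:

```r
library(kelpcanopy)

dyn <- dynamics_config(trend = -0.008, oscillation_amplitude = 0,
                       heatwave_depth = 0.2, recovery_level = 0.8, seed = 42)
cfg <- pipeline_config(dynamics = dyn, trend_years = 1984:2013, seed = 42)
out <- run_pipeline(cfg)

print(out$trend)
#> Kelp canopy trend: -0.678 %/yr (SE 0.159, p = 0.0002099), AR(1), n = 30

cat(sprintf("response %.1f%%  recovery %.1f%%  recent %.1f%%\n",
            out$heatwave$response_pct, out$heatwave$recovery_pct,
            out$heatwave$recent_state_pct))
#> response 20.0%  recovery 79.7%  recent 57.3%
```

The fitted slope (−0.68 ± 0.16 %/yr on the pre-disturbance window) agrees
with the configured −0.8 within its standard error; the response and
recovery percentages recover the configured collapse (20%) and recovery
(80%) levels. Per-cell results live in `out$per_cell`:

```r
head(out$per_cell[, c("cell_id", "latitude", "slope_pct_yr",
                      "response_pct", "recovery_pct")])
#>      cell_id latitude slope_pct_yr response_pct recovery_pct
#> 1 cell_01_01 36.49731   -0.6382203     19.38788     79.51427
#> 2 cell_01_02 36.49731   -0.6613455     23.61075     81.15470
#> 3 cell_02_01 36.49192   -0.5643103     18.38514     80.90557
#> 4 cell_02_02 36.49192   -0.8067506     17.71731     77.50939
```

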