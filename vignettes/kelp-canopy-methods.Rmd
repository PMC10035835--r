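---
title: "Estimating kelp canopy dynamics from multispectral imagery: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating kelp canopy dynamics from multispectral imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kelpcanopy)
```

# The problem

Surface-canopy-forming kelps (giant kelp, bull kelp) float at the sea
surface, where their tissue reflects strongly in the near infrared while
seawater absorbs it almost completely. That contrast makes the emergent
canopy visible to moderate-resolution multispectral satellites, and a
30 m-class archive reaching back to the mid-1980s makes it possible to ask
questions field programs cannot: is a recent collapse part of a decadal
oscillation, a secular decline, or a response to a discrete disturbance
such as the 2014–2016 northeast Pacific marine heatwaves?

`kelpcanopy` implements the full chain from reflectance scenes to those
answers. Because real archives are hundreds of gigabytes and every
published intermediate is expensive to audit, the package is built around
a synthetic-scene generator with exact ground truth: each stage is tested
against either closed-form truth or an independent brute-force oracle.

# Stage by stage

## Masking

Three masks are built per scene, each with a deliberately strict boundary:

* **Clouds** come from the per-pixel quality-assurance band
  (`cloud_mask_from_qa()`); the QA code sets are configurable because QA
  bit dialects differ between product collections. Unknown codes are never
  silently masked — they pass through and are counted.
* **Land** is any DEM pixel with elevation *strictly greater than* 0 m
  (`land_mask_from_dem()`). A pixel at exactly 0 m is sea. Missing
  elevations are conservatively treated as land.
* **Intertidal** pixels are exposed shoreline that a DEM at sea-level
  datum misses. On a cloud-free reference scene acquired at a negative
  tide, MNDWI = (green − SWIR1)/(green + SWIR1) is computed and pixels
  with MNDWI *strictly less than* 0.1 are masked
  (`intertidal_mask()`). MNDWI is insensitive to floating kelp because
  canopy SWIR reflectance stays low (water absorption dominates within
  millimetres), so open water with kelp remains strongly positive while
  wet exposed substrate goes negative.

Residual tidal artifacts are handled by `flag_tidal_pixels()`: for pixels
within one pixel (8-connectivity) of land, the OLS slope of estimated
canopy area against tide height is tested; a negative slope with two-sided
p < 0.05 (t distribution) flags the pixel. Flags are *reported*, not
removed — the workflow this mirrors confirmed flagged pixels against
high-resolution imagery before removal — with an opt-in switch for
automatic removal. The α = 0.05 and the minimum of 8 paired observations
are package choices; the adjacency radius of one pixel likewise.

## Classification

Classification exists to keep glint- or turbidity-brightened seawater out
of the unmixer, which would otherwise assign it spurious positive kelp
fractions. Spectra are first brightness-normalized: each of the six bands
is divided by the six-band mean, so the result is invariant to overall
brightness scaling and has mean exactly 1. The normalization formula is a
package choice (several are in use in the field); divide-by-mean was
chosen for exact scale invariance and idempotence, and both properties are
tested.

Training follows the unsupervised-seeding idiom: `cluster_training_spectra()`
runs k-means (Euclidean, k = 15, 10 seeded restarts keeping the best
inertia — the restarts stabilize an otherwise under-determined
clustering), `assign_cluster_classes()` turns cluster labels into class
labels (in tests, by majority ground-truth class per cluster, automating
what is a manual step in operational practice; an explicit cluster→class
mapping is also accepted), and `train_decision_tree()` fits a CART binary
tree (Gini impurity, axis-aligned splits, no pruning, default maximum
depth 8) over the four classes kelp / seawater / cloud / land. One
classifier is trained per sensor generation and they share no parameters;
`classify_scene()` refuses a generation mismatch.

## Spectral unmixing (MESMA)

Each kelp-class pixel is modelled as a sum-to-one linear mixture of two
endmembers over the blue, green, red and NIR bands: the single static kelp
endmember K shared by all scenes, and one of ~30 seawater endmembers W
sampled per scene from its own seawater-class pixels (spatially stratified
over a coarse block grid so distinct water masses are represented; the
selection procedure is a package choice, seeded and deterministic). For
each candidate W the least-squares fraction has the closed form

$$f^* = \frac{\sum_b (x_b - W_b)(K_b - W_b)}{\sum_b (K_b - W_b)^2},$$

clamped to [0, 1] *before* the RMSE is evaluated, so the reported model is
always a feasible proportion. The candidate with minimum RMSE over the
four bands wins; exact ties break to the lowest endmember index for
determinism. There is no shade endmember and no >2-endmember model: the
mixture space is kelp + seawater only. Canopy area is fraction × pixel
area (900 m² for 30 m pixels). Submerged canopy is invisible to this
model by construction — a fraction estimates *emergent* canopy only.

The closed form is verified in two independent ways: exact recovery
(≤ 1e−6) of noiseless mixtures across the fraction grid, and agreement
with a 1e−4-step brute-force grid search on random noisy pixels.

## Aggregation and missing-data rules

Quarters are calendar quarters (Jan–Mar, …, Oct–Dec). Per pixel and
quarter, `seasonal_pixel_stats()` records the mean canopy area over
cloud-free acquisitions, its standard error (sd/√n, 0 when n = 1), and the
overpass count. *Potential kelp habitat* is every pixel where canopy was
detected at least once across the series.

Cell aggregation applies the rules exactly at their stated boundaries:

* A cell-quarter is **missing** when the unobserved fraction of the
  cell's *habitat* pixels exceeds 25% (strictly; exactly 25% is kept).
  The denominator choice — habitat pixels rather than all water pixels —
  is a package decision, configurable, made because cloud impact is only
  meaningful where kelp could be.
* Habitat pixels observed in a retained quarter contribute their mean;
  unobserved ones contribute 0, never NA — missingness is triggered only
  by the cloud rule.
* Cells with fewer than 500 (10 km) or 25 (1 km) habitat pixels are
  excluded; exactly the threshold is retained.
* The annual value is the maximum over the year's non-missing quarters,
  missing when ≥ 2 quarters are missing.
* The regional value sums member cells, missing when strictly more than
  half the cells lost more than one quarter. In non-missing years,
  individually missing cells contribute 0 with a logged count by default;
  `strict = TRUE` propagates them as missing. Published practice does not
  state which behaviour was used, so both exist and neither is asserted
  as canonical.

Cell membership uses pixel centers in half-open rectangles
[x0, x1) × [y0, y1), so grids tile without double counting (tested by
reconstituting the full pixel set from a cell grid).

## Trend estimation

Annual series are normalized by their maximum (so slopes read as percent
of maximum per year) and fitted with

$$y_t = \beta_0 + \beta_1\,t + \varepsilon_t,\qquad
\varepsilon \sim \mathrm{AR}(p),\ p \in \{0, 1, 2\},$$

by exact Gaussian restricted maximum likelihood, selecting p by AIC.
Two design points deserve emphasis:

* **Gap-aware likelihood.** Annual series routinely have missing years.
  Rather than imputing, the error covariance between observations h years
  apart is the stationary AR autocorrelation at lag h (φ^h for AR(1), the
  Yule–Walker recursion for AR(2)), evaluated on the actual year stamps.
  The fit is verified against an independent GLS implementation on both
  gap-free and gapped series.
* **REML throughout.** The restricted likelihoods of the candidate orders
  are directly comparable because every candidate shares the same mean
  (trend) model — only the error-correlation structure differs. REML also
  removes the small-sample downward bias of ML variance estimates. This
  matters quantitatively at the ~38-year series lengths of satellite
  records: in the package's own calibration simulations (AR(1), φ = 0.5,
  n = 38), ML-based selection and inference leave 95% confidence
  intervals covering the true slope noticeably below nominal, driven by
  runs where AIC under-selects order 0, while the REML version restores
  near-nominal coverage and the nominal type-I error rate. REML is also
  the default of the standard GLS software in this field. The acceptance
  script recomputes both calibration numbers on every run.

Stationarity is enforced structurally: AR coefficients are optimized
through the partial-autocorrelation parametrization (tanh-transformed,
mapped by Durbin–Levinson), so every candidate is stationary and no fit
needs to be discarded for unit roots. A numerically exact fit (residual
variance at the floating-point floor) selects the most parsimonious
order directly — AIC differences are meaningless at the residual floor.
Standard errors use σ̂² = RSS/(n−2); p-values are two-sided t with n−2
degrees of freedom. `kelp_trend()` returns a classed model object with
`print`, `summary`, `coef`, `predict`, `residuals`, `fitted` and `plot`
methods.

## Heatwave metrics

With the default windows — baseline 1984–2013, event 2014–2016,
post-event 2017–2021, recent 2014–2021 —

* response = 100 × min(event) / mean(baseline),
* recovery = 100 × mean(post-event) / mean(baseline),
* recent state = 100 × mean(recent) / mean(baseline),

all computed after dropping missing years from each window, all invariant
to rescaling the series, and all well above 100% when canopy exceeds its
history (recovery is not capped). A zero baseline is flagged as undefined
rather than returning infinity. Latitudinal structure is assessed by the
Pearson correlation of log(metric + 1) with cell latitude (the +1
percentage point keeps zero-response cells finite), two-sided p from the
t distribution with n − 2 degrees of freedom; a permutation test is used
as the oracle in the test suite.

# The synthetic generator

`generate_scene_series()` emulates the *structure* of a Landsat coastal
archive, not its radiometry:

* Six-band scenes in which kelp pixels are exact linear
  kelp/seawater mixtures, seawater varies smoothly across the scene
  (glint/turbidity analogue), clouds are random blobs marked in the QA
  band, land and an elevation-zero intertidal fringe sit along one edge,
  and per-band Gaussian noise (truncated to [0, 1]) is optional.
* Quarterly cadence with a configurable number of acquisitions per
  quarter (default 3) instead of a literal 8/16-day calendar — enough to
  exercise seasonal means at desk scale.
* Annual dynamics in normalized units: linear trend + optional decadal
  sinusoid + stationary AR noise. Years inside the configured heatwave
  window are pinned to `heatwave_depth` × the deterministic baseline
  mean, and post-event years to `recovery_level` × that mean, so the
  disturbance magnitude is known *exactly* by construction and the
  metrics can be checked against it to machine precision on noise-free
  runs.
* Spatial allocation by **occupancy**: habitat pixels are filled to their
  per-pixel capacity in a fixed quality order until the quarter's true
  total area is met, with one marginal pixel taking the remainder. Canopy
  loss therefore contracts extent while surviving stands stay dense —
  the pattern real collapses show (die-off mosaics with persistent
  refugia) — and occupied pixels keep fractions well inside the
  classifier's detectable range. Uniform fading of all pixels to a few
  percent cover would be both unrealistic and undetectable by any
  plausible classifier.

What the generator does **not** emulate: radiative transfer, sensor noise
spectra, atmospheric residuals, geolocation error, orbital geometry, or
real endmember spectra (none are published as numbers; the library is a
plausible stand-in, and no claim of spectral realism is made). Passing
tests therefore demonstrate the *pipeline's* correctness — masks, rules,
estimators, error propagation — on data whose structure matches the real
problem; they do not validate radiometric performance on real imagery.
Sensor generations differ in the package by the classifier contract (one
tree per generation, no sharing), not by simulated spectral-response
differences: cross-sensor radiometric calibration is assumed, as it is in
the calibrated collections this workflow consumes.

# Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| MNDWI threshold | 0.1 (strict <) | index | separates exposed intertidal from water |
| cloud missing-data rule | 0.25 (strict >) | fraction of habitat pixels | cell-quarter validity |
| habitat thresholds | 500 / 25 | pixels | 10 km / 1 km cell retention |
| pixel area | 900 | m² | 30 m pixels |
| seawater endmembers | 30 | per scene | covers within-scene water variability |
| k-means clusters | 15 | — | training-set seeding |
| tree depth | 8 | — | CART capacity without pruning |
| AR orders | {0, 1, 2} | — | AIC-selected error model |
| tidal-flag α, min n | 0.05, 8 | — | artifact screening |
| heatwave windows | 1984–2013 / 2014–2016 / 2017–2021 | years | baseline / event / recovery |

All are configuration, not constants (`pipeline_config()`).

# Problem sizes

The test suite and the acceptance script run at desk scale, chosen so the
whole suite completes in about a minute while every rule is still
exercised: 40 × 40-pixel domains (four 20 × 20-pixel cells), 38-year
archives at 3 acquisitions per quarter (456 scenes), 1000-series
calibration experiments at n = 38, and 100-pixel unmixing oracle
comparisons. The parameter-recovery experiment uses the 1 km-scale
habitat threshold (25 pixels) appropriate to its 600 m cells, disables
the decadal oscillation (the target quantity is the linear slope), and
estimates the trend on the pre-disturbance window 1984–2013 — a step
disturbance pinned to fixed levels is not a linear trend, and fitting
across it would estimate a mixture of the two regimes rather than the
configured slope.

# Known limitations

* Emergent canopy only; submerged biomass is invisible to the mixture
  model.
* The spectral library is synthetic; nothing here calibrates against
  field spectra.
* The two-endmember model has no shade term; strongly shadowed water or
  sun-glint outside the seawater-endmember span will bias fractions.
* Trend inference is conditional on the selected AR order; order
  selection uncertainty is not propagated (the calibration simulations
  quantify the net effect at typical series lengths).
* GeoJSON cell grids assume axis-aligned rectangular cells in a projected
  plane with an equirectangular geographic anchor; no reprojection is
  performed.
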