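---
title: "Graph-based imputation of monitoring-network time series: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-based imputation of monitoring-network time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ozimpute)
```

This vignette is the package's account of its science: the models it fits,
the parameters that matter, what the synthetic generator emulates, the
numerical conventions, and the design choices made where more than one
reasonable option existed. It states no empirical number that the test suite
or `scripts/acceptance.R` does not itself compute.

## 1. Data model

An hourly concentration panel is a stations × hours matrix in ppb with
explicit missingness (`series_panel`). Timestamps are timezone-naive
wall-clock hours on a strict hourly grid; leap days are handled through
`day_of_year ≤ 366`. A *gap* is a maximal run of consecutive missing hours,
classified as

* `short_single` — 1–5 h at one station (instrument calibration scale),
* `long_single` — ≥ 6 h at one station (outages up to months),
* `multi_station` — hours at which **every** station is missing
  (transmission failures).

The boundary sits between 5 and 6 h because the linear interpolator's tuned
threshold for hourly ozone is `L_t = 6` (gaps strictly shorter than `L_t`,
i.e. up to 5 h, are interpolated). Partial network outages remain
single-station gaps; only literally network-wide hours form the third class.
A single-station run touching a network-wide block is split at the block
boundary, so every missing cell belongs to exactly one record; runs without
an observed value on one side (panel edge or adjacent network-wide block) are
flagged unbounded, and the interpolator skips them because a line needs two
endpoints.

Each (station, hour) carries a fixed 19-dimensional auxiliary vector
(`feature_names()`): hour of day, day of week, day of year; temperature,
relative humidity, cloud cover, boundary-layer height, wind components u and
v; reanalysis O₃, NO and NO₂; NOₓ emissions; altitude, relative altitude,
population density, nightlight, and integer-encoded station and area types
(background/industrial/traffic and rural/suburban/urban as 1/2/3 — trees and
Euclidean distances need numbers, and the codebook is documented here because
the encoding is otherwise arbitrary).

## 2. Base imputers

* **Spatiotemporal mean** (`impute_spatiotemporal_mean`): every gap gets the
  mean of all observed values. Zero variance across imputations, hence
  R² = 0 by construction — the floor any serious method must beat.
* **Spatial mean** (`impute_spatial_mean`): the mean over stations observed
  at that hour; where no station reports (network-wide outages) a per-hour
  reference series — in practice a network-mean reanalysis concentration —
  fills in. Captures the cycles, ignores station identity.
* **Linear interpolation** (`interpolate_linear`): the line through the
  observed endpoints of a bounded gap shorter than `L_t`. Exact on locally
  affine signals; degrades with gap length because it knows nothing of the
  diurnal cycle.
* **Nearest neighbor** (`impute_nearest_neighbor`): the measured value of
  the labeled sample nearest in standardized Euclidean feature space. The
  hybrid (`impute_nnh`) dispatches on `L_t` between this and interpolation.
* **Reference field** (`impute_reference_field`): the value of the
  spatially nearest grid cell at the temporally nearest reference step of a
  coarse gridded field.
* **Random forest** (`impute_random_forest` / `fit_rf`): `ranger` regression
  forest mapping features to ppb. The reference configuration is 500 trees;
  the tuned maximum depth on the full-scale panel is 15. `max_depth = 0`
  denotes a root-only tree (training mean), `Inf` unlimited depth.

Hyperparameter procedures mirror standard practice: `tune_lt` scans
`L_t ∈ {1..12}` in 1-h steps against validation RMSE; `tune_depth` searches
downward from unlimited depth for the largest depth at which training and
validation RMSE agree — "agree" is made numeric as a relative difference
≤ 2% of the validation RMSE, since exact equality never occurs;
`forward_feature_selection` greedily adds the feature with the best
validation metric and stops at the first non-improvement. The selection
metric is validation RMSE with strict improvement (the alternative, R², is
exposed via the `metric` argument); on the synthetic generator this drops
the deliberately uninformative reanalysis-NO channel.

Standardization (`standardize_features`) uses the fitting subset's mean and
sample (n−1) standard deviation only — when test predictions are produced,
the scaler is fit on training+validation rows — to avoid leaking held-out
statistics. Zero-variance features standardize to 0. Nearest-neighbor ties
break toward the smallest sample index for determinism.

## 3. The spatiotemporal graph

Nodes are (station, hour) pairs, indexed station-major to match the feature
table. An edge exists iff the stations are ≤ 50 km apart (great-circle,
sphere radius 6371 km) **and** the hours differ by ≤ 6 h, both inclusive:
50 km is the distance at which the areas of influence of two stations still
overlap, and ozone varies on hourly scales. Weights come from a pluggable
distance-decay kernel; the default is

\[ w(\Delta x, \Delta t) = \frac{1}{(1 + \Delta x / d_{\max})\,(1 + \Delta t / t_{\max})}, \]

maximal (1) at zero separation and strictly decreasing in each argument. Any
global rescaling of the weights cancels in the normalized adjacency
`S = D^{-1/2} A D^{-1/2}`, so the kernel's overall scale is immaterial to
propagation; the kernel argument exists so an alternative decay can be
dropped in without touching the builder. Every node has a self-loop of
weight `w(0,0)`, which keeps all degrees positive (no division by zero in
`D^{-1/2}`) and lets a node retain its own signal during propagation.

The adjacency is one symmetric sparse `dgCMatrix`; construction and
matrix-vector application are linear in the edge count. At the package's
study scale (30 stations × 2160 h ≈ 65k nodes, ≈ 6M stored entries) build
time is a few seconds and one propagation sweep is ~10 ms. This
representation is comfortable to about 10⁵–10⁶ nodes / 10⁸ entries in 8 GB;
beyond that the natural strategy — since edges never span more than
`t_max` hours — is to materialize the adjacency in overlapping time bands of
width `L·t_max` and sweep bands sequentially, at the cost of re-entering
boundary values between bands. The package documents rather than implements
that banded mode, because the sparse matrix covers every scale the package
itself generates.

## 4. Correct and smooth for regression

The classification algorithm is adapted by using a single output channel and
no softmax. Both stages use the same anchored recursion

\[ v^{(l+1)} = (1-\alpha)\,v^{(0)} + \alpha\, S\, v^{(l)}, \qquad v^{(L)} \text{ returned}, \]

whose iterates stay bounded by \(\lVert v^{(0)}\rVert/(1-\alpha)\) (geometric
series; `S` has spectral radius ≤ 1) and which is linear in `v^(0)` — both
properties are tested against dense-matrix oracles at 10⁻¹⁰ tolerance.

**Correct.** `e⁰` holds the base model's residuals on labeled nodes and 0
elsewhere; `E = propagate(e⁰, S, α₁, L₁)`; the corrected prediction is
`ŷ + γE` (`fixed_gamma` mode, the literal reading) or, in `autoscale` mode,
`ŷ + sE` with `s` chosen so the mean absolute correction on unlabeled nodes
equals the mean absolute training residual — the rescaling damps the
influence of training nodes on unlabeled nodes with the number of hops.
`fixed_gamma` with a tuned γ is the default; autoscale is exposed because it
is the variant that matters when corrections must not amplify far from
labels.

Residuals need base predictions *at labeled nodes*. Each imputer therefore
reports fitted values beyond the gap cells: the mean imputers use the same
mean, the random forest uses out-of-bag predictions on training rows (an
honest error estimate; in-sample predictions of a deep forest are
near-perfect and would silence the correction), and the interpolation and
nearest-neighbor imputers report the observation itself (zero residual —
for those bases correct-and-smooth reduces to the smooth stage).

**Smooth.** `G⁰` equals the measurements on labeled nodes and the corrected
predictions elsewhere; the same propagation with (α₂, L₂) yields the final
values, which are written back to gap cells only — observed cells are never
modified, and filled values are clipped at 0 ppb as concentrations.

**Tuning.** `tune_cs` grid-searches validation RMSE. The tuned values for
the original full-scale application are not transcribable from the main
text, so the default grid is the package's own: α₁ = 0.8, L₁ = L₂ = 20,
γ ∈ {0, 0.5, 1} and autoscale, α₂ ∈ {0.5, 0.8}, plus the do-nothing
configuration (L₁ = L₂ = 0, γ = 0). Including do-nothing guarantees the
selected configuration never loses to the base imputer on validation; the
search caches the propagated error vector across grid points sharing
(α₁, L₁), so the whole grid costs little more than one propagation per
distinct setting. Ties go to the first grid point.

## 5. The synthetic generator

The generator (`synthetic_config`, `simulate_network`) emulates the
statistical regime the method targets, with every default configurable:

* 30 stations uniform in a 300 km square around 51°N 10°E, mapped to
  coordinates with the same spherical radius as the distance function so
  planar and great-circle distances agree; log-normal altitude and
  population density, nightlight increasing with population, categorical
  station/area types.
* 2160 hourly steps (90 days): long enough for day-scale gap buckets and a
  seasonal trend segment, small enough that the full 10-seed ranking
  experiment runs on one CPU in minutes. Monte-Carlo checks of the field's
  correlation structure use 2 stations × 10⁴ hours instead.
* Concentrations `base + seasonal + diurnal + r(s,t) + noise`, clipped at 0:
  base 30 ppb, seasonal and diurnal amplitudes 10 ppb (peaks in late July
  and at 15:00), residual field `r` zero-mean Gaussian with exponential
  spatial covariance (sd 8 ppb, e-folding length 100 km — comfortably above
  the 50 km edge rule, so neighbors carry signal) and stationary AR(1)
  hourly persistence φ = 0.95; white noise 2 ppb.
* Features: noisy affine transforms of the latent cycles and field.
  `reanalysis_o3` is deliberately *coarse*: cycles plus a 150 km
  kernel-smoothed version of `r`, a smooth spatial bias, and noise. A
  feature-based model therefore resolves the regional signal but not the
  station-scale residual, which remains spatially correlated in its errors —
  exactly the structure the correct step exploits, and the regime any
  real reanalysis-fed model sits in. `reanalysis_no` is pure noise so
  forward selection has something to drop.
* Gaps: 15% of cells, split 17/57/26 between the three classes. Short
  lengths uniform on 1–5 h; long lengths log-uniform on 6 h to
  `n_hours/20` (the cap keeps equal-length masked counterparts placeable
  between network-wide blocks; at 90 days the longest gaps are ~4.5 days);
  network-wide lengths from a {3, 4, 18, 43} h mixture echoing observed
  simultaneous outages. Placements keep a 1-h separation so every injected
  run is maximal and gap detection inverts the injection exactly.

What the generator does **not** emulate: chemistry (NOₓ titration,
precursor dependence), advective transport and wind direction, terrain
effects, instrument drift, or missingness that depends on the concentration
itself (NMAR). Passing tests therefore demonstrate the machinery and the
qualitative method ranking under a known, favorable-but-plausible
correlation structure; they do not certify accuracy numbers for any real
network.

## 6. Evaluation protocol

70% of all cells train the models; 15% are masked (half validation, half
test) and 15% remain genuinely missing. Masking preserves gap structure: for
every real gap record, one counterpart run of the same length and class is
placed uniformly at random among feasible positions (greedily balanced
between validation and test by cell count within class), so the masked
length histogram per class equals the real one exactly. One counterpart per
real record — rather than one per set — is what makes the masked total match
the 15% missing budget and the 70/7.5/7.5/15 accounting.

Network-wide counterparts are placed on hour runs clear of real or masked
network-wide blocks, and the cells actually observed there are masked and
scored. Requiring *every* station to be observed across an 18–43 h window
would be infeasible once 15% scattered missingness exists (the probability
is effectively zero at any realistic network size), so partial coverage is
accepted and only truly held-out cells enter the metrics.

Metrics are the coefficient of determination R², RMSE in ppb, and Willmott's
index of agreement d, each computed by *pooling* the masked cells of a
bucket (buckets: 1 h, 2 h, 3–5 h, 6–23 h, 1–6 days, ≥ 7 days; single- and
multi-station scopes separately) rather than averaging per-gap scores —
the metric definitions are written over samples, and pooling keeps small
buckets well-defined. The truth mean in R² and d is the mean over the
evaluated bucket. Degenerate buckets (n < 2 or zero truth variance) report
`NA` for the variance-based metrics rather than a fabricated value.

`repeat_splits` re-runs mask → impute → evaluate over seeds and reports the
min/max range; the stability test tunes hyperparameters once on a separate
split and then scores all masked cells of ten resplits, mirroring the
tune-once-then-resplit protocol.

## 7. Numerical conventions and edge cases

Double precision throughout; propagation oracle tolerance 10⁻¹⁰. All
randomness flows through per-operation sub-seeds of one user seed, and every
simulator and split operation restores the caller's RNG state. Nearest
reference-time ties resolve to the earlier step; nearest-neighbor distance
ties to the smallest sample index; grid-search ties to the first grid point.
Imputed concentrations are clipped at 0. A panel with a single station
cannot have network-wide gaps by definition. The daily 8-h exceedance metric
(`count_exceedances`, threshold 70 ppb) takes, per day, the maximum over the
24 running 8-h means whose window *starts* that day (windows may cross
midnight; any window with a missing hour is skipped); this convention is
configurable since the metric's name fixes the statistic but not the window
anchoring, and counts are monotone in the imputed values.

## 8. Known limitations

* The graph is static and isotropic: no wind direction, no time-resolved
  edges, no learned structure.
* Single pollutant; multi-pollutant nodes would need typed labels.
* The nearest-neighbor imputer reports zero training residuals, so
  correct-and-smooth can only smooth, not correct, that base.
* The combined pipeline's accuracy on real networks depends on feature
  quality (above all the reanalysis channel) in ways the synthetic
  generator can suggest but not prove.
* At desk scale the evaluation sets are thousands, not hundreds of
  thousands, of cells; bucket metrics carry visible sampling noise, which
  is why the robustness checks are ranges and sign tests rather than tight
  point values.
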