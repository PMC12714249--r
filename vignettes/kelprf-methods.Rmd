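---
title: "Methods: terrain, SST compositing and Monte Carlo forest ensembles in kelprf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: terrain, SST compositing and Monte Carlo forest ensembles in kelprf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kelprf)
```

`kelprf` classifies 30 m seafloor cells into four benthic cover classes
(bare, kelp, mixed, red turf) by combining bathymetry-derived terrain
attributes with summer sea-surface-temperature (SST) composites in a Monte
Carlo ensemble of random forests, and maps the ensemble's per-cell votes
into a nine-category confidence raster. This vignette documents the model,
its tunable parameters, the synthetic data the package tests itself
against, and the numerical conventions chosen where the problem is
genuinely open.

## The classification model

The response is a four-level factor observed at drop-camera locations; the
predictors are co-registered raster layers sampled at each observation's
30 m cell. A single random forest would already give OOB error estimates,
but a one-shot 70/30 split makes the external validation accuracy — and
especially per-class F1 — hostage to one arbitrary draw when classes have
only 45–80 observations. The package therefore repeats the whole exercise
`n_sim` times (default 175): simulation *i* seeds the RNG with
`base_seed + i`, draws a simple random 70/30 training/validation split,
fits a forest, and records

* training accuracy = 1 − OOB error (no hold-out needed),
* validation accuracy on the 30% external set,
* one-vs-rest precision, recall and F1 per class, with F1 = 2PR/(P+R)
  defined as 0 when P + R = 0,
* permutation importance (mean decrease in accuracy on OOB cases,
  averaged over trees), per class and model-wide, in raw percentage
  points.

Cross-simulation summaries are arithmetic means and standard deviations.
Two conventions deserve emphasis because they change the numbers:

* **F1 is averaged per simulation, then across simulations.** The F1 of
  the mean precision and recall is a different (slightly larger) number;
  the tests pin the convention with a constructed two-simulation example.
* **Importance is unscaled** (not divided by its standard deviation
  across trees). Scaled and unscaled variants rank variables similarly
  but are numerically incomparable; raw accuracy decrease has intelligible
  units.

The gap between mean training and mean validation accuracy is the
overfitting diagnostic: under i.i.d. simple random splits both estimate
generalization accuracy, so a persistent positive gap flags leakage or
optimistic OOB behavior. Note the caveat: ground-truth cells from one
camera drop are spatially adjacent, and the default split ignores that
grouping (deliberately, to match the reference field protocol). A
group-aware split is available (`mc_params(group_by_drop = TRUE)`) for
judging how much drop-level autocorrelation inflates the estimates.

Forest hyperparameters default to `ntree = 215`, `mtry = 6`,
`nodesize = 1`, unlimited `maxnodes`; `tune_hyperparameters()` sweeps any
of them (plus `n_sim`) over reduced Monte Carlo runs for plateau
inspection. The learner itself is `randomForest`; the package deliberately
does not re-implement CART/bagging.

## Terrain attributes

All terrain operations work on elevation = −depth, so "ridge" and
"convex-up" refer to shoal crests.

* **Slope/aspect** (Horn 3×3): slope in degrees from horizontal; aspect in
  degrees clockwise from grid north, the direction of steepest descent.
  Cells with zero gradient take a flat sentinel (−1) rather than an
  arbitrary angle, and their northness/eastness are both 0 — the sentinel
  must never reach `cos`/`sin`, and a flat cell has no meaningful
  direction. Border cells and cells adjacent to nodata are nodata.
* **Mean curvature** (Zevenbergen–Thorne): −(z_xx + z_yy)/2, scaled per
  100 m by default (`curvature_scale`), positive = convex-up. The 3×3
  quadric interpolates the window exactly, so the implementation's central
  differences are tested against an independent 9-term polynomial solve.
* **VRM**: resultant length of unit normals over a `vrm_window` (default
  3 cells ≈ one 12–15 m neighborhood at 4–5 m resolution). The denominator
  is the count of *valid* cells in the window, so nodata does not bias
  ruggedness upward; flat cells contribute (0, 0, 1).
* **Geomorphons**: in each of 8 compass directions the maximum upward and
  downward line-of-sight angles within `geomorphon_lookup` cells are
  compared against `flatness_angle` (default 2.5°), coding the direction
  +/0/−; the (+, −) count pair indexes the standard ten-form landform
  table, collapsed to six forms (peak and spur → ridge, pit and hollow →
  valley). Ties between equal upward and downward angles above the
  threshold code "+" — a fixed, documented tie-break. Directions with no
  visible cell (grid edge, nodata) count as level, so edge cells are still
  classified; only nodata centers are nodata. The lookup distance is not a
  settled community constant, so it is exposed as a parameter
  (default 10 cells) rather than hard-coded; the same goes for applying
  the flatness angle symmetrically to both angle senses, which this
  implementation does.

One-hot encoding turns the six forms into 0/1 layers that partition valid
cells. Aggregation to the analysis resolution assigns each fine cell to the
coarse cell containing its center — this supports non-integer resolution
ratios such as 4 m → 30 m — with means for continuous layers and majority
(fraction ≥ 0.5 → 1) for indicators; a coarse cell with no valid fine cell
is nodata.

## SST compositing

Scenes carry Kelvin temperatures plus a QA bitmask (bit 0 cloud, bit 1
cloud shadow — a simplified semantics defined by this package, not a
Landsat decoder). Processing order follows the field workflow: mask QA
bits, reject scenes whose masked fraction over the AOI *strictly exceeds*
25% (a scene at exactly 25% is retained — "greater than" read literally),
convert to °C, then reduce per cell to mean, median (midpoint rule for
even counts), sample standard deviation (n − 1; scene counts per cell are
small, ≤ 16) and range. Cells with fewer than `min_obs = 3` valid
observations are nodata in all four layers: with one or two observations a
standard deviation is meaningless, and field workflows rarely state a
per-cell minimum, so a conservative configurable default is used.
Scene order and fully clouded scenes provably do not affect the result.

## Stack assembly and collinearity screening

The analysis mask is the AOI ∩ (depth ≥ 1 m) ∩ all-layers-valid; the 1 m
floor removes land and intertidal cells relative to the MLLW-style datum.
The screen computes Pearson r for all continuous-layer pairs on one shared
random sample of 10 000 masked cells (one draw, not per pair). Any pair at
|r| ≥ 0.7 loses its later-priority member, iterating until no retained
pair violates the threshold — which makes screening idempotent. The
priority list encodes the outlier-robustness argument explicitly: median
over mean, standard deviation over range, and depth/terrain variables
never dropped by default. One-hot layers are exempt (binary indicators;
Pearson r is not a meaningful redundancy measure for them), and a constant
layer yields an undefined r that is recorded as not-collinear with a
warning rather than silently dropped.

## Vote-threshold mapping

Each simulation's forest classifies every masked cell; per-forest winners
are taken from the forest's own tree-vote matrix with a deterministic
first-level tie-break (the learner's default class output breaks ties at
random, which would make maps irreproducible). With plurality fraction f
over `n_sim` votes: f ≥ 0.75 → high confidence, 0.50 ≤ f < 0.75 → low
confidence, f < 0.50 or a tied plurality → no-majority. Both boundaries
are inclusive for their tier; at `n_sim = 175` a fraction of exactly 0.75
cannot occur, but the convention matters for other ensemble sizes. Ties
are never resolved in favor of a class. The map is masked to a 50 m depth
limit (a generous envelope for the relevant macroalgae), and the cover
table reports percentages over mapped (non-nodata) cells only — cells with
missing predictors inside the depth envelope are excluded from
denominators.

## The synthetic scene generator

The generator exists so every stage has a testable input with known
answers. It emulates:

* **Bathymetry** (default 1200 × 1200 cells at 5 m): a smooth random depth
  field with a fixed 100 m correlation scale plus a *spatially varying
  small-scale roughness* component and Gaussian island shoals. The split
  into large-scale relief (25 m amplitude) and independent roughness
  (1.5 m) matters: it keeps ruggedness from being a deterministic function
  of slope, as it would be in a single smooth field, so the collinearity
  screen sees realistically distinct terrain variables. Defaults span
  intertidal (< 1 m) through > 50 m cells. The 5 m → 30 m ratio is an
  integer (6) so aggregation tests are exact; the aggregation operation
  itself supports non-integer ratios.
* **Thermal scenes** (default 16, matching a five-summer Landsat-style
  collection): a shared spatial pattern (latitudinal gradient + mild
  shallow-water warming), per-scene offsets whose local amplitude varies
  smoothly in space (so per-cell sd and range share one spatial driver,
  as temporal SST variability does in coastal waters), per-pixel noise,
  and blob-shaped cloud/shadow QA regions whose AOI fractions are spread
  evenly across `cloud_fraction_range`.
* **Ground truth** (default 61 drops of 2–5 contiguous cells, class
  weights 79/77/45/46 of 247): drops are 4-connected random walks on
  eligible cells, emulating a drifting camera frame; labels follow a
  multinomial-logit rule on z-scored (depth, VRM, median SST) with Gumbel
  utility noise (`noise_scale`, default 0.15) and intercepts calibrated by
  a softmax fixed point so realized class frequencies track the weights.
  The default coefficients encode the ecological structure the package is
  designed to detect: bare on smooth low-ruggedness sediment, kelp deeper
  and cooler, red turf shallower and warmer, mixed in between; their
  magnitudes are set so the signal is strongly recoverable, which is what
  the recovery tests rely on.

Everything is a pure function of the configuration (including its seed).
What the generator does **not** emulate: tides and datum subtleties, real
Landsat QA semantics and revisit timing, spatial autocorrelation of
habitat classes beyond the drop-cluster rule, label error correlated with
terrain, and any backscatter information. Passing recovery tests therefore
demonstrates that the pipeline's plumbing and estimator are sound — not
that real Gulf of Maine habitats are classifiable at any particular
accuracy.

## Numerical conventions and degenerate inputs

* Flat aspect sentinel −1; northness = eastness = 0 on flat cells.
* VRM is clamped to [0, 1] against floating-point drift and is exactly 0
  on planes (asserted to 1e−12).
* All-nodata depth input is an error; an empty post-rejection scene
  collection degrades to all-nodata SST with a warning (the `min_obs`
  rule then masks everything downstream).
* A Monte Carlo split that loses a class entirely is redrawn with a
  warning (possible for the 45-observation class under simple random
  splits); a stratified option exists but is off by default to match the
  reference protocol.
* Training rows are canonically re-ordered before simulation so metrics
  are invariant to incoming row order under a fixed seed.
* Determinism is contractual within one package version; forests depend
  on the learner's RNG stream, so cross-version bit-identity is not
  promised.

## Problem sizes used by the test suite

Unit tests run on grids from 3 × 3 hand cases to 32 × 32 oracle
comparisons (5 random grids per operation) and a 360 × 360-cell fine scene
(60 × 60 analysis cells) for pipeline-level checks. The signal-recovery
check uses the full default scene — 1200 × 1200 fine cells, 200 × 200
analysis cells, ~31 000 masked cells, ~210 ground-truth records — with a
50-simulation ensemble, a size chosen to exercise realistic spatial
structure while keeping a complete test run around a minute on one CPU.
`scripts/acceptance.R` repeats that full-scene run from scratch at a
caller-supplied seed.

## Known limitations

* No geospatial CRS handling: grids are planar with a square cell size;
  I/O is Esri ASCII grid. Reprojection and GeoTIFF belong upstream.
* The collinearity screen is pairwise Pearson only (no VIF or clustering
  alternatives), matching the reference workflow.
* Geomorphons use a single lookup distance (no multi-scale search) and
  the six-form collapse is fixed.
* The ensemble ignores spatial autocorrelation between validation and
  training cells from the same drop unless `group_by_drop` is enabled;
  accuracy estimates under the default split should be read accordingly.
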