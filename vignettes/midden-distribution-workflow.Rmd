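---
title: "Methods: midden distribution modelling from LIDAR and disturbance layers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: midden distribution modelling from LIDAR and disturbance layers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its methods: the occurrence
model and its assumptions, the synthetic landscape the tests run on, the
numerical conventions, and the design decisions taken where the workflow was
genuinely open.

## The modelling problem

Red squirrel middens are persistent cone caches that mark occupied
territories. Given (a) a classified LIDAR point cloud, (b) five digitized
feature classes (lake, ski/walking trails, winter dog trail, highway,
buildings) and (c) a census of midden locations in a study polygon, the
pipeline estimates a 0–1 relative index of occurrence (RIO) for every
3 × 3 m cell, classifies the area into occupied/unoccupied, and converts
midden counts and areas into density, territory-size and population
estimates. The RIO is deliberately *not* treated as a calibrated
probability: presences are a census but absences are random background
points, so only the ranking and relative structure of the scores carry
meaning.

## Predictor construction

Ten aligned rasters are built on one north-up, square-cell grid (row 1 is
the northernmost row; cells are half-open so a point on a shared edge
belongs to the cell to its east/south and is counted exactly once):

* **DEM** — mean z of ground returns per cell. The aggregation rule (mean) is
  this package's choice; at ~13 ground returns per 9 m² cell the mean is
  robust and smooth. Cells without ground returns are filled by
  inverse-distance weighting from the `k = 8` nearest filled cells, because
  the model requires a complete predictor stack.
* **Canopy height** — max z of vegetation returns per cell minus the cell's
  DEM value, floored at 0. Above-ground referencing is required for the
  canopy-height response threshold (≈9 m) to be meaningful; cells without
  vegetation returns are genuinely open and get 0, not no-data.
* **Canopy density** — vegetation returns / all returns per cell, in [0, 1].
  Unclassified returns are merged into the vegetation class first, since
  provider classification typically leaves much of the canopy unclassified.
* **Slope/aspect** — Horn 3 × 3 finite differences with replicated borders.
  Aspect is the compass bearing of steepest descent in degrees clockwise
  from north; flat cells are coded −1 and aspect is fed to the trees as raw
  degrees. The circular discontinuity at 0/360 is a known limitation, but it
  mirrors how GIS aspect layers are normally consumed by tree ensembles, and
  trees can split around it.
* **Distance layers** — each feature class is rasterized (every cell touched
  by the geometry is a source cell) and each cell receives the Euclidean
  distance between cell centres to the nearest source cell. This matches
  raster-GIS "Euclidean distance" semantics; it differs from exact
  vector-geometry distance by at most one cell diagonal (≈4.24 m at 3 m
  cells), which is below the GPS accuracy of the emulated surveys.

## Training data

The data cube holds one row per point: the midden presences (label 1) and
`n_absence = 600` uniform random points in the study polygon (label 0), with
every predictor extracted by nearest-cell lookup (no interpolation, matching
the extraction-tool semantics the workflow emulates). Weights balance the
classes exactly: absences carry weight 1, presences carry
`n_absence / n_presence`, so both classes contribute equal total weight to
the loss. No minimum distance between absences and presences is enforced by
default (the emulated design treats its absences as near-real absences
because the presence survey was a census); an optional `min_dist` filter
exists for sensitivity analyses. The pipeline log reports the realized
background sampling density in points per hectare rather than asserting any
nominal value.

## The boosted occurrence model

`rio_boost()` implements stochastic gradient boosting with binomial deviance
loss from first principles (the tree growth and traversal are in C++):

* `F0` is the logit of the weighted prevalence (0 under balanced weights).
* Iteration *m* computes residuals `r = y − p`, draws a random `subsample`
  fraction of rows without replacement, and grows a regression tree on the
  residuals by exact greedy search over all features and all midpoints
  between consecutive distinct sorted values, maximizing the weighted
  squared-error reduction. Ties go to the lowest feature index, then the
  lowest threshold, making fits deterministic.
* Leaf values are Newton steps `sum(w·r) / sum(w·p·(1−p))` over the leaf's
  subsample rows (0 when the curvature sum falls below 1e−12); the ensemble
  updates all rows by `shrinkage` times the tree.

Tunable parameters, defaults, and why:

| parameter | default | rationale |
|---|---|---|
| `n_trees` | 400 | the emulated modelling setup's ensemble size |
| `max_depth` | 10 | "node depth" read as maximum tree depth |
| `min_leaf` | 2 | minimum unweighted samples per terminal node |
| `shrinkage` | 0.01 | small, safe learning rate for 400 trees; the reference tool's internal default is undocumented, so this is the package's own choice, always logged |
| `subsample` | 0.5 | standard stochastic-gradient-boosting fraction; same caveat |

Variable importance sums each feature's split improvements (weighted SSE
reductions) over all trees and rescales the maximum to 100. Partial
dependence is computed brute force — every training row is re-scored with
the feature forced to each grid value — on the tree log-odds scale, centered
by the curve's grid mean, so only shape and zero crossings are
interpretable. Training (internal) AUC is the weighted Mann–Whitney
statistic; no cross-validation is performed because the workflow this
package reproduces reports internal ROC only, and with deep trees and tiny
leaves the internal AUC saturates near 1 — it should be read as a bound, not
an out-of-sample estimate.

## Surfaces, occupancy and abundance

The prediction lattice defaults to the predictor cell centres clipped to the
study polygon, so the subsequent inverse-distance interpolation
(`power = 2`, `k = 12` neighbours, both ordinary GIS defaults and both
exposed) is an exact identity at lattice cells and only genuinely
interpolates where the lattice is coarser or the polygon clipped a cell. The
occupancy threshold is the nearest-rank lower 5th percentile of presence
RIOs — the `k = ceiling(0.05 N)`-th smallest value — which is the only
reading of a "one-sided 95% interval of the presence values" that guarantees
the occupied class (closed inequality, `RIO ≥ t`) contains at least 95% of
presences; the retained fraction can exceed the target by at most `1/N`.

Abundance arithmetic is exact rational arithmetic with round-half-up applied
only for reporting (densities at 2 decimal places, occupied-area midden
density also reported at 1). The population range assumes one midden per
squirrel at the upper end and `1 + max_secondary` middens per squirrel at
the lower end, with `pop_low = floor(n / (1 + max_secondary))`; the
midden-to-squirrel ratio is ecologically unresolved, so `max_secondary`
(default 3) is a free parameter, not an estimate. Validation extracts the
RIO under each independent point and reports min/quartiles/mean/max (type-7
quantiles) and the fraction strictly above the mean scored-lattice RIO.

## The synthetic landscape generator

The generator is first-class, tested code: it is what makes every stage of
the pipeline testable and what provides ground truth for parameter-recovery
checks. It emulates the descriptive statistics of the surveyed area:

* an ~880 × 850 m bounding box (snapped down to whole 3 m cells, i.e.
  879 × 849 m) containing an irregular ~45.5 ha study polygon — the polygon,
  not the box, is where absences, lattices and middens live;
* elevation 145–190 m as Gaussian-smoothed white noise rescaled exactly to
  that range (any smooth autocorrelated field suffices; smoothing white
  noise is the simplest reproducible choice, bandwidth 60 m by default);
* canopy height in [0, 25] m, with a canopy density field coupled to height
  (tall stands tend to be denser) plus independent smooth structure, clipped
  to [0, 1]; an open meadow patch and the lake carry height 0 and density 0;
* a LIDAR cloud at 0.82 m (2.7 ft) ground spacing with ~4 cm vertical noise
  and per-cell Poisson vegetation returns proportional to density, 30% of
  them labelled `unclassified` (provider classification gaps are real but
  unquantified; 0.3 is the package's fixed emulation choice);
* the five feature classes in their qualitative positions: lake in the
  north, highway along the west edge, trails crossing the interior,
  buildings near the east edge;
* a midden point process: cell-wise Bernoulli draws with
  `p = plogis(intercept + sum of responses)`, where the responses are
  piecewise-linear functions with the threshold shapes the model is expected
  to recover — canopy height crossing zero at 9 m, trail distance with
  breakpoints at 10/30/50 m, canopy density crossing at 0.45, lake distance
  crossing at 250 m. The intercept is calibrated by root finding so the
  *expected raw* presence count is 198; the <10 m merge rule
  (`thin_middens`, greedy in deterministic y-descending/x-ascending order)
  is applied afterwards, exactly as the field protocol merges diffuse
  middens, so realized thinned counts land somewhat below 198.

What the generator does **not** emulate: GPS positioning error on midden
locations (presences sit exactly at cell centres), spatial interaction
between middens (no inhibition or clustering beyond the covariates),
forest-growth realism, or real georeferencing (a planar local CRS tag is
carried through unchanged). Because presences are error-free cell centres
among tens of thousands of background cells, deep trees can memorize them;
internal AUCs near 1.0 on synthetic runs therefore demonstrate capacity, not
real-world transferability — which is precisely why the acceptance checks
are phrased as bounds and recovery properties rather than point
reproduction.

One scale caveat matters for small test landscapes: a smoothing bandwidth of
tens of meters leaves only a handful of independent terrain/canopy patches
on a sub-hectare grid, and any two smooth fields then correlate strongly by
chance. Recovery experiments therefore scale the bandwidth down with the
extent (e.g. 9 m canopy bandwidth on the ~2000-cell recovery landscapes) so
the predictors retain enough independent variation for importance ranks to
be meaningful.

## Numerical conventions

* Half-open cell membership everywhere (east/south edge ownership); row 1
  is north; cell (r, c) centre at
  `(x0 + (c − 0.5)s, y0 − (r − 0.5)s)`.
* No-data is `NA`, never a sentinel value inside valid ranges; stacks must
  be gap-filled before extraction and extraction fails loudly otherwise.
* The nearest-rank threshold guards its `ceiling` against floating-point
  noise in `(1 − coverage) · N` with a 1e−9 tolerance.
* IDW treats a query within 1e−9 m of a data point as coincident and copies
  the value exactly.
* Split ties and thinning order are pinned (lowest feature/threshold;
  y-descending then x-ascending) so every stochastic stage is bit-for-bit
  reproducible given the seed; all randomness derives from a single seed per
  run, and model JSON is written at 17 significant digits so serialization
  round-trips exactly.
* Reported estimates round half-up, since printed survey summaries use
  commercial rounding.

## Problem sizes

The test suite exercises each gridding operation against brute-force oracles
on ≤ 30 × 30 grids, the boosting contracts on 200–500-row tables, parameter
recovery on three ~2000-cell landscapes, and the end-to-end reproducibility
harness plus the acceptance script on the full ~83,000-cell (50,530 within
the polygon) survey-scale landscape with 400-tree fits — sizes chosen so the
whole suite completes in a few minutes on a single core while still covering
the full survey scale.

## Known limitations

* Aspect enters as raw degrees with flat = −1; a circular encoding (sin/cos)
  would remove the 0/360 seam at the cost of diverging from the emulated
  GIS layer.
* Rasterized (cell-centre) distances, not exact vector distances; bounded
  error of one cell diagonal.
* Internal AUC only; no cross-validation or spatial block validation.
* The pseudo-absence design can place absences in occupied cells; on
  synthetic runs the stored truth makes that contamination measurable, and
  the optional `min_dist` filter allows sensitivity checks.
* The midden-to-squirrel conversion is a bound pair, not an estimator.
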