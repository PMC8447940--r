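# middensdm

High-resolution (3 × 3 m) distribution modelling of American red squirrel
(*Tamiasciurus hudsonicus*) middens from LIDAR-derived canopy/terrain rasters
and human-disturbance distance layers.

Red squirrels cache spruce cones in persistent middens, which makes middens a
durable, countable proxy for territory occupancy. This package implements, as
a tested and reusable R pipeline, the full workflow that turns a classified
LIDAR point cloud, a handful of digitized landscape features and a midden
survey into (i) a relative index of occurrence (RIO) surface, (ii) a binary
occupancy map, (iii) density/territory/population estimates and (iv) a
validation report against an independent point set. It is aimed at spatial
ecologists who want a transparent, fully scriptable alternative to the
GIS-plus-proprietary-machine-learning toolchain such workflows are usually
built on, and it ships a synthetic landscape generator with known response
functions so every stage can be tested end to end without field data.

## The model

The core is a stochastic gradient-boosted tree classifier (TreeNet/MART
family) for presence/pseudo-absence data. With binary labels $y_i$, case
weights $w_i$ balancing the classes, and predictors $x_i$ (canopy height,
canopy density, slope, aspect, elevation and Euclidean distances to lake,
trails, dog trail, highway and buildings), the fitted score is

$$\mathrm{RIO}(x) = \frac{1}{1 + e^{-F(x)}},\qquad
  F(x) = F_0 + \nu \sum_{m=1}^{M} T_m(x),$$

where $F_0$ is the logit of the weighted prevalence and each $T_m$ is a
depth-limited regression tree fit to the residuals $y_i - p_i$ on a random
half of the rows, with Newton leaf values
$\gamma = \sum w_i r_i / \sum w_i p_i (1-p_i)$. Defaults are $M = 400$ trees,
depth ≤ 10, ≥ 2 samples per leaf, shrinkage $\nu = 0.01$ and subsample 0.5.
The RIO is a relative index, not a calibrated probability.

Around the model sit the supporting stages: LIDAR gridding (DEM from ground
returns, canopy height/density from vegetation returns, Horn slope/aspect),
raster Euclidean distance transforms, uniform pseudo-absence sampling with
class-balancing weights, lattice scoring plus inverse-distance-weighted
interpolation to a full RIO raster, occupancy classification at the RIO
threshold that retains 95% of observed presences, and midden-count abundance
arithmetic.

## Worked example

A full synthetic survey at study scale — an ~880 × 850 m landscape with a
~45.5 ha study polygon, ~1.4 million LIDAR returns and a midden process
calibrated to ~198 expected presences — runs in under a minute:

```r
library(middensdm)

cfg <- run_config(landscape = landscape_config(seed = 1), seed = 1)
res <- run_pipeline(cfg, "demo_run", quiet = TRUE)

print(res$model)
#> rio_boost: 400 trees, depth <= 10, min leaf 2, shrinkage 0.01, subsample 0.5
#>   754 training rows, 10 features; F0 = 0.0000
#>   training deviance 1663.55 -> 382.22, training AUC 1.0000

print(res$occupancy)
#> occupancy_map: threshold 0.6952, occupied area 1.45 ha
#>   presences in occupied cells: 147 (95.5%)

print(res$abundance$whole_area)
#> abundance_estimate: 154 middens over 45.48 ha
#>   midden density: 3.39 / ha (339 / km^2)
#>   mean territory: 0.30 ha (one midden per squirrel)
#>   population: 38-154 squirrels (up to 3 secondary middens)
#>   density range: 0.84-3.39 squirrels / ha
```

The training rows are the 154 simulated middens (after the <10 m merge rule)
plus 600 random pseudo-absences. `summary(res$model)` prints the predictor
importance table (canopy height ranks first on this landscape), and
`plot(res$model)` draws partial-dependence curves; the canopy-height curve
turns positive near the generator's 9 m breakpoint. The occupancy threshold
is the empirical lower 5th percentile of presence RIOs, so ~95% of presences
fall in the occupied class by construction. Every artifact (predictor grids,
data cube, model JSON, scored lattice, RIO and occupancy rasters, abundance
and validation reports) is written to the run directory together with a
manifest of parameters and md5 checksums; rerunning the same configuration
reproduces every file bit for bit.

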