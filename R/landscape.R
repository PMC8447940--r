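# Synthetic study-area generator: terrain, canopy, human features, LIDAR
# returns and a midden point process with a known response model. Emulates the
# descriptive statistics of the surveyed area: ~880 x 850 m bounding box, a
# ~45.5 ha irregular study polygon, elevation 145-190 m, canopy up to ~25 m,
# LIDAR point spacing ~0.82 m (2.7 ft), and five disturbance/landscape feature
# classes (lake, trails, dog trail, highway, buildings).

#' Configuration of the synthetic landscape
#'
#' Collects every tunable parameter of the generator with defaults matching
#' the emulated study area. The raster bounding box is snapped down to whole
#' cells (`floor(extent / cell_size)` cells per axis).
#'
#' @param extent_x,extent_y Bounding-box side lengths in meters.
#' @param cell_size Raster cell size in meters (the analysis resolution).
#' @param elevation_range Two-vector, min and max terrain elevation (m).
#' @param max_canopy_height Upper bound of generated canopy height (m).
#' @param lidar_point_spacing Nominal ground-return spacing (m); 0.82 m is
#'   2.7 ft.
#' @param seed Integer seed; the same config and seed give bit-identical
#'   landscapes.
#' @param lake List with `center` (x, y) and `radius` (m) of the lake polygon
#'   in the north.
#' @param meadow List with `center` and `radius` (m) of an open treeless patch
#'   (canopy height and density forced to zero).
#' @param highway_offset Distance (m) of the north-south highway polyline from
#'   the west edge.
#' @param trails List of two-column vertex matrices for the ski/walking trail
#'   network.
#' @param dogtrail List of vertex matrices for the winter dog-walking trail.
#' @param buildings List of building rectangles, each `c(xmin, ymin, xmax,
#'   ymax)`; may be empty.
#' @param area_polygon Two-column ring of the study-area polygon (default
#'   ~45.5 ha inside the bounding box).
#' @param terrain_smooth,canopy_smooth Gaussian smoothing bandwidth (m) used
#'   to spatially autocorrelate the white-noise terrain and canopy fields.
#' @param ground_noise_sd Vertical noise of ground returns (m); the emulated
#'   survey reports ~0.08 m vertical accuracy at 95%.
#' @param veg_returns_per_cell Expected vegetation returns per cell at density
#'   1 (Poisson rate scale).
#' @param unclassified_fraction Fraction of vegetation returns labelled
#'   `unclassified`, emulating incomplete provider classification.
#' @param target_middens Expected midden count used to calibrate the response
#'   intercept (the emulated survey found 198).
#' @return An object of class `landscape_config`; `$grid` holds the implied
#'   [grid_spec()].
#' @export
landscape_config <- function(extent_x = 880, extent_y = 850, cell_size = 3,
                             elevation_range = c(145, 190),
                             max_canopy_height = 25,
                             lidar_point_spacing = 0.82,
                             seed = 1L,
                             lake = list(center = c(650, 780), radius = 65),
                             meadow = list(center = c(680, 560), radius = 70),
                             highway_offset = 15,
                             trails = NULL, dogtrail = NULL, buildings = NULL,
                             area_polygon = NULL,
                             terrain_smooth = 60, canopy_smooth = 24,
                             ground_noise_sd = 0.04,
                             veg_returns_per_cell = 8,
                             unclassified_fraction = 0.3,
                             target_middens = 198) {
  if (!is.numeric(cell_size) || cell_size <= 0) {
    stop("configuration error: cell_size must be strictly positive")
  }
  for (v in c(extent_x, extent_y, lidar_point_spacing, max_canopy_height,
              terrain_smooth, canopy_smooth, veg_returns_per_cell)) {
    if (!is.numeric(v) || length(v) != 1L || v < 0) {
      stop("configuration error: spatial parameters must be non-negative")
    }
  }
  if (lidar_point_spacing == 0) {
    stop("configuration error: lidar_point_spacing must be > 0")
  }
  if (unclassified_fraction < 0 || unclassified_fraction > 1) {
    stop("configuration error: unclassified_fraction must lie in [0, 1]")
  }
  nc <- max(1L, floor(extent_x / cell_size))
  nr <- max(1L, floor(extent_y / cell_size))
  W <- nc * cell_size
  H <- nr * cell_size
  if (is.null(trails)) {
    trails <- list(
      cbind(c(60, 300, 560, 820), c(120, 400, 300, 520)),
      cbind(c(100, 400, 700), c(700, 560, 680)),
      cbind(c(440, 400, 250), c(120, 560, 700))
    )
  }
  if (is.null(dogtrail)) {
    dogtrail <- list(cbind(c(60, 400, 820), c(200, 250, 230)))
  }
  if (is.null(buildings)) {
    buildings <- list(c(830, 300, 870, 340), c(830, 400, 868, 450),
                      c(835, 550, 872, 590))
  }
  if (is.null(area_polygon)) {
    # ~45.48 ha: 760 x 650 rectangle with a 280 m right-triangle cut in the NE
    area_polygon <- cbind(c(60, 820, 820, 540, 60),
                          c(100, 100, 470, 750, 750))
  }
  cfg <- structure(
    list(extent_x = W, extent_y = H, cell_size = cell_size,
         elevation_range = sort(as.numeric(elevation_range)),
         max_canopy_height = max_canopy_height,
         lidar_point_spacing = lidar_point_spacing,
         seed = as.integer(seed), lake = lake, meadow = meadow,
         highway_offset = highway_offset, trails = trails,
         dogtrail = dogtrail, buildings = buildings,
         area_polygon = area_polygon,
         terrain_smooth = terrain_smooth, canopy_smooth = canopy_smooth,
         ground_noise_sd = ground_noise_sd,
         veg_returns_per_cell = veg_returns_per_cell,
         unclassified_fraction = unclassified_fraction,
         target_middens = target_middens,
         grid = grid_spec(0, H, cell_size, nr, nc)),
    class = "landscape_config"
  )
  cfg
}

# run expr with the RNG seeded from (seed, stream) and the caller's RNG state
# untouched afterwards
with_seed <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((as.integer(seed) * 131L + as.integer(stream)) %% 2147483587L)
  expr
}

# Gaussian smoothing of a matrix by separable band-matrix convolution with
# per-row renormalized (truncated at 3 sigma) kernels; sigma in cells.
smooth_gaussian <- function(m, sigma) {
  if (sigma <= 0) return(m)
  band <- function(n) {
    r <- min(n - 1L, max(1L, ceiling(3 * sigma)))
    i <- matrix(seq_len(n), n, n)
    d <- i - t(i)
    k <- ifelse(abs(d) <= r, exp(-d^2 / (2 * sigma^2)), 0)
    k / rowSums(k)
  }
  band(nrow(m)) %*% m %*% t(band(ncol(m)))
}

rescale_range <- function(m, lo, hi) {
  rng <- range(m)
  if (hi == lo || rng[2] == rng[1]) {
    return(matrix(lo, nrow(m), ncol(m)))
  }
  (m - rng[1]) / (rng[2] - rng[1]) * (hi - lo) + lo
}

#' Generate smooth synthetic terrain
#'
#' Spatially autocorrelated elevation surface: Gaussian-smoothed white noise
#' rescaled exactly to `elevation_range`. Deterministic per config seed.
#'
#' @param config A [landscape_config()].
#' @return A [raster_grid()] of elevation in meters.
#' @export
generate_terrain <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  g <- config$grid
  vals <- with_seed(config$seed, 101L, {
    noise <- matrix(rnorm(g$nrow * g$ncol), g$nrow, g$ncol)
    smooth_gaussian(noise, config$terrain_smooth / config$cell_size)
  })
  vals <- rescale_range(vals, config$elevation_range[1], config$elevation_range[2])
  raster_grid(vals, g, "elevation", "m")
}

#' Generate canopy height and density fields
#'
#' A smoothed random canopy-height field in `[0, max_canopy_height]` with a
#' positively correlated density field in `[0, 1]`. Cells in the configured
#' open meadow and under the lake carry height 0 and density 0, as do cells
#' with height below 0.5 m.
#'
#' @param config A [landscape_config()].
#' @param elevation Elevation raster from [generate_terrain()] (carried for
#'   alignment; canopy is generated independently of elevation).
#' @return List with elements `height` and `density`, both [raster_grid()]s.
#' @export
generate_canopy <- function(config, elevation) {
  stopifnot(inherits(config, "landscape_config"))
  g <- config$grid
  if (!grids_aligned(g, elevation)) stop("alignment error: elevation raster")
  sig <- config$canopy_smooth / config$cell_size
  fields <- with_seed(config$seed, 202L, {
    list(h = smooth_gaussian(matrix(rnorm(g$nrow * g$ncol), g$nrow, g$ncol), sig),
         d = smooth_gaussian(matrix(rnorm(g$nrow * g$ncol), g$nrow, g$ncol), sig))
  })
  h <- rescale_range(fields$h, 0, config$max_canopy_height)
  dnoise <- rescale_range(fields$d, -0.5, 0.5)
  d <- if (config$max_canopy_height > 0) {
    # moderate height-density coupling: tall stands tend to be denser, but
    # density keeps independent structure of its own
    0.45 * h / config$max_canopy_height + 0.9 * dnoise + 0.35
  } else h * 0
  d <- pmin(pmax(d, 0), 1) # matrix first: pmin/pmax keep its dims
  cc <- cell_centers(g)
  cx <- matrix(cc$x, g$nrow, g$ncol, byrow = TRUE)
  cy <- matrix(cc$y, g$nrow, g$ncol)
  open_cells <- (cx - config$meadow$center[1])^2 +
    (cy - config$meadow$center[2])^2 <= config$meadow$radius^2
  open_cells <- open_cells | (cx - config$lake$center[1])^2 +
    (cy - config$lake$center[2])^2 <= config$lake$radius^2
  h[open_cells] <- 0
  d[open_cells] <- 0
  d[h < 0.5] <- 0
  list(height = raster_grid(h, g, "canopy_height", "m"),
       density = raster_grid(d, g, "canopy_density", "fraction"))
}

#' Generate the five landscape feature classes
#'
#' Lake polygon in the north, highway polyline along the west edge, a trail
#' network crossing the interior, a dog trail in the south, and building
#' rectangles near the east edge. All geometries are validated and must lie
#' inside the bounding box.
#'
#' @param config A [landscape_config()].
#' @return An object of class `feature_set`: named list with elements `lake`,
#'   `trails`, `dogtrail`, `highway`, `buildings`, each a (possibly empty)
#'   list of two-column coordinate matrices.
#' @export
generate_features <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  lake <- circle_ring(config$lake$center[1], config$lake$center[2],
                      config$lake$radius)
  highway <- list(cbind(c(config$highway_offset, config$highway_offset),
                        c(0, config$extent_y)))
  buildings <- lapply(config$buildings, function(b) {
    rect_ring(b[1], b[2], b[3], b[4])
  })
  fs <- structure(list(lake = list(lake), trails = config$trails,
                       dogtrail = config$dogtrail, highway = highway,
                       buildings = buildings),
                  class = "feature_set")
  for (cls in names(fs)) {
    for (geom in fs[[cls]]) {
      if (any(geom[, 1] < 0 | geom[, 1] > config$extent_x |
                geom[, 2] < 0 | geom[, 2] > config$extent_y)) {
        stop(sprintf("configuration error: %s feature outside extent", cls))
      }
    }
  }
  for (cls in c("lake", "buildings")) {
    for (geom in fs[[cls]]) {
      if (!polygon_is_valid(geom)) {
        stop(sprintf("configuration error: invalid %s polygon", cls))
      }
    }
  }
  fs
}

#' Generate a classified LIDAR point cloud
#'
#' Ground returns on a jittered regular grid at the configured point spacing,
#' with z equal to the local (cell) elevation plus vertical noise. Vegetation
#' returns are drawn per cell with Poisson-expected count
#' `density * veg_returns_per_cell`, z uniform between the ground and the
#' local canopy height. A configured fraction of vegetation returns is
#' labelled `unclassified` to emulate provider data.
#'
#' @param config A [landscape_config()].
#' @param elevation,height,density Aligned rasters from [generate_terrain()]
#'   and [generate_canopy()].
#' @return A data.frame with columns `x`, `y`, `z` (m) and `class` in
#'   `{ground, vegetation, unclassified}`.
#' @export
generate_point_cloud <- function(config, elevation, height, density) {
  stopifnot(inherits(config, "landscape_config"))
  g <- config$grid
  for (r in list(elevation, height, density)) {
    if (!grids_aligned(g, r)) stop("alignment error: rasters must match config grid")
  }
  s <- config$lidar_point_spacing
  if (s <= 0) stop("configuration error: lidar_point_spacing must be > 0")
  with_seed(config$seed, 303L, {
    gx <- seq(s / 2, config$extent_x - s / 4, by = s)
    gy <- seq(s / 2, config$extent_y - s / 4, by = s)
    pts <- expand.grid(x = gx, y = gy)
    n <- nrow(pts)
    px <- pmin(pmax(pts$x + runif(n, -0.3 * s, 0.3 * s), 0), config$extent_x - 1e-9)
    py <- pmin(pmax(pts$y + runif(n, -0.3 * s, 0.3 * s), 0), config$extent_y - 1e-9)
    cells <- point_cell(g, px, py)
    gz <- elevation$values[cbind(cells$row, cells$col)] +
      rnorm(n, 0, config$ground_noise_sd)
    ground <- data.frame(x = px, y = py, z = gz, class = "ground",
                         stringsAsFactors = FALSE)

    lambda <- density$values * config$veg_returns_per_cell
    lambda[height$values <= 0] <- 0
    counts <- rpois(length(lambda), lambda)
    idx <- which(counts > 0)
    veg <- NULL
    if (length(idx)) {
      reps <- counts[idx]
      rows <- rep(((idx - 1L) %% g$nrow) + 1L, reps)
      cols <- rep(((idx - 1L) %/% g$nrow) + 1L, reps)
      m <- length(rows)
      vx <- g$origin_x + (cols - 1L) * g$cell_size + runif(m, 0, g$cell_size)
      vy <- g$origin_y - (rows - 1L) * g$cell_size - runif(m, 0, g$cell_size)
      ve <- elevation$values[cbind(rows, cols)]
      vh <- height$values[cbind(rows, cols)]
      vz <- ve + runif(m, 0, 1) * vh
      cls <- ifelse(runif(m) < config$unclassified_fraction,
                    "unclassified", "vegetation")
      veg <- data.frame(x = vx, y = vy, z = vz, class = cls,
                        stringsAsFactors = FALSE)
    }
    rbind(ground, veg)
  })
}

#' Midden response model with known truth
#'
#' Per-predictor piecewise-linear response functions on the log-odds scale,
#' with the threshold shapes the distribution model is expected to recover:
#' canopy height crossing zero near 9 m, trail distance with breakpoints near
#' 10/30/50 m, canopy density crossing near 0.45, and lake distance crossing
#' near 250 m. Responses are linearly interpolated between knots and held
#' constant beyond the outer knots, so they are finite everywhere.
#'
#' @param intercept Baseline log-odds; `NA` means "calibrate to the target
#'   midden count" inside [simulate_middens()].
#' @param responses Named list of two-column `(x, y)` knot matrices; names
#'   must match predictor-stack layer names. Pass only a subset to activate
#'   only some responses.
#' @return An object of class `response_truth`.
#' @export
response_truth <- function(intercept = NA_real_, responses = NULL) {
  if (is.null(responses)) {
    responses <- list(
      canopy_height = cbind(c(0, 9, 25), c(-1.5, 0, 1.5)),
      dist_trails = cbind(c(0, 10, 30, 50), c(-1.2, 0, 0.7, -0.3)),
      canopy_density = cbind(c(0, 0.45, 1), c(-1.0, 0, 1.0)),
      dist_lake = cbind(c(0, 250, 600), c(0.8, 0, -0.8))
    )
  }
  for (nm in names(responses)) {
    k <- responses[[nm]]
    if (!is.matrix(k) || ncol(k) != 2L || any(!is.finite(k))) {
      stop("response knots must be finite two-column matrices")
    }
  }
  structure(list(intercept = intercept, responses = responses,
                 realized_count = NA_integer_),
            class = "response_truth")
}

# evaluate one piecewise-linear response at x (constant beyond outer knots)
eval_response <- function(knots, x) {
  approx(knots[, 1], knots[, 2], xout = x, rule = 2)$y
}

#' Simulate midden presences from a predictor stack
#'
#' Cell-wise inhomogeneous Bernoulli draw with probability
#' `plogis(intercept + sum of responses)`. If the truth's intercept is `NA`
#' it is first calibrated (by root finding) so the expected presence count
#' over the candidate cells equals `target_count`.
#'
#' @param stack A `predictor_stack` containing every layer named by the truth.
#' @param truth A [response_truth()].
#' @param seed Integer seed for the Bernoulli draw.
#' @param area_polygon Optional study-area ring; only cells whose centres fall
#'   inside are candidates.
#' @param target_count Expected presence count used when calibrating the
#'   intercept (default 198, the emulated survey total).
#' @return List with `points` (data.frame `id`, `x`, `y` of presence cell
#'   centres) and `truth` (the truth record with intercept and realized count
#'   filled in).
#' @export
simulate_middens <- function(stack, truth, seed, area_polygon = NULL,
                             target_count = 198) {
  stopifnot(inherits(stack, "predictor_stack"), inherits(truth, "response_truth"))
  missing_layers <- setdiff(names(truth$responses), names(stack))
  if (length(missing_layers)) {
    stop("missing predictor layer: ", paste(missing_layers, collapse = ", "))
  }
  cells <- as.data.frame(stack)
  if (!is.null(area_polygon)) {
    cells <- cells[points_in_polygon(area_polygon, cells$x, cells$y), ,
                   drop = FALSE]
  }
  eta0 <- rep(0, nrow(cells))
  for (nm in names(truth$responses)) {
    eta0 <- eta0 + eval_response(truth$responses[[nm]], cells[[nm]])
  }
  b <- truth$intercept
  if (is.na(b)) {
    f <- function(b) sum(plogis(b + eta0)) - target_count
    b <- stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
  }
  p <- plogis(b + eta0)
  hits <- with_seed(seed, 404L, rbinom(length(p), 1L, p) == 1L)
  pts <- data.frame(id = seq_len(sum(hits)),
                    x = cells$x[hits], y = cells$y[hits])
  truth$intercept <- b
  truth$realized_count <- nrow(pts)
  list(points = pts, truth = truth)
}

#' Merge nearby middens into one diffuse midden
#'
#' Greedy thinning mirroring the field rule that middens closer than the merge
#' radius count as one: points are visited in deterministic order (y
#' descending, then x ascending) and a point within `radius` of an
#' already-kept point is dropped. Every dropped point is within `radius` of a
#' kept one; kept points may still chain closer than `radius` to each other
#' only through dropped intermediaries, never directly.
#'
#' @param points Data.frame with columns `x`, `y`.
#' @param radius Merge radius in meters (default 10, the field rule).
#' @return The kept subset of `points` (original columns preserved).
#' @export
thin_middens <- function(points, radius = 10) {
  if (radius <= 0) stop("radius must be > 0")
  n <- nrow(points)
  if (n <= 1L) return(points)
  ord <- order(-points$y, points$x)
  px <- points$x[ord]; py <- points$y[ord]
  keep <- logical(n)
  kx <- numeric(0); ky <- numeric(0)
  for (i in seq_len(n)) {
    if (!length(kx) || min((kx - px[i])^2 + (ky - py[i])^2) >= radius^2) {
      keep[i] <- TRUE
      kx <- c(kx, px[i]); ky <- c(ky, py[i])
    }
  }
  out <- points[ord[keep], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate a complete synthetic landscape
#'
#' Convenience driver: terrain, canopy, features, point cloud, the
#' generator-truth predictor stack (generated rasters plus distance layers),
#' and thinned midden presences.
#'
#' @param config A [landscape_config()].
#' @param truth A [response_truth()]; default full response set.
#' @return List of class `synthetic_landscape` with elements `config`,
#'   `elevation`, `canopy`, `features`, `cloud`, `stack` (truth predictors),
#'   `middens` (thinned points), `middens_raw`, and `truth`.
#' @export
simulate_landscape <- function(config = landscape_config(),
                               truth = response_truth()) {
  elevation <- generate_terrain(config)
  canopy <- generate_canopy(config, elevation)
  features <- generate_features(config)
  cloud <- generate_point_cloud(config, elevation, canopy$height,
                                canopy$density)
  g <- config$grid
  sa <- slope_aspect(elevation)
  stack <- stack_predictors(list(
    canopy_height = canopy$height,
    canopy_density = canopy$density,
    slope = sa$slope,
    aspect = sa$aspect,
    elevation = elevation,
    dist_lake = euclidean_distance(features, "lake", g),
    dist_trails = euclidean_distance(features, "trails", g),
    dist_dogtrail = euclidean_distance(features, "dogtrail", g),
    dist_highway = euclidean_distance(features, "highway", g),
    dist_buildings = euclidean_distance(features, "buildings", g)
  ))
  sim <- simulate_middens(stack, truth, config$seed,
                          area_polygon = config$area_polygon,
                          target_count = config$target_middens)
  middens <- thin_middens(sim$points, radius = 10)
  middens$id <- seq_len(nrow(middens))
  structure(list(config = config, elevation = elevation, canopy = canopy,
                 features = features, cloud = cloud, stack = stack,
                 middens = middens, middens_raw = sim$points,
                 truth = sim$truth),
            class = "synthetic_landscape")
}
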