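# Shared fixtures and independent brute-force oracles. Oracles are written
# without reference to the package internals they check.

# a small (80 x 80 cell) landscape configuration that runs in ~1 s
tiny_config <- function(seed = 3, target_middens = 60, ...) {
  defaults <- list(
    extent_x = 240, extent_y = 240, cell_size = 3, seed = seed,
    lake = list(center = c(120, 210), radius = 25),
    meadow = list(center = c(180, 60), radius = 30),
    trails = list(cbind(c(10, 120, 230), c(30, 120, 200))),
    dogtrail = list(cbind(c(10, 230), c(60, 70))),
    buildings = list(c(200, 100, 230, 130)),
    area_polygon = cbind(c(5, 235, 235, 5), c(5, 5, 235, 235)),
    terrain_smooth = 30, canopy_smooth = 12,
    target_middens = target_middens
  )
  overrides <- list(...)
  args <- defaults
  args[names(overrides)] <- overrides # plain replacement, no recursive merge
  do.call(landscape_config, args)
}

# a ~2000-cell landscape for the parameter-recovery simulations, with
# smoothing bandwidth scaled to the small extent
recovery_config <- function(seed) {
  landscape_config(
    extent_x = 150, extent_y = 120, cell_size = 3, seed = seed,
    lake = list(center = c(75, 100), radius = 15),
    meadow = list(center = c(120, 30), radius = 15),
    trails = list(cbind(c(5, 70, 145), c(10, 60, 110)),
                  cbind(c(20, 120), c(100, 15))),
    dogtrail = list(cbind(c(5, 145), c(30, 35))),
    buildings = list(c(125, 55, 145, 70)),
    area_polygon = cbind(c(1, 149, 149, 1), c(1, 1, 119, 119)),
    terrain_smooth = 20, canopy_smooth = 9
  )
}

tiny_stack <- function(cfg) {
  el <- generate_terrain(cfg)
  can <- generate_canopy(cfg, el)
  fs <- generate_features(cfg)
  sa <- slope_aspect(el)
  g <- cfg$grid
  stack_predictors(list(
    canopy_height = can$height, canopy_density = can$density,
    slope = sa$slope, aspect = sa$aspect, elevation = el,
    dist_lake = euclidean_distance(fs, "lake", g),
    dist_trails = euclidean_distance(fs, "trails", g),
    dist_dogtrail = euclidean_distance(fs, "dogtrail", g),
    dist_highway = euclidean_distance(fs, "highway", g),
    dist_buildings = euclidean_distance(fs, "buildings", g)
  ))
}

# label every cell of a stack by a Bernoulli draw from the given truth and
# return the balanced cell-level training table
cell_training_table <- function(stk, truth, seed, prevalence = 0.3) {
  g <- attr(stk, "spec")
  cells <- as.data.frame(stk)
  sim <- simulate_middens(stk, truth, seed,
                          target_count = round(prevalence * nrow(cells)))
  cells$label <- 0L
  pc <- point_cell(g, sim$points$x, sim$points$y)
  cells$label[(pc$row - 1L) * g$ncol + pc$col] <- 1L
  balance_weights(cells)
}

# random classified point cloud over a given extent
random_cloud <- function(n, xmax, ymax, zrange = c(100, 130), seed = 1) {
  set.seed(seed)
  data.frame(
    x = runif(n, 0, xmax), y = runif(n, 0, ymax),
    z = runif(n, zrange[1], zrange[2]),
    class = sample(c("ground", "vegetation", "unclassified"), n,
                   replace = TRUE),
    stringsAsFactors = FALSE
  )
}

# ---- independent oracles ---------------------------------------------------

# O(cells^2) Euclidean distance transform over source cells
bf_edt <- function(src_rc, nr, nc, cell) {
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      out[r, c] <- min(sqrt((src_rc[, 1] - r)^2 + (src_rc[, 2] - c)^2)) * cell
    }
  }
  out
}

# all-points inverse-distance weighting at query locations
bf_idw <- function(px, py, pv, qx, qy, power = 2) {
  vapply(seq_along(qx), function(i) {
    d <- sqrt((px - qx[i])^2 + (py - qy[i])^2)
    if (min(d) < 1e-9) return(pv[which.min(d)])
    w <- d^(-power)
    sum(w * pv) / sum(w)
  }, numeric(1))
}

# all-pairs weighted Mann-Whitney AUC
bf_auc <- function(labels, scores, weights = rep(1, length(labels))) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  num <- 0
  for (i in pos) {
    for (j in neg) {
      num <- num + weights[i] * weights[j] *
        (if (scores[i] > scores[j]) 1 else if (scores[i] == scores[j]) 0.5 else 0)
    }
  }
  num / (sum(weights[pos]) * sum(weights[neg]))
}

# per-cell counting of vegetation fraction and max-return height
bf_cell_stats <- function(cloud, spec, dem) {
  dens <- matrix(NA_real_, spec$nrow, spec$ncol)
  hgt <- matrix(0, spec$nrow, spec$ncol)
  for (r in seq_len(spec$nrow)) {
    for (c in seq_len(spec$ncol)) {
      x0 <- spec$origin_x + (c - 1) * spec$cell_size
      y0 <- spec$origin_y - r * spec$cell_size
      inx <- cloud$x >= x0 & cloud$x < x0 + spec$cell_size &
        cloud$y > y0 & cloud$y <= y0 + spec$cell_size
      if (any(inx)) {
        veg <- cloud$class[inx] != "ground"
        dens[r, c] <- sum(veg) / sum(inx)
        if (any(veg)) {
          hgt[r, c] <- max(0, max(cloud$z[inx][veg]) - dem$values[r, c])
        }
      }
    }
  }
  list(density = dens, height = hgt)
}

# type-7 quartiles computed from first principles on the sorted sample
bf_quartile <- function(v, p) {
  s <- sort(v)
  h <- (length(s) - 1) * p
  lo <- floor(h)
  s[lo + 1] * (1 - (h - lo)) + s[min(lo + 2, length(s))] * (h - lo)
}

# linear interpolation of the first negative-to-positive zero crossing
pd_zero_crossing <- function(pd) {
  s <- sign(pd$pd)
  idx <- which(s[-1] > 0 & s[-length(s)] <= 0)
  if (!length(idx)) return(NA_real_)
  i <- idx[1]
  pd$value[i] + (0 - pd$pd[i]) * (pd$value[i + 1] - pd$value[i]) /
    (pd$pd[i + 1] - pd$pd[i])
}
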