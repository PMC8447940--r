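# Synthetic landscape generator: determinism, ranges, and the midden process.

test_that("terrain is deterministic per seed, bounded, and seed-sensitive", {
  cfg <- tiny_config(seed = 11)
  a <- generate_terrain(cfg)
  b <- generate_terrain(cfg)
  expect_identical(a$values, b$values)
  expect_true(min(a$values) >= 145 && max(a$values) <= 190)

  other <- generate_terrain(tiny_config(seed = 12))
  expect_true(any(a$values != other$values))

  flat <- generate_terrain(tiny_config(seed = 11,
                                       elevation_range = c(150, 150)))
  expect_true(all(flat$values == 150))

  expect_error(landscape_config(cell_size = 0), "configuration error")
})

test_that("canopy fields respect bounds, meadow carving, and correlate", {
  cfg <- tiny_config(seed = 5)
  el <- generate_terrain(cfg)
  can <- generate_canopy(cfg, el)
  h <- can$height$values; d <- can$density$values
  expect_true(all(h >= 0 & h <= cfg$max_canopy_height))
  expect_true(all(d >= 0 & d <= 1))
  expect_gt(cor(as.vector(h), as.vector(d)), 0)

  # meadow cells carry zero canopy
  cc <- cell_centers(cfg$grid)
  g <- cfg$grid
  cx <- matrix(cc$x, g$nrow, g$ncol, byrow = TRUE)
  cy <- matrix(cc$y, g$nrow, g$ncol)
  meadow <- (cx - 180)^2 + (cy - 60)^2 <= 30^2
  expect_true(all(h[meadow] == 0))
  expect_true(all(d[meadow] == 0))

  bare <- generate_canopy(tiny_config(seed = 5, max_canopy_height = 0), el)
  expect_true(all(bare$height$values == 0))
  expect_true(all(bare$density$values == 0))
})

test_that("feature classes are present, valid, and confined to the extent", {
  cfg <- tiny_config()
  fs <- generate_features(cfg)
  expect_named(fs, c("lake", "trails", "dogtrail", "highway", "buildings"))
  expect_true(all(lengths(fs) > 0))
  for (cls in c("lake", "buildings")) {
    for (geom in fs[[cls]]) expect_true(polygon_is_valid(geom))
  }

  no_bld <- generate_features(tiny_config(buildings = list()))
  expect_length(no_bld$buildings, 0)
  expect_length(no_bld$lake, 1)

  expect_error(
    generate_features(tiny_config(buildings = list(c(200, 100, 900, 130)))),
    "outside extent"
  )
})

test_that("point cloud has ground coverage and rate-consistent vegetation", {
  cfg <- tiny_config(seed = 2)
  el <- generate_terrain(cfg)
  can <- generate_canopy(cfg, el)
  cloud <- generate_point_cloud(cfg, el, can$height, can$density)

  # ground-only when there is no canopy
  cfg0 <- tiny_config(seed = 2, max_canopy_height = 0)
  bare <- generate_canopy(cfg0, el)
  cloud0 <- generate_point_cloud(cfg0, el, bare$height, bare$density)
  expect_true(all(cloud0$class == "ground"))

  # expected vegetation count over all (>= 1000) cells within 3 Poisson SEs
  lambda_total <- sum(can$density$values[can$height$values > 0] *
                        cfg$veg_returns_per_cell)
  n_veg <- sum(cloud$class != "ground")
  expect_lt(abs(n_veg - lambda_total), 3 * sqrt(lambda_total))

  # z bounded below by local elevation minus the ground-noise bound
  cl <- point_cell(cfg$grid, cloud$x, cloud$y)
  el_at <- el$values[cbind(cl$row, cl$col)]
  expect_true(all(cloud$z >= el_at - 6 * cfg$ground_noise_sd))

  expect_error(generate_point_cloud(tiny_config(lidar_point_spacing = 0),
                                    el, can$height, can$density),
               "configuration error")
})

test_that("midden simulation follows the response model", {
  cfg <- tiny_config(seed = 9)
  stk <- tiny_stack(cfg)
  n_cells <- prod(dim(stk$canopy_height$values))

  # numerically zero intercept floor -> no presences
  none <- simulate_middens(stk, response_truth(intercept = -50), 1)
  expect_equal(nrow(none$points), 0)

  # flat responses at intercept 0 -> about half the cells are presences
  flat <- response_truth(intercept = 0,
                         responses = list(canopy_height = cbind(c(0, 25), c(0, 0))))
  half <- simulate_middens(stk, flat, 4)
  expect_lt(abs(nrow(half$points) - 0.5 * n_cells),
            3 * sqrt(0.25 * n_cells))

  # a single active height response pushes presences into taller cells
  tall <- response_truth(responses = list(canopy_height = cbind(c(0, 9, 25),
                                                                c(-2, 0, 2))))
  sim <- simulate_middens(stk, tall, 4, target_count = 400)
  cells <- as.data.frame(stk)
  pc <- point_cell(attr(stk, "spec"), sim$points$x, sim$points$y)
  pres_idx <- (pc$row - 1L) * attr(stk, "spec")$ncol + pc$col
  expect_gt(mean(cells$canopy_height[pres_idx]),
            mean(cells$canopy_height[-pres_idx]))

  # expected count is monotone in the intercept
  counts <- vapply(c(-6, -4, -2), function(b) {
    nrow(simulate_middens(stk, response_truth(intercept = b), 4)$points)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))

  # a truth naming an absent layer fails loudly
  bad <- response_truth(responses = list(nosuch = cbind(c(0, 1), c(0, 0))))
  expect_error(simulate_middens(stk, bad, 1), "nosuch")
})

test_that("thinning drops points only within the merge radius of kept ones", {
  two_close <- data.frame(x = c(0, 3), y = c(0, 4)) # 5 m apart
  expect_equal(nrow(thin_middens(two_close, 10)), 1)
  two_far <- data.frame(x = c(0, 9), y = c(0, 12)) # 15 m apart
  expect_equal(nrow(thin_middens(two_far, 10)), 2)

  set.seed(8)
  pts <- data.frame(x = runif(200, 0, 100), y = runif(200, 0, 100))
  kept <- thin_middens(pts, 10)
  dropped <- pts[!paste(pts$x, pts$y) %in% paste(kept$x, kept$y), ]
  for (i in seq_len(nrow(dropped))) {
    dmin <- min(sqrt((kept$x - dropped$x[i])^2 + (kept$y - dropped$y[i])^2))
    expect_lt(dmin, 10)
  }
  # kept points are themselves mutually separated
  if (nrow(kept) > 1) {
    dm <- as.matrix(dist(kept[c("x", "y")]))
    expect_true(all(dm[upper.tri(dm)] >= 10))
  }
  expect_identical(thin_middens(pts, 10), kept)
})

test_that("the full landscape bundle is bit-reproducible per seed", {
  a <- simulate_landscape(tiny_config(seed = 21))
  b <- simulate_landscape(tiny_config(seed = 21))
  expect_identical(a$elevation$values, b$elevation$values)
  expect_identical(a$cloud, b$cloud)
  expect_identical(a$middens, b$middens)
  expect_identical(a$truth$intercept, b$truth$intercept)
})
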