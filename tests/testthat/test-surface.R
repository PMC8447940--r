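# Lattice scoring, IDW interpolation, occupancy thresholding/classification.

test_that("the lattice sits on cell centres clipped to the polygon", {
  spec <- grid_spec(0, 9, 3, 3, 3)
  square <- cbind(c(0, 9, 9, 0), c(0, 0, 9, 9))
  lat <- make_lattice(square, spec)
  expect_equal(nrow(lat), 9)
  expect_setequal(lat$x, c(1.5, 4.5, 7.5))

  # clipping removes centres outside the polygon; count equals brute force
  tri <- cbind(c(0, 9, 0), c(0, 0, 9))
  lat_tri <- make_lattice(tri, spec)
  cc <- expand.grid(x = c(1.5, 4.5, 7.5), y = c(1.5, 4.5, 7.5))
  expect_equal(nrow(lat_tri), sum(points_in_polygon(tri, cc$x, cc$y)))
  expect_false(any(lat_tri$x == 7.5 & lat_tri$y == 7.5))

  expect_warning(make_lattice(square, spec, spacing = 1), "below the cell size")
  expect_error(make_lattice(cbind(c(100, 101, 101), c(100, 100, 101)), spec),
               "no points")
})

test_that("scored lattices decompose into extraction plus prediction", {
  cfg <- tiny_config(seed = 16)
  stk <- tiny_stack(cfg)
  tab <- cell_training_table(stk, response_truth(), seed = 1)
  m <- rio_boost(label ~ canopy_height + canopy_density + dist_trails +
                   dist_lake, tab, weights = tab$weight, n_trees = 20,
                 seed = 2)
  lat <- make_lattice(cfg$area_polygon, cfg$grid)
  sc <- score_lattice(m, lat, stk)
  expect_true(all(abs(sc$PROB_0 + sc$PROB_1 - 1) < 1e-12))
  expect_equal(sc$PROB_1, unname(predict(m, extract_values(lat, stk))),
               tolerance = 1e-12)
})

test_that("IDW is exact at points, symmetric, convex, and matches brute force", {
  spec <- grid_spec(0, 30, 3, 10, 10)
  set.seed(23)
  pts <- data.frame(x = runif(20, 0, 30), y = runif(20, 0, 30),
                    PROB_1 = runif(20))
  # with k >= n the surface must equal the all-points oracle
  surf <- idw_interpolate(pts, spec, power = 2, k = 25)
  cc <- cell_centers(spec)
  grid <- expand.grid(col = 1:10, row = 1:10)
  oracle <- bf_idw(pts$x, pts$y, pts$PROB_1, cc$x[grid$col], cc$y[grid$row])
  expect_equal(surf$values[cbind(grid$row, grid$col)], oracle,
               tolerance = 1e-9)
  # convexity: interpolated values stay inside the data range
  expect_true(all(surf$values >= min(pts$PROB_1) &
                    surf$values <= max(pts$PROB_1)))

  # a point exactly on a cell centre is reproduced exactly
  on_centre <- data.frame(x = 16.5, y = 16.5, PROB_1 = 0.42)
  s1 <- idw_interpolate(rbind(pts, on_centre), spec, k = 4)
  expect_equal(s1$values[point_cell(spec, 16.5, 16.5)$row,
                         point_cell(spec, 16.5, 16.5)$col], 0.42)

  # equidistant pair averages exactly
  pair <- data.frame(x = c(13.5, 19.5), y = c(16.5, 16.5),
                     PROB_1 = c(0.2, 0.8))
  s2 <- idw_interpolate(pair, spec, k = 2)
  expect_equal(s2$values[point_cell(spec, 16.5, 16.5)$row,
                         point_cell(spec, 16.5, 16.5)$col], 0.5)

  expect_error(idw_interpolate(pts, spec, k = 0), "k must be")
})

test_that("the occupancy threshold retains the target presence fraction", {
  vals <- seq(0.05, 1, by = 0.05) # N = 20
  t <- occupancy_threshold(vals, 0.95)
  expect_equal(t, 0.05)
  expect_gte(mean(vals >= t), 0.95)

  expect_equal(occupancy_threshold(rep(0.3, 25)), 0.3)
  expect_error(occupancy_threshold(runif(10)), "at least 20")

  set.seed(29)
  for (k in 1:100) {
    n <- sample(20:400, 1)
    v <- runif(n)
    t <- occupancy_threshold(v, 0.95)
    frac <- mean(v >= t)
    expect_gte(frac, 0.95)
    expect_lte(frac, 0.95 + 1 / n + 1e-12)
  }
})

test_that("occupancy classification reports areas and presence capture", {
  spec <- grid_spec(0, 30, 3, 10, 10)
  set.seed(33)
  surf <- raster_grid(matrix(runif(100, 0.1, 0.9), 10, 10), spec, "rio")

  all_occ <- classify_occupancy(surf, 0.05)
  expect_equal(all_occ$occupied_area_ha, 100 * 9 / 1e4)
  none <- classify_occupancy(surf, 0.95)
  expect_equal(none$occupied_area_ha, 0)

  # area equals brute-force cell counting at any threshold
  for (t in c(0.25, 0.5, 0.75)) {
    occ <- classify_occupancy(surf, t)
    expect_equal(occ$occupied_area_ha, sum(surf$values >= t) * 9 / 1e4)
  }
  # monotone non-increasing in the threshold
  areas <- vapply(seq(0.1, 0.9, 0.1), function(t) {
    classify_occupancy(surf, t)$occupied_area_ha
  }, numeric(1))
  expect_true(all(diff(areas) <= 0))

  pres <- data.frame(x = c(1.5, 4.5), y = c(28.5, 28.5))
  occ <- classify_occupancy(surf, 0.5, presences = pres)
  manual <- sum(surf$values[1, 1:2] >= 0.5)
  expect_equal(occ$n_presences_occupied, manual)

  expect_error(classify_occupancy(surf, 1.2), "between 0 and 1")
})
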