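# LIDAR gridding, terrain derivatives and distance layers, checked against
# independent per-cell oracles on small fixtures.

test_that("vegetation merge relabels without losing returns", {
  cloud <- data.frame(
    x = runif(10), y = runif(10), z = runif(10),
    class = rep(c("ground", "vegetation", "unclassified"), c(3, 2, 5)),
    stringsAsFactors = FALSE
  )
  merged <- merge_vegetation(cloud)
  expect_equal(sum(merged$class == "ground"), 3)
  expect_equal(sum(merged$class == "vegetation"), 7)
  expect_equal(nrow(merged), 10)
  expect_identical(merge_vegetation(merged), merged)

  allg <- data.frame(x = 1, y = 1, z = 1, class = "ground")
  expect_identical(merge_vegetation(allg), allg)
  expect_error(merge_vegetation(transform(allg, class = "water")),
               "unknown point class token")
})

test_that("DEM is the per-cell mean of ground z, gap-filled within bounds", {
  spec <- grid_spec(0, 6, 3, 2, 2)
  cloud <- data.frame(x = c(1, 2), y = c(5, 5), z = c(149, 151),
                      class = "ground")
  dem <- build_dem(cloud, spec)
  expect_equal(dem$values[1, 1], 150)
  # the three empty cells were IDW-filled from the single donor
  expect_true(all(dem$values == 150))

  flat <- data.frame(x = runif(500, 0, 30), y = runif(500, 0, 30),
                     z = 160, class = "ground")
  dem_flat <- build_dem(flat, grid_spec(0, 30, 3, 10, 10))
  expect_true(all(dem_flat$values == 160))

  # gap-filled values stay inside the donor range
  set.seed(4)
  sparse <- data.frame(x = runif(40, 0, 30), y = runif(40, 0, 30),
                       z = runif(40, 100, 120), class = "ground")
  dg <- build_dem(sparse, grid_spec(0, 30, 3, 10, 10))
  expect_true(all(dg$values >= min(sparse$z) & dg$values <= max(sparse$z)))

  expect_error(build_dem(transform(flat, class = "vegetation"), spec),
               "no ground returns")
})

test_that("canopy density and height match brute-force per-cell counting", {
  spec <- grid_spec(0, 30, 3, 10, 10)
  cloud <- merge_vegetation(random_cloud(10000, 30, 30, seed = 7))
  dem <- build_dem(cloud, spec)
  oracle <- bf_cell_stats(cloud, spec, dem)

  dens <- canopy_density(cloud, spec)
  filled <- is.finite(oracle$density)
  expect_equal(dens$values[filled], oracle$density[filled], tolerance = 1e-12)
  expect_true(all(dens$values >= 0 & dens$values <= 1))

  hgt <- canopy_height(cloud, dem, spec)
  expect_equal(hgt$values, oracle$height, tolerance = 1e-12)
  expect_true(all(hgt$values >= 0))

  # single-cell arithmetic examples
  one <- grid_spec(0, 3, 3, 1, 1)
  c1 <- data.frame(x = rep(1.5, 10), y = rep(1.5, 10), z = 100,
                   class = rep(c("vegetation", "ground"), c(6, 4)))
  expect_equal(canopy_density(c1, one)$values[1, 1], 0.6)
  expect_equal(canopy_density(transform(c1, class = "ground"), one)$values[1, 1], 0)
  c2 <- data.frame(x = c(1, 2, 1), y = c(1, 1, 2), z = c(152, 158, 150),
                   class = c("vegetation", "vegetation", "ground"))
  d2 <- raster_grid(150, one, "elevation", "m")
  expect_equal(canopy_height(c2, d2, one)$values[1, 1], 8)
  expect_equal(canopy_height(c2[3, ], d2, one)$values[1, 1], 0)
  expect_error(canopy_height(c2, raster_grid(150, grid_spec(0, 6, 3, 2, 2)), one),
               "alignment")
})

test_that("Horn slope/aspect match the analytic plane oracle", {
  spec <- grid_spec(0, 30, 3, 10, 10)
  cc <- cell_centers(spec)

  flat <- raster_grid(100, spec)
  sa <- slope_aspect(flat)
  expect_true(all(sa$slope$values == 0))
  expect_true(all(sa$aspect$values == -1))

  # plane rising due east at dz/dx = 1: slope 45 deg, steepest descent west
  east <- raster_grid(matrix(cc$x, 10, 10, byrow = TRUE), spec)
  sa_e <- slope_aspect(east)
  inner <- 2:9
  expect_equal(sa_e$slope$values[inner, inner],
               matrix(45, 8, 8), tolerance = 1e-9)
  expect_equal(sa_e$aspect$values[inner, inner],
               matrix(270, 8, 8), tolerance = 1e-9)

  # random planes: interior slope = atan(|gradient|), aspect = bearing of -grad
  set.seed(12)
  for (k in 1:5) {
    a <- runif(1, -2, 2); b <- runif(1, -2, 2)
    z <- outer(cc$y, cc$x, function(y, x) a * x + b * y)
    sa_p <- slope_aspect(raster_grid(z, spec))
    expect_equal(sa_p$slope$values[inner, inner],
                 matrix(atan(sqrt(a^2 + b^2)) * 180 / pi, 8, 8),
                 tolerance = 1e-9)
    expect_equal(sa_p$aspect$values[inner, inner],
                 matrix((atan2(-a, -b) * 180 / pi) %% 360, 8, 8),
                 tolerance = 1e-9)
  }

  expect_error(slope_aspect(raster_grid(1, grid_spec(0, 6, 3, 2, 2))),
               "3 x 3")
})

test_that("Euclidean distance equals the O(cells^2) oracle and is Lipschitz", {
  spec <- grid_spec(0, 90, 3, 30, 30)
  set.seed(31)
  feats <- list(trails = list(
    cbind(runif(2, 0, 90), runif(2, 0, 90)),
    cbind(runif(3, 0, 90), runif(3, 0, 90))
  ))
  d <- euclidean_distance(feats, "trails", spec)
  src <- middensdm:::rasterize_features(feats$trails, spec, FALSE)
  oracle <- bf_edt(src, spec$nrow, spec$ncol, spec$cell_size)
  expect_equal(d$values, oracle, tolerance = 1e-9)
  expect_true(all(d$values[cbind(src[, 1], src[, 2])] == 0))

  # 8-neighbour Lipschitz bound: one cell step changes d by <= cell diagonal
  lim <- sqrt(2) * spec$cell_size + 1e-9
  v <- d$values
  expect_true(all(abs(diff(v)) <= lim))
  expect_true(all(abs(t(diff(t(v)))) <= lim))
  expect_true(all(abs(v[-1, -1] - v[-30, -30]) <= lim))
  expect_true(all(abs(v[-1, -30] - v[-30, -1]) <= lim))

  # exact axis-aligned arithmetic: 4 cells due east of a source = 12 m
  one_cell <- list(buildings = list(rect_closed <- cbind(c(1, 2, 2, 1),
                                                         c(88, 88, 89, 89))))
  d1 <- euclidean_distance(one_cell, "buildings", spec)
  expect_equal(d1$values[1, 5], 12)

  expect_error(euclidean_distance(list(trails = list()), "trails", spec),
               "trails")
})

test_that("stacks enforce alignment and survive a write/read round trip", {
  spec <- grid_spec(0, 30, 3, 10, 10)
  r1 <- raster_grid(matrix(runif(100), 10, 10), spec, "a", "m")
  r2 <- raster_grid(matrix(runif(100), 10, 10), spec, "b", "m")
  stk <- stack_predictors(list(a = r1, b = r2))
  expect_length(stk, 2)

  off <- raster_grid(matrix(runif(100), 10, 10), grid_spec(0, 30, 1.5, 10, 10))
  expect_error(stack_predictors(list(a = r1, c = off)), "alignment")

  dir <- withr::local_tempdir()
  mp <- write_stack(stk, dir)
  back <- read_stack(mp)
  expect_identical(names(back), c("a", "b"))
  expect_equal(back$a$values, r1$values, tolerance = 1e-12)
  expect_equal(back$b$values, r2$values, tolerance = 1e-12)
})
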