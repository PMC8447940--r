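# From classified LIDAR returns and vector features to the aligned 3 x 3 m
# predictor rasters: DEM, canopy height, canopy density, slope, aspect, and
# Euclidean-distance layers.

CLOUD_CLASSES <- c("ground", "vegetation", "unclassified")

check_cloud <- function(cloud) {
  stopifnot(is.data.frame(cloud),
            all(c("x", "y", "z", "class") %in% names(cloud)))
  if (!all(is.finite(cloud$x) & is.finite(cloud$y) & is.finite(cloud$z))) {
    stop("point cloud contains non-finite coordinates")
  }
  bad <- setdiff(unique(cloud$class), CLOUD_CLASSES)
  if (length(bad)) stop("unknown point class token: ", paste(bad, collapse = ", "))
  invisible(cloud)
}

#' Merge unclassified returns into the vegetation class
#'
#' Provider classification typically leaves part of the vegetated returns
#' unclassified; they are combined with the classified vegetation so both
#' canopy metrics see all non-ground returns. Ground returns are untouched and
#' the return count is preserved; the operation is idempotent.
#'
#' @param cloud Point-cloud data.frame (`x`, `y`, `z`, `class`).
#' @return The cloud with every `unclassified` return relabelled `vegetation`.
#' @export
merge_vegetation <- function(cloud) {
  check_cloud(cloud)
  cloud$class[cloud$class == "unclassified"] <- "vegetation"
  cloud
}

# mean aggregation of point values per grid cell; returns matrix with NA for
# empty cells, plus the per-cell counts
aggregate_mean <- function(spec, x, y, v) {
  cl <- point_cell(spec, x, y)
  ok <- cl$inside
  id <- (cl$row[ok] - 1L) * spec$ncol + cl$col[ok]
  sums <- rowsum(v[ok], id)
  cnts <- rowsum(rep(1, sum(ok)), id)
  m <- matrix(NA_real_, spec$nrow, spec$ncol)
  cellid <- as.integer(rownames(sums))
  m[cbind((cellid - 1L) %/% spec$ncol + 1L, (cellid - 1L) %% spec$ncol + 1L)] <-
    sums[, 1] / cnts[, 1]
  m
}

# fill NA cells by inverse-distance weighting from the k nearest filled cells
gap_fill_idw <- function(grid, k = 8, power = 2) {
  v <- grid$values
  miss <- which(!is.finite(v), arr.ind = TRUE)
  if (nrow(miss) == 0L) return(grid)
  filled <- which(is.finite(v), arr.ind = TRUE)
  if (nrow(filled) == 0L) stop("cannot gap-fill: no filled cells")
  cc <- cell_centers(grid)
  est <- .knn_idw_cpp(cc$x[filled[, 2]], cc$y[filled[, 1]],
                      v[filled], cc$x[miss[, 2]], cc$y[miss[, 1]],
                      as.integer(k), power)
  v[miss] <- est
  raster_grid(v, same_spec(grid), grid$name, grid$units)
}

#' Digital elevation model from ground returns
#'
#' Cell value is the mean z of ground returns falling in the cell (half-open
#' edge membership); cells without any ground return are filled by
#' inverse-distance weighting from the `k` nearest filled cells.
#'
#' @param cloud Point cloud (after [merge_vegetation()]).
#' @param spec Target [grid_spec()].
#' @param k Number of donor cells for gap filling.
#' @return A [raster_grid()] of elevation (m).
#' @export
build_dem <- function(cloud, spec, k = 8) {
  check_cloud(cloud)
  g <- cloud[cloud$class == "ground", ]
  if (nrow(g) == 0L) stop("no ground returns: cannot build a DEM")
  m <- aggregate_mean(spec, g$x, g$y, g$z)
  gap_fill_idw(raster_grid(m, spec, "elevation", "m"), k = k)
}

#' Canopy density from return-class ratios
#'
#' Cell value is the fraction of returns in the cell that are vegetation
#' returns. Cells with zero returns are no-data, then gap-filled by
#' inverse-distance weighting.
#'
#' @param cloud Point cloud (after [merge_vegetation()]).
#' @param spec Target [grid_spec()].
#' @param k Donor-cell count for gap filling.
#' @return A [raster_grid()] with values in `[0, 1]`.
#' @export
canopy_density <- function(cloud, spec, k = 8) {
  check_cloud(cloud)
  cl <- point_cell(spec, cloud$x, cloud$y)
  ok <- cl$inside
  id <- (cl$row[ok] - 1L) * spec$ncol + cl$col[ok]
  veg <- rowsum(as.numeric(cloud$class[ok] != "ground"), id)
  tot <- rowsum(rep(1, sum(ok)), id)
  m <- matrix(NA_real_, spec$nrow, spec$ncol)
  cellid <- as.integer(rownames(tot))
  m[cbind((cellid - 1L) %/% spec$ncol + 1L, (cellid - 1L) %% spec$ncol + 1L)] <-
    veg[, 1] / tot[, 1]
  out <- gap_fill_idw(raster_grid(m, spec, "canopy_density", "fraction"), k = k)
  out$values <- pmin(pmax(out$values, 0), 1)
  out
}

#' Canopy height from the highest vegetation return
#'
#' Cell value is the maximum z of vegetation returns in the cell minus the
#' cell's DEM elevation, floored at zero; cells without vegetation returns
#' are 0 (open ground).
#'
#' @param cloud Point cloud (after [merge_vegetation()]).
#' @param dem DEM raster aligned with `spec`.
#' @param spec Target [grid_spec()].
#' @return A [raster_grid()] of height above ground (m).
#' @export
canopy_height <- function(cloud, dem, spec) {
  check_cloud(cloud)
  if (!grids_aligned(dem, spec)) stop("alignment error: dem does not match grid spec")
  v <- cloud[cloud$class == "vegetation", ]
  m <- matrix(0, spec$nrow, spec$ncol)
  if (nrow(v)) {
    cl <- point_cell(spec, v$x, v$y)
    ok <- cl$inside
    id <- (cl$row[ok] - 1L) * spec$ncol + cl$col[ok]
    z <- v$z[ok]
    o <- order(id, z)
    id <- id[o]; z <- z[o]
    last <- c(id[-1] != id[-length(id)], TRUE) # last (= max z) per cell id
    cellid <- id[last]
    rc <- cbind((cellid - 1L) %/% spec$ncol + 1L, (cellid - 1L) %% spec$ncol + 1L)
    m[rc] <- pmax(0, z[last] - dem$values[rc])
  }
  raster_grid(m, spec, "canopy_height", "m")
}

#' Slope and aspect by Horn's method
#'
#' Horn 3x3 finite differences with replicated-border padding. Slope is
#' `atan(sqrt(gx^2 + gy^2))` in degrees. Aspect is the compass direction of
#' steepest descent, degrees clockwise from north in `[0, 360)`; flat cells
#' (slope 0) are coded -1.
#'
#' @param dem Elevation [raster_grid()] of at least 3 x 3 cells.
#' @return List with `slope` and `aspect` rasters (degrees).
#' @export
slope_aspect <- function(dem) {
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 3L || nc < 3L) stop("dem must be at least 3 x 3 cells")
  zp <- rbind(z[1, , drop = FALSE], z, z[nr, , drop = FALSE])
  zp <- cbind(zp[, 1, drop = FALSE], zp, zp[, nc, drop = FALSE])
  sh <- function(dr, dc) zp[(1 + dr):(nr + dr), (1 + dc):(nc + dc)]
  cs <- dem$cell_size
  # row 1 is north: dr = 0 looks one row north, dr = 2 one row south
  gx <- ((sh(0, 2) + 2 * sh(1, 2) + sh(2, 2)) -
           (sh(0, 0) + 2 * sh(1, 0) + sh(2, 0))) / (8 * cs)
  gy <- ((sh(0, 0) + 2 * sh(0, 1) + sh(0, 2)) -
           (sh(2, 0) + 2 * sh(2, 1) + sh(2, 2))) / (8 * cs) # toward north
  slope <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  aspect <- (atan2(-gx, -gy) * 180 / pi) %% 360
  aspect[slope == 0] <- -1
  list(slope = raster_grid(slope, same_spec(dem), "slope", "degrees"),
       aspect = raster_grid(aspect, same_spec(dem), "aspect", "degrees"))
}

# Rasterize a feature class onto a grid: a cell is a source cell when its
# centre lies inside a polygon or when a (densely sampled) boundary/line
# passes through it. Returns 1-based (row, col) matrix of source cells.
rasterize_features <- function(geoms, spec, polygon) {
  pts_r <- integer(0); pts_c <- integer(0)
  cc <- cell_centers(spec)
  for (geom in geoms) {
    geom <- as.matrix(geom)
    if (polygon && nrow(geom) >= 3L) {
      grid <- expand.grid(col = seq_len(spec$ncol), row = seq_len(spec$nrow))
      inside <- points_in_polygon(geom, cc$x[grid$col], cc$y[grid$row])
      pts_r <- c(pts_r, grid$row[inside]); pts_c <- c(pts_c, grid$col[inside])
      geom <- rbind(geom, geom[1L, ]) # close the ring for the boundary pass
    }
    dense <- densify_polyline(geom, spec$cell_size / 3)
    cl <- point_cell(spec, dense[, 1], dense[, 2])
    ok <- cl$inside
    pts_r <- c(pts_r, cl$row[ok]); pts_c <- c(pts_c, cl$col[ok])
  }
  unique(cbind(row = pts_r, col = pts_c))
}

#' Euclidean-distance layer to a feature class
#'
#' The feature class is rasterized (source cells are all cells the geometry
#' touches) and every cell receives the Euclidean distance from its centre to
#' the nearest source-cell centre; source cells are 0. This matches raster-GIS
#' "Euclidean distance" semantics; it differs from exact vector distance by at
#' most one cell diagonal.
#'
#' @param features A `feature_set` (see [generate_features()]) or a plain
#'   named list of geometry lists.
#' @param class Feature-class name (`"lake"`, `"trails"`, `"dogtrail"`,
#'   `"highway"`, `"buildings"`).
#' @param spec Target [grid_spec()].
#' @param polygon Treat geometries as filled polygons; default for `lake` and
#'   `buildings`.
#' @return A [raster_grid()] of distances (m).
#' @export
euclidean_distance <- function(features, class, spec,
                               polygon = class %in% c("lake", "buildings")) {
  geoms <- features[[class]]
  if (is.null(geoms) || length(geoms) == 0L) {
    stop(sprintf("empty feature class: '%s'", class))
  }
  src <- rasterize_features(geoms, spec, polygon)
  if (nrow(src) == 0L) {
    stop(sprintf("feature class '%s' does not intersect the grid", class))
  }
  d <- .edt_cpp(src[, 1] - 1L, src[, 2] - 1L, spec$nrow, spec$ncol,
                spec$cell_size)
  raster_grid(d, spec, paste0("dist_", class), "m")
}

#' Build the standard predictor stack from a cloud and features
#'
#' Runs the full gridding chain (vegetation merge, DEM, canopy height and
#' density, slope/aspect, five distance layers) and returns the ten aligned
#' predictors.
#'
#' @param cloud Raw classified point cloud.
#' @param features A `feature_set`.
#' @param spec Target [grid_spec()].
#' @return A `predictor_stack` with layers `canopy_height`, `canopy_density`,
#'   `slope`, `aspect`, `elevation`, `dist_lake`, `dist_trails`,
#'   `dist_dogtrail`, `dist_highway`, `dist_buildings`.
#' @export
build_predictor_stack <- function(cloud, features, spec) {
  cloud <- merge_vegetation(cloud)
  dem <- build_dem(cloud, spec)
  sa <- slope_aspect(dem)
  stack_predictors(list(
    canopy_height = canopy_height(cloud, dem, spec),
    canopy_density = canopy_density(cloud, spec),
    slope = sa$slope,
    aspect = sa$aspect,
    elevation = dem,
    dist_lake = euclidean_distance(features, "lake", spec),
    dist_trails = euclidean_distance(features, "trails", spec),
    dist_dogtrail = euclidean_distance(features, "dogtrail", spec),
    dist_highway = euclidean_distance(features, "highway", spec),
    dist_buildings = euclidean_distance(features, "buildings", spec)
  ))
}
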