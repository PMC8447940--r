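# Score a regular lattice with the fitted model, interpolate to a full RIO
# raster, and classify occupancy by the one-sided 95% presence-coverage rule.

#' Regular point lattice inside the study area
#'
#' Axis-aligned lattice at predictor cell centres (default spacing = the cell
#' size, so every cell centre is a lattice point), clipped to the study-area
#' polygon. Coarser lattices take every k-th centre.
#'
#' @param area_polygon Study-area ring.
#' @param spec The predictor [grid_spec()].
#' @param spacing Lattice spacing in meters (default: cell size). A spacing
#'   below the cell size triggers a warning and is raised to the cell size.
#' @return Data.frame with columns `id`, `x`, `y`.
#' @export
make_lattice <- function(area_polygon, spec, spacing = spec$cell_size) {
  if (spacing <= 0) stop("spacing must be > 0")
  if (spacing < spec$cell_size) {
    warning("lattice spacing below the cell size; using the cell size")
    spacing <- spec$cell_size
  }
  step <- max(1L, round(spacing / spec$cell_size))
  cc <- cell_centers(spec)
  xs <- cc$x[seq(1L, spec$ncol, by = step)]
  ys <- cc$y[seq(1L, spec$nrow, by = step)]
  grid <- expand.grid(x = xs, y = ys)
  inside <- points_in_polygon(area_polygon, grid$x, grid$y)
  pts <- grid[inside, , drop = FALSE]
  if (nrow(pts) == 0L) stop("lattice has no points inside the area polygon")
  data.frame(id = seq_len(nrow(pts)), x = pts$x, y = pts$y)
}

#' Score a lattice with the occurrence model
#'
#' Extracts all predictor values at each lattice point and evaluates the
#' model. Output columns mirror the deposited prediction tables: `PROB_1` is
#' the RIO and `PROB_0 = 1 - PROB_1`.
#'
#' @param model A fitted [rio_boost()] model.
#' @param lattice Data.frame with `id`, `x`, `y` from [make_lattice()].
#' @param stack A gap-filled `predictor_stack`.
#' @return Data.frame with columns `id`, `x`, `y`, `PROB_0`, `PROB_1`.
#' @export
score_lattice <- function(model, lattice, stack) {
  vals <- extract_values(lattice, stack)
  rio <- predict(model, vals)
  data.frame(id = lattice$id, x = lattice$x, y = lattice$y,
             PROB_0 = 1 - rio, PROB_1 = rio)
}

#' Inverse-distance-weighted RIO surface
#'
#' Interpolates scored lattice points onto the full grid with
#' inverse-distance weighting over the `k` nearest points (weight
#' \eqn{d^{-power}}). A cell whose centre coincides with a lattice point
#' (within 1e-9 m) takes that point's value exactly, so the default
#' cell-centre lattice makes the surface an identity on covered cells.
#'
#' @param scored Data.frame from [score_lattice()] (needs `x`, `y`,
#'   `PROB_1`).
#' @param spec Target [grid_spec()].
#' @param power IDW exponent (default 2).
#' @param k Neighbour count (default 12).
#' @return An object of class `rio_surface`: a [raster_grid()] with attribute
#'   `provenance` (lattice size, IDW parameters).
#' @export
idw_interpolate <- function(scored, spec, power = 2, k = 12) {
  if (k < 1) stop("k must be >= 1")
  if (nrow(scored) < 1L) stop("at least one scored point is required")
  cc <- cell_centers(spec)
  grid <- expand.grid(col = seq_len(spec$ncol), row = seq_len(spec$nrow))
  est <- .knn_idw_cpp(scored$x, scored$y, scored$PROB_1,
                      cc$x[grid$col], cc$y[grid$row],
                      as.integer(k), power)
  m <- matrix(NA_real_, spec$nrow, spec$ncol)
  m[cbind(grid$row, grid$col)] <- est
  out <- raster_grid(m, spec, "rio", "index")
  attr(out, "provenance") <- list(n_points = nrow(scored), power = power,
                                  k = k)
  class(out) <- c("rio_surface", class(out))
  out
}

#' Occupancy threshold from presence RIO values
#'
#' The RIO cutoff below which only `1 - coverage` of presence values fall:
#' the k-th smallest presence RIO with `k = ceiling((1 - coverage) * N)`
#' (nearest-rank lower quantile). With the default one-sided 95% coverage the
#' fraction of presence values at or above the threshold lies in
#' `[coverage, coverage + 1/N]`.
#'
#' @param rio_at_presences RIO values extracted at (>= 20) presence points.
#' @param coverage Target presence coverage (default 0.95).
#' @return The threshold `t_occupied`.
#' @export
occupancy_threshold <- function(rio_at_presences, coverage = 0.95) {
  v <- rio_at_presences[is.finite(rio_at_presences)]
  n <- length(v)
  if (n < 20L) stop("need at least 20 presence values for a stable threshold")
  # tolerance guards ceiling() against floating-point (1 - coverage) noise
  k <- max(1L, ceiling((1 - coverage) * n - 1e-9))
  sort(v)[k]
}

#' Binary occupancy map from a RIO surface
#'
#' A cell is occupied iff its RIO is at or above the threshold (closed
#' inequality). Reports the occupied area in hectares and, when presence
#' points are supplied, how many fall in occupied cells.
#'
#' @param surface A `rio_surface` (or any [raster_grid()] of RIO values).
#' @param t_occupied Threshold in (0, 1).
#' @param presences Optional data.frame of presence points (`x`, `y`).
#' @param area_polygon Optional ring; when given, area and counts consider
#'   only cells whose centres fall inside it.
#' @return An object of class `occupancy_map`: list with the binary `raster`,
#'   `t_occupied`, `occupied_area_ha`, and (if presences were given)
#'   `n_presences_occupied` / `presence_fraction`.
#' @export
classify_occupancy <- function(surface, t_occupied, presences = NULL,
                               area_polygon = NULL) {
  if (!is.finite(t_occupied) || t_occupied <= 0 || t_occupied >= 1) {
    stop("t_occupied must lie strictly between 0 and 1")
  }
  occ <- (surface$values >= t_occupied) * 1
  consider <- matrix(TRUE, surface$nrow, surface$ncol)
  if (!is.null(area_polygon)) {
    cc <- cell_centers(surface)
    grid <- expand.grid(col = seq_len(surface$ncol), row = seq_len(surface$nrow))
    inside <- points_in_polygon(area_polygon, cc$x[grid$col], cc$y[grid$row])
    consider[cbind(grid$row, grid$col)] <- inside
  }
  area_ha <- sum(occ == 1 & consider) * surface$cell_size^2 / 1e4
  out <- list(
    raster = raster_grid(occ, same_spec(surface), "occupied", "binary"),
    t_occupied = t_occupied,
    occupied_area_ha = area_ha
  )
  if (!is.null(presences) && nrow(presences)) {
    cl <- point_cell(surface, presences$x, presences$y)
    inocc <- cl$inside & occ[cbind(pmin(pmax(cl$row, 1L), surface$nrow),
                                   pmin(pmax(cl$col, 1L), surface$ncol))] == 1
    out$n_presences_occupied <- sum(inocc)
    out$presence_fraction <- sum(inocc) / nrow(presences)
  }
  structure(out, class = "occupancy_map")
}

#' @export
print.occupancy_map <- function(x, ...) {
  cat(sprintf("occupancy_map: threshold %.4g, occupied area %.2f ha\n",
              x$t_occupied, x$occupied_area_ha))
  if (!is.null(x$n_presences_occupied)) {
    cat(sprintf("  presences in occupied cells: %d (%.1f%%)\n",
                x$n_presences_occupied, 100 * x$presence_fraction))
  }
  invisible(x)
}
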