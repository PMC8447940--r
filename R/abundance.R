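# Midden counts and occupied areas to density, territory-size and population
# estimates; independent-point validation against the RIO surface.

# round half-up at `digits` decimal places (printed estimates use commercial
# rounding, not banker's)
round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Density, territory and population estimates from midden counts
#'
#' Exact rational arithmetic, rounded half-up only for reporting. With `n`
#' middens over `area_ha` hectares:
#' density = n / area; mean territory = area / n; the population is bounded by
#' `floor(n / (1 + max_secondary))` squirrels (each owning one primary plus up
#' to `max_secondary` secondary middens) and `n` squirrels (one midden each).
#'
#' @param n_middens Midden count (>= 1).
#' @param area_ha Reference area in hectares (> 0).
#' @param max_secondary Maximum secondary middens per squirrel (default 3).
#' @return An object of class `abundance_estimate` with raw values plus
#'   reported (2 dp, and 1 dp for density) fields.
#' @export
abundance_summary <- function(n_middens, area_ha, max_secondary = 3) {
  if (n_middens < 1 || area_ha <= 0 || max_secondary < 0) {
    stop("n_middens must be >= 1, area_ha > 0 and max_secondary >= 0")
  }
  density <- n_middens / area_ha
  territory <- area_ha / n_middens
  pop_high <- as.integer(n_middens)
  pop_low <- as.integer(floor(n_middens / (1 + max_secondary)))
  dens_low <- pop_low / area_ha
  dens_high <- pop_high / area_ha
  structure(list(
    n_middens = as.integer(n_middens), area_ha = area_ha,
    max_secondary = as.integer(max_secondary),
    density_per_ha_raw = density,
    density_per_km2_raw = 100 * density,
    territory_ha_raw = territory,
    pop_low = pop_low, pop_high = pop_high,
    density_range_per_ha_raw = c(dens_low, dens_high),
    # reported precision
    density_per_ha = round_half_up(density, 2),
    density_per_ha_1dp = round_half_up(density, 1),
    density_per_km2 = round_half_up(100 * density, 0),
    territory_ha = round_half_up(territory, 2),
    density_range_per_ha = round_half_up(c(dens_low, dens_high), 2)
  ), class = "abundance_estimate")
}

#' @export
print.abundance_estimate <- function(x, ...) {
  cat(sprintf("abundance_estimate: %d middens over %.2f ha\n",
              x$n_middens, x$area_ha))
  cat(sprintf("  midden density: %.2f / ha (%.0f / km^2)\n",
              x$density_per_ha, x$density_per_km2))
  cat(sprintf("  mean territory: %.2f ha (one midden per squirrel)\n",
              x$territory_ha))
  cat(sprintf("  population: %d-%d squirrels (up to %d secondary middens)\n",
              x$pop_low, x$pop_high, x$max_secondary))
  cat(sprintf("  density range: %.2f-%.2f squirrels / ha\n",
              x$density_range_per_ha[1], x$density_range_per_ha[2]))
  invisible(x)
}

#' Validate independent points against the RIO surface
#'
#' Extracts the RIO at each independent point (nearest cell) and summarizes:
#' min, first and third quartile (type-7 linear interpolation), mean, max,
#' and the fraction of point RIOs strictly above the mean RIO of the scored
#' lattice (the "above average prediction" rate).
#'
#' @param surface A `rio_surface`.
#' @param points Data.frame of independent presence points (`x`, `y`).
#' @param lattice_scores Scored lattice from [score_lattice()]; its `PROB_1`
#'   mean is the grid reference level.
#' @return An object of class `validation_report`.
#' @export
validate_points <- function(surface, points, lattice_scores) {
  if (is.null(points) || nrow(points) == 0L) stop("empty validation point set")
  cl <- point_cell(surface, points$x, points$y)
  if (any(!cl$inside)) stop("validation points outside the surface extent")
  rio <- surface$values[cbind(cl$row, cl$col)]
  grid_mean <- mean(lattice_scores$PROB_1)
  q <- quantile(rio, c(0.25, 0.75), type = 7, names = FALSE)
  structure(list(
    n_points = nrow(points),
    mean = mean(rio), min = min(rio), max = max(rio),
    q1 = q[1], q3 = q[2],
    grid_mean = grid_mean,
    frac_above_grid_mean = mean(rio > grid_mean),
    rio = rio
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("validation_report: %d independent points\n", x$n_points))
  cat(sprintf("  RIO min %.4f | q1 %.4f | mean %.4f | q3 %.4f | max %.4f\n",
              x$min, x$q1, x$mean, x$q3, x$max))
  cat(sprintf("  %.0f%% of points score above the grid mean (%.4f)\n",
              100 * x$frac_above_grid_mean, x$grid_mean))
  invisible(x)
}
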