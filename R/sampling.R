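# Training "data cube": presences, random pseudo-absences, per-point
# predictor extraction, and class-balancing weights.

#' Uniform random pseudo-absence points in a polygon
#'
#' Rejection sampling from the polygon's bounding box; deterministic per seed.
#'
#' @param area_polygon Two-column ring of the sampling area.
#' @param n Number of points (the emulated design uses 600).
#' @param seed Integer seed.
#' @return Data.frame with columns `id`, `x`, `y`.
#' @export
random_absences <- function(area_polygon, n, seed) {
  if (n < 1L) stop("n must be >= 1")
  area_polygon <- as.matrix(area_polygon)
  if (nrow(area_polygon) < 3L || polygon_area(area_polygon) <= 0) {
    stop("degenerate polygon")
  }
  xr <- range(area_polygon[, 1]); yr <- range(area_polygon[, 2])
  with_seed(seed, 505L, {
    xs <- numeric(0); ys <- numeric(0)
    while (length(xs) < n) {
      m <- max(2L * (n - length(xs)), 64L)
      cx <- runif(m, xr[1], xr[2]); cy <- runif(m, yr[1], yr[2])
      ok <- points_in_polygon(area_polygon, cx, cy)
      xs <- c(xs, cx[ok]); ys <- c(ys, cy[ok])
    }
    data.frame(id = seq_len(n), x = xs[seq_len(n)], y = ys[seq_len(n)])
  })
}

#' Extract predictor values at points
#'
#' Nearest-cell extraction (the value of the cell containing the point, no
#' interpolation) for every layer of the stack, under the half-open edge rule.
#'
#' @param points Data.frame with columns `x`, `y` (other columns preserved).
#' @param stack A `predictor_stack` that has been gap-filled (no no-data).
#' @return `points` with one added column per layer.
#' @export
extract_values <- function(points, stack) {
  stopifnot(inherits(stack, "predictor_stack"))
  sp <- attr(stack, "spec")
  cl <- point_cell(sp, points$x, points$y)
  if (any(!cl$inside)) {
    stop("points outside the stack extent: ",
         paste(utils::head(which(!cl$inside), 10L), collapse = ", "))
  }
  out <- points
  for (nm in names(stack)) {
    v <- stack[[nm]]$values[cbind(cl$row, cl$col)]
    if (any(!is.finite(v))) {
      stop(sprintf("no-data cell encountered in layer '%s'; gap-fill the stack first", nm))
    }
    out[[nm]] <- v
  }
  out
}

#' Class-balancing weights for a presence/absence table
#'
#' Absences keep weight 1; presences receive `n_absence / n_presence`, so the
#' summed weight of each class is equal (the equal-ratio weighting used when
#' training the occurrence model).
#'
#' @param table Data.frame with a binary `label` column (1 presence,
#'   0 absence).
#' @return The table with a `weight` column added or replaced.
#' @export
balance_weights <- function(table) {
  if (!"label" %in% names(table)) stop("table must have a 'label' column")
  n1 <- sum(table$label == 1)
  n0 <- sum(table$label == 0)
  if (n1 == 0L || n0 == 0L) stop("both classes must be non-empty")
  table$weight <- ifelse(table$label == 1, n0 / n1, 1)
  table
}

#' Build the training data cube
#'
#' Combines presence points and random pseudo-absences, extracts all predictor
#' values, and applies class-balancing weights. The background sampling
#' density (points per hectare) is attached as attribute `sampling_density`.
#'
#' @param presences Data.frame with `x`, `y` columns of presence points.
#' @param area_polygon Sampling-area ring for the pseudo-absences.
#' @param stack A gap-filled `predictor_stack`.
#' @param n_absence Number of pseudo-absences (default 600).
#' @param seed Integer seed for the absence draw.
#' @param min_dist Optional minimum distance (m) from any presence for an
#'   absence to be kept (off by default; the emulated design used none).
#' @return A data.frame ("sample table") with columns `id`, `x`, `y`, `label`,
#'   `weight` and one column per predictor.
#' @export
build_sample_table <- function(presences, area_polygon, stack,
                               n_absence = 600, seed = 1L, min_dist = 0) {
  stopifnot(nrow(presences) >= 1L)
  abs_pts <- random_absences(area_polygon, n_absence, seed)
  if (min_dist > 0) {
    keep <- vapply(seq_len(nrow(abs_pts)), function(i) {
      min((presences$x - abs_pts$x[i])^2 + (presences$y - abs_pts$y[i])^2) >=
        min_dist^2
    }, logical(1))
    abs_pts <- abs_pts[keep, , drop = FALSE]
    if (nrow(abs_pts) == 0L) stop("min_dist filtered out every absence")
  }
  pts <- rbind(
    data.frame(id = seq_len(nrow(presences)), x = presences$x,
               y = presences$y, label = 1L),
    data.frame(id = nrow(presences) + seq_len(nrow(abs_pts)), x = abs_pts$x,
               y = abs_pts$y, label = 0L)
  )
  tab <- balance_weights(extract_values(pts, stack))
  tab <- tab[c("id", "x", "y", "label", "weight",
               setdiff(names(tab), c("id", "x", "y", "label", "weight")))]
  attr(tab, "sampling_density") <-
    nrow(tab) / (polygon_area(area_polygon) / 1e4)
  tab
}
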