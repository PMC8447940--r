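#' Planar grid geometry
#'
#' A `grid_spec` describes a north-up, square-cell planar grid: the outer
#' corner of the north-west cell, the cell size, and the number of rows and
#' columns. Row 1 is the northernmost row. The centre of cell \eqn{(r, c)}
#' (1-based) is at \eqn{(x_0 + (c - 1/2)\,s,\; y_0 - (r - 1/2)\,s)} where
#' \eqn{s} is the cell size.
#'
#' Cell membership is half-open on shared edges: a point lying exactly on a
#' vertical cell boundary belongs to the cell to its east, and a point on a
#' horizontal boundary belongs to the cell to its south, so every point is
#' counted in exactly one cell.
#'
#' @param origin_x,origin_y Coordinates (m) of the outer (north-west) corner
#'   of the north-west cell.
#' @param cell_size Cell edge length in meters; must be positive.
#' @param nrow,ncol Grid dimensions.
#' @param crs Free-text tag for the (planar, meters) coordinate reference
#'   system carried through all outputs; no reprojection is ever performed.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(origin_x, origin_y, cell_size, nrow, ncol,
                      crs = "LOCAL_METERS") {
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0) {
    stop("configuration error: cell_size must be a positive number")
  }
  if (nrow < 1L || ncol < 1L) stop("grid must have at least one cell")
  structure(
    list(origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
         cell_size = as.numeric(cell_size), nrow = as.integer(nrow),
         ncol = as.integer(ncol), crs = crs),
    class = "grid_spec"
  )
}

#' Raster grid of one variable
#'
#' Couples a [grid_spec()] with an `nrow x ncol` matrix of values. `NA` is the
#' no-data sentinel and is never a valid value.
#'
#' @param values Numeric matrix with `spec$nrow` rows and `spec$ncol` columns
#'   (row 1 = north), or a single number recycled to the full grid.
#' @param spec A [grid_spec()].
#' @param name Variable name (e.g. `"canopy_height"`).
#' @param units Measurement units (e.g. `"m"`, `"fraction"`, `"degrees"`).
#' @return An object of class `raster_grid` (which inherits `grid_spec`).
#' @export
raster_grid <- function(values, spec, name = "value", units = "") {
  stopifnot(inherits(spec, "grid_spec"))
  if (length(values) == 1L) {
    values <- matrix(as.numeric(values), spec$nrow, spec$ncol)
  }
  values <- as.matrix(values)
  if (nrow(values) != spec$nrow || ncol(values) != spec$ncol) {
    stop("values matrix does not match grid dimensions")
  }
  storage.mode(values) <- "double"
  out <- unclass(spec)
  out$values <- values
  out$name <- name
  out$units <- units
  structure(out, class = c("raster_grid", "grid_spec"))
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("raster_grid '%s' [%s]: %d x %d cells of %g m (crs %s)\n",
              x$name, x$units, x$nrow, x$ncol, x$cell_size, x$crs))
  if (length(v)) {
    cat(sprintf("  range %.4g .. %.4g, mean %.4g, %d no-data cells\n",
                min(v), max(v), mean(v), sum(!is.finite(x$values))))
  }
  invisible(x)
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells of %g m, origin (%.1f, %.1f), crs %s\n",
              x$nrow, x$ncol, x$cell_size, x$origin_x, x$origin_y, x$crs))
  invisible(x)
}

#' Cell-centre coordinates of a grid
#'
#' @param spec A [grid_spec()] or [raster_grid()].
#' @return A list with `x` (length `ncol`, west to east) and `y` (length
#'   `nrow`, north to south) centre coordinates.
#' @export
cell_centers <- function(spec) {
  list(
    x = spec$origin_x + (seq_len(spec$ncol) - 0.5) * spec$cell_size,
    y = spec$origin_y - (seq_len(spec$nrow) - 0.5) * spec$cell_size
  )
}

#' Locate points on a grid
#'
#' Maps planar coordinates to 1-based (row, col) indices under the half-open
#' edge rule (shared edges belong to the east/south cell).
#'
#' @param spec A [grid_spec()].
#' @param x,y Point coordinates (m).
#' @return A data.frame with columns `row`, `col`, and logical `inside`.
#' @export
point_cell <- function(spec, x, y) {
  col <- floor((x - spec$origin_x) / spec$cell_size) + 1
  row <- floor((spec$origin_y - y) / spec$cell_size) + 1
  inside <- col >= 1 & col <= spec$ncol & row >= 1 & row <= spec$nrow
  data.frame(row = as.integer(row), col = as.integer(col), inside = inside)
}

#' Test two grids for exact alignment
#'
#' @param a,b Grids to compare.
#' @return `TRUE` if origin, cell size and dimensions are identical.
#' @export
grids_aligned <- function(a, b) {
  isTRUE(all.equal(a$origin_x, b$origin_x, tolerance = 1e-9)) &&
    isTRUE(all.equal(a$origin_y, b$origin_y, tolerance = 1e-9)) &&
    a$cell_size == b$cell_size && a$nrow == b$nrow && a$ncol == b$ncol
}

same_spec <- function(g) grid_spec(g$origin_x, g$origin_y, g$cell_size,
                                   g$nrow, g$ncol, g$crs)

#' Assemble aligned predictor rasters into a named stack
#'
#' Asserts that every layer shares the first layer's origin, cell size and
#' dimensions, then returns them as an ordered, named stack. The standard
#' predictor set has ten layers: canopy height, canopy density, slope, aspect,
#' elevation, and Euclidean distances to lake, trails, dog trail, highway and
#' buildings.
#'
#' @param ... Named [raster_grid()] layers, or a single named list of them.
#' @return An object of class `predictor_stack`: a named list of layers with
#'   the shared [grid_spec()] as attribute `spec`.
#' @export
stack_predictors <- function(...) {
  layers <- list(...)
  if (length(layers) == 1L && !inherits(layers[[1L]], "raster_grid")) {
    layers <- layers[[1L]]
  }
  if (length(layers) < 1L) stop("at least one raster is required")
  nms <- names(layers)
  if (is.null(nms) || any(!nzchar(nms))) {
    nms <- vapply(layers, function(l) l$name, character(1))
  }
  names(layers) <- nms
  ref <- layers[[1L]]
  for (i in seq_along(layers)) {
    if (!inherits(layers[[i]], "raster_grid")) {
      stop("layer '", nms[i], "' is not a raster_grid")
    }
    if (!grids_aligned(ref, layers[[i]])) {
      stop(sprintf("alignment error: layer '%s' does not align with '%s'",
                   nms[i], nms[1L]))
    }
  }
  structure(layers, spec = same_spec(ref), class = "predictor_stack")
}

#' @export
print.predictor_stack <- function(x, ...) {
  sp <- attr(x, "spec")
  cat(sprintf("predictor_stack: %d layers on %d x %d cells of %g m\n",
              length(x), sp$nrow, sp$ncol, sp$cell_size))
  cat(" ", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}

#' Flatten a predictor stack to a per-cell data.frame
#'
#' @param x A `predictor_stack`.
#' @param row.names,optional Unused, for generic compatibility.
#' @param ... Unused.
#' @return A data.frame with one row per cell (row-major, north row first) and
#'   one column per layer, plus `x`/`y` cell-centre coordinates and
#'   `row`/`col` indices.
#' @export
as.data.frame.predictor_stack <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  sp <- attr(x, "spec")
  cc <- cell_centers(sp)
  grid <- expand.grid(col = seq_len(sp$ncol), row = seq_len(sp$nrow))
  out <- data.frame(
    row = grid$row, col = grid$col,
    x = cc$x[grid$col], y = cc$y[grid$row]
  )
  for (nm in names(x)) {
    out[[nm]] <- as.vector(t(x[[nm]]$values))[(grid$row - 1L) * sp$ncol +
                                                grid$col]
  }
  out
}
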