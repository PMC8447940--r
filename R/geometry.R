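# Light-weight planar geometry on simple features:
# a polygon is a closed ring as a two-column matrix (x, y); a polyline is an
# open two-column matrix; a feature class is a list of such matrices.

#' Point-in-polygon test
#'
#' Even-odd test of points against one polygon ring (delegates to
#' [mgcv::in.out()]).
#'
#' @param poly Two-column matrix of ring vertices (closed or open; the ring is
#'   closed implicitly).
#' @param x,y Point coordinates.
#' @return Logical vector.
#' @export
points_in_polygon <- function(poly, x, y) {
  poly <- as.matrix(poly)
  if (nrow(poly) < 3L) stop("degenerate polygon: fewer than 3 vertices")
  bnd <- poly
  if (!all(bnd[1L, ] == bnd[nrow(bnd), ])) bnd <- rbind(bnd, bnd[1L, ])
  mgcv::in.out(bnd, cbind(as.numeric(x), as.numeric(y)))
}

#' Shoelace area of a polygon ring
#'
#' @param poly Two-column vertex matrix.
#' @return Absolute area in squared coordinate units.
#' @export
polygon_area <- function(poly) {
  poly <- as.matrix(poly)
  if (all(poly[1L, ] == poly[nrow(poly), ])) poly <- poly[-nrow(poly), , drop = FALSE]
  x <- poly[, 1L]; y <- poly[, 2L]
  n <- nrow(poly)
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Polygon validity predicate
#'
#' A ring is treated as valid when it has at least three distinct vertices,
#' finite coordinates, positive area, and no two non-adjacent edges intersect
#' (simple, non-self-intersecting ring).
#'
#' @param poly Two-column vertex matrix.
#' @return Logical scalar.
#' @export
polygon_is_valid <- function(poly) {
  poly <- as.matrix(poly)
  if (all(poly[1L, ] == poly[nrow(poly), ])) poly <- poly[-nrow(poly), , drop = FALSE]
  if (nrow(poly) < 3L || !all(is.finite(poly))) return(FALSE)
  if (polygon_area(poly) <= 0) return(FALSE)
  n <- nrow(poly)
  seg <- function(i) rbind(poly[i, ], poly[if (i == n) 1L else i + 1L, ])
  inter <- function(p1, p2, p3, p4) {
    d1 <- (p4[1] - p3[1]) * (p1[2] - p3[2]) - (p4[2] - p3[2]) * (p1[1] - p3[1])
    d2 <- (p4[1] - p3[1]) * (p2[2] - p3[2]) - (p4[2] - p3[2]) * (p2[1] - p3[1])
    d3 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
    d4 <- (p2[1] - p1[1]) * (p4[2] - p1[2]) - (p2[2] - p1[2]) * (p4[1] - p1[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next # adjacent through the closure
      a <- seg(i); b <- seg(j)
      if (inter(a[1, ], a[2, ], b[1, ], b[2, ])) return(FALSE)
    }
  }
  TRUE
}

# Sample points along a polyline at most `step` apart (vertices included).
densify_polyline <- function(line, step) {
  line <- as.matrix(line)
  out <- list(line[1L, , drop = FALSE])
  for (i in seq_len(nrow(line) - 1L)) {
    a <- line[i, ]; b <- line[i + 1L, ]
    len <- sqrt(sum((b - a)^2))
    nseg <- max(1L, ceiling(len / step))
    t <- seq_len(nseg) / nseg
    out[[length(out) + 1L]] <- cbind(a[1] + t * (b[1] - a[1]),
                                     a[2] + t * (b[2] - a[2]))
  }
  do.call(rbind, out)
}

# Regular rectangle ring helper.
rect_ring <- function(xmin, ymin, xmax, ymax) {
  cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax))
}

# Circle approximated by a regular polygon.
circle_ring <- function(cx, cy, r, n = 48L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}
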