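#' Gate geometries
#'
#' A gate is a rectangular or polygonal region drawn on a two-dimensional
#' feature scatter. `rectangle_gate()` and `polygon_gate()` construct
#' validated geometry objects; [point_in_geometry()] is the single membership
#' predicate shared by forward gating and back-gating.
#'
#' Boundary policy: points exactly on an edge are INSIDE for both geometries,
#' the usual flow-cytometry convention. Polygons use the even-odd fill rule;
#' they are implicitly closed (last vertex joins the first), and a
#' self-intersecting polygon is accepted with a validation warning since it
#' can arise from a free-hand lasso.
#'
#' @param x_min,x_max,y_min,y_max rectangle bounds, `x_min < x_max`,
#'   `y_min < y_max`.
#' @param x,y polygon vertex coordinates (>= 3 vertices, nonzero area).
#' @return an object of class `gate_geometry`.
#' @examples
#' rectangle_gate(0, 1, 0, 2)
#' polygon_gate(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' @name gate_geometry
NULL

#' @rdname gate_geometry
#' @export
rectangle_gate <- function(x_min, x_max, y_min, y_max) {
  x_min <- unname(as.numeric(x_min)); x_max <- unname(as.numeric(x_max))
  y_min <- unname(as.numeric(y_min)); y_max <- unname(as.numeric(y_max))
  vals <- c(x_min, x_max, y_min, y_max)
  if (length(vals) != 4L || anyNA(vals)) {
    stop_fmt("rectangle bounds must be four numbers")
  }
  if (!(x_min < x_max) || !(y_min < y_max)) {
    stop_fmt("rectangle requires x_min < x_max and y_min < y_max")
  }
  structure(list(kind = "rectangle", x_min = x_min, x_max = x_max,
                 y_min = y_min, y_max = y_max),
            class = "gate_geometry")
}

#' @rdname gate_geometry
#' @export
polygon_gate <- function(x, y) {
  if (length(x) != length(y)) stop_fmt("polygon x and y differ in length")
  if (length(x) < 3L) stop_fmt("polygon needs at least 3 vertices")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop_fmt("polygon vertices must be finite")
  }
  # a self-intersecting outline (e.g. a bowtie) can have zero signed area
  # yet enclose points under the even-odd rule, so it is accepted with a
  # warning; only a non-self-intersecting zero-area outline is degenerate
  if (polygon_self_intersects(x, y)) {
    warn_fmt("polygon is self-intersecting; even-odd fill rule applies")
  } else if (polygon_signed_area(x, y) == 0) {
    stop_fmt("degenerate polygon: zero area")
  }
  structure(list(kind = "polygon", x = as.numeric(x), y = as.numeric(y)),
            class = "gate_geometry")
}

#' @export
print.gate_geometry <- function(x, ...) {
  if (x$kind == "rectangle") {
    cat(sprintf("rectangle gate x:[%g, %g] y:[%g, %g]\n",
                x$x_min, x$x_max, x$y_min, x$y_max))
  } else {
    cat(sprintf("polygon gate with %d vertices\n", length(x$x)))
  }
  invisible(x)
}

polygon_signed_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

# Segment-pair crossing test over non-adjacent edges of the closed polygon.
polygon_self_intersects <- function(x, y) {
  n <- length(x)
  x2 <- c(x, x[1L]); y2 <- c(y, y[1L])
  seg_cross <- function(i, j) {
    p1 <- c(x2[i], y2[i]); p2 <- c(x2[i + 1L], y2[i + 1L])
    p3 <- c(x2[j], y2[j]); p4 <- c(x2[j + 1L], y2[j + 1L])
    d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
    d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
    ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
  }
  for (i in seq_len(n - 2L)) {
    for (j in seq.int(i + 2L, n)) {
      if (i == 1L && j == n) next      # adjacent through closure
      if (seg_cross(i, j)) return(TRUE)
    }
  }
  FALSE
}

#' Point-in-geometry membership test
#'
#' Vectorized over points. Rectangles are boundary-inclusive on all four
#' edges; polygons use even-odd ray casting with points lying exactly on an
#' edge counted inside. Comparisons are exact floating point: membership is a
#' geometric predicate and no epsilon is applied.
#'
#' @param x,y numeric vectors of point coordinates (same length).
#' @param geometry a `gate_geometry` from [rectangle_gate()] or
#'   [polygon_gate()].
#' @return logical vector, `TRUE` where the point is inside or on the edge.
#' @export
points_in_geometry <- function(x, y, geometry) {
  stopifnot(inherits(geometry, "gate_geometry"), length(x) == length(y))
  if (geometry$kind == "rectangle") {
    return(x >= geometry$x_min & x <= geometry$x_max &
           y >= geometry$y_min & y <= geometry$y_max)
  }
  px <- geometry$x; py <- geometry$y
  n <- length(px)
  jx <- c(px[n], px[-n]); jy <- c(py[n], py[-n])
  inside <- rep(FALSE, length(x))
  on_edge <- rep(FALSE, length(x))
  for (k in seq_len(n)) {
    x1 <- jx[k]; y1 <- jy[k]; x2 <- px[k]; y2 <- py[k]
    # collinear and within the segment's bounding box => on the edge
    cross <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
    on_edge <- on_edge | (cross == 0 &
                          x >= pmin(x1, x2) & x <= pmax(x1, x2) &
                          y >= pmin(y1, y2) & y <= pmax(y1, y2))
    # even-odd crossing of the rightward horizontal ray (half-open in y)
    crosses <- ((y1 > y) != (y2 > y)) &
      (x < (x2 - x1) * (y - y1) / (y2 - y1) + x1)
    crosses[is.na(crosses)] <- FALSE
    inside <- xor(inside, crosses)
  }
  inside | on_edge
}

#' @rdname points_in_geometry
#' @param point length-2 numeric `(x, y)` for the scalar form.
#' @export
point_in_geometry <- function(point, geometry) {
  points_in_geometry(point[1L], point[2L], geometry)
}

geometry_to_list <- function(g) {
  if (g$kind == "rectangle") {
    list(kind = "rectangle",
         coords = list(x_min = g$x_min, x_max = g$x_max,
                       y_min = g$y_min, y_max = g$y_max))
  } else {
    list(kind = "polygon", coords = list(x = g$x, y = g$y))
  }
}

geometry_from_list <- function(l) {
  if (is.null(l$kind)) stop_fmt("geometry spec lacks required key 'kind'")
  if (l$kind == "rectangle") {
    cc <- l$coords
    for (k in c("x_min", "x_max", "y_min", "y_max")) {
      if (is.null(cc[[k]])) stop_fmt("rectangle geometry lacks required key '%s'", k)
    }
    rectangle_gate(cc$x_min, cc$x_max, cc$y_min, cc$y_max)
  } else if (l$kind == "polygon") {
    if (is.null(l$coords$x) || is.null(l$coords$y)) {
      stop_fmt("polygon geometry lacks required key 'x'/'y'")
    }
    polygon_gate(unlist(l$coords$x), unlist(l$coords$y))
  } else {
    stop_fmt("unknown geometry kind '%s'", l$kind)
  }
}
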