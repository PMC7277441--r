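# Planar polygon primitives used by the coverage model.
#
# Polygons are two-column numeric matrices of vertices (x, y), NOT closed
# (last vertex != first). Units are whatever the planar system carries;
# throughout the pipeline that is miles (see projection.R).

#' Signed polygon area (shoelace formula)
#'
#' Positive for counter-clockwise rings, negative for clockwise.
#'
#' @param poly Two-column numeric matrix of vertices, not closed.
#' @return Signed area in squared coordinate units.
#' @export
polygon_area_signed <- function(poly) {
  stopifnot(is.matrix(poly), ncol(poly) == 2)
  n <- nrow(poly)
  if (n < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

#' Absolute polygon area
#'
#' @inheritParams polygon_area_signed
#' @return Non-negative area.
#' @export
polygon_area <- function(poly) abs(polygon_area_signed(poly))

#' Area-weighted polygon centroid
#'
#' @inheritParams polygon_area_signed
#' @return Length-2 numeric vector (x, y).
#' @export
polygon_centroid <- function(poly) {
  n <- nrow(poly)
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(2:n, 1)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(c(mean(x), mean(y)))
  c(sum((x + x[j]) * cr), sum((y + y[j]) * cr)) / (6 * a)
}

ensure_ccw <- function(poly) {
  if (polygon_area_signed(poly) < 0) poly[rev(seq_len(nrow(poly))), , drop = FALSE] else poly
}

#' Clip a polygon against a convex polygon (Sutherland–Hodgman)
#'
#' The subject may be any simple polygon; the clip polygon must be convex
#' (circle buffers are). Returns the intersection polygon, possibly with
#' fewer than 3 vertices when the intersection is empty or degenerate.
#'
#' @param subject Two-column matrix, any simple polygon.
#' @param clip Two-column matrix, convex polygon.
#' @return Two-column matrix of the clipped polygon vertices.
#' @export
clip_polygon_convex <- function(subject, clip) {
  stopifnot(is.matrix(subject), is.matrix(clip))
  clip <- ensure_ccw(clip)
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    m <- nrow(out)
    if (m == 0) return(out)
    a <- clip[i, ]
    b <- clip[if (i == nc) 1L else i + 1L, ]
    # signed side of each subject vertex relative to directed clip edge a->b
    s <- (b[1] - a[1]) * (out[, 2] - a[2]) - (b[2] - a[2]) * (out[, 1] - a[1])
    nxt <- c(2:m, 1L)[seq_len(m)]
    if (m == 1) nxt <- 1L
    keep <- s >= 0
    crossed <- xor(keep, keep[nxt])
    denom <- s - s[nxt]
    t <- ifelse(crossed & denom != 0, s / denom, 0)
    ix <- out[, 1] + t * (out[nxt, 1] - out[, 1])
    iy <- out[, 2] + t * (out[nxt, 2] - out[, 2])
    # interleave kept vertices and edge intersections in traversal order
    xs <- rbind(ifelse(keep, out[, 1], NA_real_), ifelse(crossed, ix, NA_real_))
    ys <- rbind(ifelse(keep, out[, 2], NA_real_), ifelse(crossed, iy, NA_real_))
    sel <- !is.na(xs)
    out <- cbind(xs[sel], ys[sel])
  }
  out
}

#' Ray-casting point-in-polygon test
#'
#' Vectorized over points. Boundary behavior follows the usual even-odd
#' crossing convention and is not guaranteed on edges.
#'
#' @param pts Two-column matrix of query points.
#' @param poly Two-column matrix, simple polygon.
#' @return Logical vector, one entry per point.
#' @export
points_in_polygon <- function(pts, poly) {
  stopifnot(is.matrix(pts), ncol(pts) == 2)
  n <- nrow(poly)
  inside <- rep(FALSE, nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cond <- ((yi > pts[, 2]) != (yj > pts[, 2])) &
      (pts[, 1] < (xj - xi) * (pts[, 2] - yi) / (yj - yi) + xi)
    inside <- xor(inside, cond)
    j <- i
  }
  inside
}

#' Circle buffer polygon around a point
#'
#' Approximates a disc of the given radius as a regular polygon with
#' `4 * segments` vertices inscribed in the true circle. At the default
#' 64 segments per quarter-circle the polygon area is within 0.1% of
#' pi * r^2, far below the 51% served-rule decision margin.
#'
#' @param point Length-2 numeric (x, y) in planar units (miles).
#' @param radius_miles Buffer radius, > 0. Default 30.
#' @param segments Vertices per quarter circle. Default 64.
#' @return Two-column matrix of the buffer polygon (counter-clockwise).
#' @export
buffer_provider <- function(point, radius_miles = 30, segments = 64L) {
  if (!is.numeric(radius_miles) || length(radius_miles) != 1 || radius_miles <= 0) {
    stop("buffer radius must be a single positive number, got ", radius_miles)
  }
  stopifnot(length(point) == 2, segments >= 1)
  k <- 4L * as.integer(segments)
  ang <- 2 * pi * (seq_len(k) - 1L) / k
  cbind(point[1] + radius_miles * cos(ang), point[2] + radius_miles * sin(ang))
}

bbox_of <- function(poly) {
  c(xmin = min(poly[, 1]), ymin = min(poly[, 2]),
    xmax = max(poly[, 1]), ymax = max(poly[, 2]))
}

# Shortest distance from a point to an axis-aligned bbox (0 if inside).
point_bbox_distance <- function(pt, bb) {
  dx <- max(bb[["xmin"]] - pt[1], 0, pt[1] - bb[["xmax"]])
  dy <- max(bb[["ymin"]] - pt[2], 0, pt[2] - bb[["ymax"]])
  sqrt(dx^2 + dy^2)
}
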