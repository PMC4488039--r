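# Light planar computational geometry on simple polygons.
#
# A polygon is an n x 2 numeric matrix of vertices (columns x, y) in a
# projected CRS with metre units; the ring is implicitly closed (the first
# vertex is NOT repeated at the end). Interiors must be simple (no
# self-intersection). A "layer" is a data.frame with a `geometry`
# list-column of such matrices (see read_geojson()).

#' Polygon signed area (shoelace formula)
#'
#' Positive for counter-clockwise rings, negative for clockwise.
#'
#' @param poly n x 2 numeric matrix of vertices, ring not closed.
#' @return signed area in squared CRS units.
#' @export
poly_signed_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Polygon area (absolute), in squared CRS units
#' @inheritParams poly_signed_area
#' @export
poly_area <- function(poly) abs(poly_signed_area(poly))

#' Polygon area in hectares (CRS units assumed metres)
#' @inheritParams poly_signed_area
#' @export
poly_area_ha <- function(poly) poly_area(poly) / 1e4

#' Polygon centroid (area-weighted)
#' @inheritParams poly_signed_area
#' @return length-2 numeric (x, y).
#' @export
poly_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(c(mean(x), mean(y)))
  c(sum((x + xn) * cr) / (6 * a), sum((y + yn) * cr) / (6 * a))
}

# Ensure counter-clockwise orientation.
poly_ccw <- function(poly) {
  if (poly_signed_area(poly) < 0) poly[rev(seq_len(nrow(poly))), , drop = FALSE] else poly
}

#' Point-in-polygon test (winding number)
#'
#' Points exactly on the boundary are treated as inside.
#'
#' @param pt length-2 numeric (x, y).
#' @param poly n x 2 vertex matrix.
#' @return logical scalar.
#' @export
point_in_polygon <- function(pt, poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  # boundary check first: distance to any segment ~ 0
  if (dist_point_poly_boundary(pt, poly) < 1e-9) return(TRUE)
  wn <- 0L
  for (i in seq_len(n)) {
    if (y[i] <= pt[2]) {
      if (yn[i] > pt[2] &&
          ((xn[i] - x[i]) * (pt[2] - y[i]) - (pt[1] - x[i]) * (yn[i] - y[i])) > 0)
        wn <- wn + 1L
    } else {
      if (yn[i] <= pt[2] &&
          ((xn[i] - x[i]) * (pt[2] - y[i]) - (pt[1] - x[i]) * (yn[i] - y[i])) < 0)
        wn <- wn - 1L
    }
  }
  wn != 0L
}

# Euclidean distance from a point to a segment.
dist_point_segment <- function(pt, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt(sum((pt - a)^2)))
  t <- max(0, min(1, sum((pt - a) * ab) / len2))
  proj <- a + t * ab
  sqrt(sum((pt - proj)^2))
}

#' Distance from a point to a polygon boundary
#'
#' Minimum Euclidean distance to any edge; zero only on the boundary itself
#' (interior points also report their distance to the boundary).
#'
#' @inheritParams point_in_polygon
#' @return non-negative distance in CRS units.
#' @export
dist_point_poly_boundary <- function(pt, poly) {
  n <- nrow(poly)
  d <- Inf
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    d <- min(d, dist_point_segment(pt, poly[i, ], poly[j, ]))
  }
  d
}

#' Clip a polygon against a convex polygon (Sutherland--Hodgman)
#'
#' The clip polygon must be convex; the subject polygon may be any simple
#' polygon. Returns NULL when the intersection is empty or degenerate.
#'
#' @param subject n x 2 vertex matrix (any simple polygon).
#' @param clip m x 2 vertex matrix (must be convex).
#' @return vertex matrix of the intersection polygon, or NULL.
#' @export
clip_polygon_convex <- function(subject, clip) {
  clip <- poly_ccw(clip)
  out <- poly_ccw(subject)
  m <- nrow(clip)
  for (i in seq_len(m)) {
    if (is.null(out) || nrow(out) < 3) return(NULL)
    a <- clip[i, ]
    b <- clip[if (i == m) 1L else i + 1L, ]
    inp <- out
    out <- matrix(numeric(0), ncol = 2)
    n <- nrow(inp)
    # side > 0 <=> left of directed edge a->b (inside for CCW clip)
    side <- (b[1] - a[1]) * (inp[, 2] - a[2]) - (b[2] - a[2]) * (inp[, 1] - a[1])
    for (k in seq_len(n)) {
      kn <- if (k == n) 1L else k + 1L
      cur_in <- side[k] >= -1e-12
      nxt_in <- side[kn] >= -1e-12
      if (cur_in) out <- rbind(out, inp[k, ])
      if (cur_in != nxt_in) {
        t <- side[k] / (side[k] - side[kn])
        out <- rbind(out, inp[k, ] + t * (inp[kn, ] - inp[k, ]))
      }
    }
  }
  if (is.null(out) || nrow(out) < 3 || poly_area(out) < 1e-12) return(NULL)
  out
}

#' Area of intersection between a polygon and a convex polygon
#' @inheritParams clip_polygon_convex
#' @return area in squared CRS units (0 when disjoint).
#' @export
intersection_area_convex <- function(subject, clip) {
  p <- clip_polygon_convex(subject, clip)
  if (is.null(p)) 0 else poly_area(p)
}

#' Dilate a convex polygon outward by a distance
#'
#' Minkowski sum of a convex polygon with a disc of radius `dist`, the disc
#' approximated by `arc_segments` chords per full circle. Used to build
#' shoreline buffer zones.
#'
#' @param poly convex n x 2 vertex matrix.
#' @param dist dilation distance (> 0), CRS units.
#' @param arc_segments number of segments approximating a full circle.
#' @return vertex matrix of the dilated polygon.
#' @export
dilate_convex <- function(poly, dist, arc_segments = 64L) {
  stopifnot(dist > 0)
  poly <- poly_ccw(poly)
  n <- nrow(poly)
  step <- 2 * pi / arc_segments
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    prev <- poly[if (i == 1L) n else i - 1L, ]
    cur <- poly[i, ]
    nxt <- poly[if (i == n) 1L else i + 1L, ]
    # outward normals of the incoming and outgoing edges (CCW ring)
    d1 <- cur - prev; d2 <- nxt - cur
    a1 <- atan2(-d1[1], d1[2])  # angle of outward normal (dy, -dx)
    a2 <- atan2(-d2[1], d2[2])
    if (a2 < a1) a2 <- a2 + 2 * pi
    ts <- seq(a1, a2, by = step)
    if (ts[length(ts)] < a2) ts <- c(ts, a2)
    arc <- cbind(cur[1] + dist * cos(ts), cur[2] + dist * sin(ts))
    out <- rbind(out, arc)
  }
  out
}

# Axis-aligned rectangle polygon helper (xmin, ymin, xmax, ymax).
rect_poly <- function(xmin, ymin, xmax, ymax) {
  cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax))
}
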