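# Minimal planar polygon primitives used by the geometry module.
# Polygons are n x 2 numeric matrices of vertices (metres, x east / y north),
# implicitly closed (last vertex connects back to the first).

#' Polygon area by the shoelace formula
#'
#' @param poly an n x 2 matrix of vertices (implicitly closed).
#' @return Area in squared input units (always non-negative).
#' @keywords internal
poly_area <- function(poly) {
  poly <- as_poly(poly)
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

as_poly <- function(poly) {
  poly <- as.matrix(poly)
  if (ncol(poly) != 2L || nrow(poly) < 3L || !is.numeric(poly)) {
    stop("polygon must be a numeric matrix with >= 3 rows and 2 columns")
  }
  # drop an explicitly repeated closing vertex
  n <- nrow(poly)
  if (all(poly[1L, ] == poly[n, ]) && n > 3L) poly <- poly[-n, , drop = FALSE]
  poly
}

#' Vectorised ray-casting point-in-polygon test
#'
#' Points exactly on an edge may fall on either side; callers needing
#' boundary-inclusive behaviour should buffer by an epsilon.
#'
#' @param px,py numeric vectors of point coordinates.
#' @param poly polygon vertex matrix.
#' @return logical vector.
#' @keywords internal
point_in_poly <- function(px, py, poly) {
  poly <- as_poly(poly)
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Clip a polygon to a convex window (Sutherland-Hodgman)
#'
#' The subject polygon may be concave; the clip polygon must be convex and is
#' re-oriented counter-clockwise internally.
#'
#' @param subject polygon to clip.
#' @param clip convex clip polygon.
#' @return Clipped vertex matrix, or NULL if the intersection is empty.
#' @keywords internal
clip_poly <- function(subject, clip) {
  subject <- as_poly(subject)
  clip <- as_poly(clip)
  if (signed_area(clip) < 0) clip <- clip[rev(seq_len(nrow(clip))), ]
  out <- subject
  nc <- nrow(clip)
  for (e in seq_len(nc)) {
    if (is.null(out) || nrow(out) < 3L) return(NULL)
    a <- clip[e, ]; b <- clip[if (e == nc) 1L else e + 1L, ]
    out <- clip_halfplane(out, a, b)
  }
  if (is.null(out) || nrow(out) < 3L) NULL else out
}

signed_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

# keep the part of `poly` left of the directed edge a -> b
clip_halfplane <- function(poly, a, b) {
  n <- nrow(poly)
  side <- (b[1] - a[1]) * (poly[, 2] - a[2]) - (b[2] - a[2]) * (poly[, 1] - a[1])
  keep_in <- side >= 0
  out <- vector("list", 2L * n)
  k <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    p <- poly[i, ]; q <- poly[j, ]
    if (keep_in[i]) {
      k <- k + 1L; out[[k]] <- p
    }
    if (xor(keep_in[i], keep_in[j])) {
      denom <- side[i] - side[j]
      t <- if (denom == 0) 0 else side[i] / denom
      k <- k + 1L; out[[k]] <- p + t * (q - p)
    }
  }
  if (k < 3L) return(NULL)
  do.call(rbind, out[seq_len(k)])
}

#' Distance from points to a polygon boundary
#'
#' Minimum Euclidean distance from each point to the polygon's edges,
#' regardless of whether the point is inside.
#'
#' @keywords internal
dist_to_poly_boundary <- function(px, py, poly) {
  poly <- as_poly(poly)
  n <- nrow(poly)
  d2 <- rep(Inf, length(px))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ax <- poly[i, 1]; ay <- poly[i, 2]
    bx <- poly[j, 1]; by <- poly[j, 2]
    vx <- bx - ax; vy <- by - ay
    len2 <- vx * vx + vy * vy
    t <- if (len2 == 0) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / len2))
    dx <- px - (ax + t * vx); dy <- py - (ay + t * vy)
    d2 <- pmin(d2, dx * dx + dy * dy)
  }
  sqrt(d2)
}

#' Axis-aligned rectangle polygon
#' @keywords internal
rect_poly <- function(xmin, ymin, xmax, ymax) {
  cbind(x = c(xmin, xmax, xmax, xmin), y = c(ymin, ymin, ymax, ymax))
}

#' Regular-polygon approximation of a disc
#' @keywords internal
disc_poly <- function(cx, cy, r, n = 256L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}

# TRUE if `poly` is an axis-aligned rectangle (4 distinct vertices)
is_axis_rect <- function(poly) {
  poly <- as_poly(poly)
  if (nrow(poly) != 4L) return(FALSE)
  xs <- sort(unique(round(poly[, 1], 9))); ys <- sort(unique(round(poly[, 2], 9)))
  length(xs) == 2L && length(ys) == 2L
}
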