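# Small planar geometry kernel used by the range and overlay computations.
# Polygons are two-column matrices of vertices (metres), implicitly closed.

#' Area of a simple polygon
#'
#' Shoelace formula; vertex order does not matter for the magnitude.
#'
#' @param poly two-column matrix of vertices (metres), not closed.
#' @return area in square metres (non-negative).
#' @keywords internal
polygon_area <- function(poly) {
  n <- nrow(poly)
  if (is.null(n) || n < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Convex hull area of a point set
#'
#' Area of the minimum convex polygon enclosing the points, in square metres.
#' Fewer than three distinct points, or a collinear set, gives area 0 with
#' attribute `degenerate = TRUE`.
#'
#' @param points two-column matrix (metres).
#' @return numeric area in m2, with attribute `degenerate`.
#' @keywords internal
convex_hull_area <- function(points) {
  pts <- unique(points)
  if (nrow(pts) < 3)
    return(structure(0, degenerate = TRUE))
  h <- grDevices::chull(pts)
  a <- polygon_area(pts[h, , drop = FALSE])
  structure(a, degenerate = (a <= 0))
}

#' Point-in-polygon test (ray casting)
#'
#' Even-odd rule with the crossing test of the standard ray-casting
#' algorithm; points exactly on an edge may land on either side and callers
#' should not rely on boundary behaviour.
#'
#' @param px,py point coordinates.
#' @param poly two-column vertex matrix, not closed.
#' @return logical vector.
#' @keywords internal
point_in_polygon <- function(px, py, poly) {
  nx <- poly[, 1]; ny <- poly[, 2]
  n <- length(nx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((ny[i] > py) != (ny[j] > py)) &
      (px < (nx[j] - nx[i]) * (py - ny[i]) / (ny[j] - ny[i]) + nx[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# orientation of the triplet (p, q, r): >0 counter-clockwise, <0 clockwise
.orient <- function(px, py, qx, qy, rx, ry) {
  (qx - px) * (ry - py) - (qy - py) * (rx - px)
}

#' Proper / improper segment intersection test
#' @keywords internal
segments_intersect <- function(p1, p2, q1, q2) {
  d1 <- .orient(q1[1], q1[2], q2[1], q2[2], p1[1], p1[2])
  d2 <- .orient(q1[1], q1[2], q2[1], q2[2], p2[1], p2[2])
  d3 <- .orient(p1[1], p1[2], p2[1], p2[2], q1[1], q1[2])
  d4 <- .orient(p1[1], p1[2], p2[1], p2[2], q2[1], q2[2])
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on_seg <- function(ax, ay, bx, by, cx, cy) { # c collinear with a-b, on it?
    min(ax, bx) - 1e-9 <= cx && cx <= max(ax, bx) + 1e-9 &&
      min(ay, by) - 1e-9 <= cy && cy <= max(ay, by) + 1e-9
  }
  (d1 == 0 && on_seg(q1[1], q1[2], q2[1], q2[2], p1[1], p1[2])) ||
    (d2 == 0 && on_seg(q1[1], q1[2], q2[1], q2[2], p2[1], p2[2])) ||
    (d3 == 0 && on_seg(p1[1], p1[2], p2[1], p2[2], q1[1], q1[2])) ||
    (d4 == 0 && on_seg(p1[1], p1[2], p2[1], p2[2], q2[1], q2[2]))
}

#' Does an axis-aligned rectangle intersect a simple polygon?
#'
#' True geometric intersection of the closed rectangle
#' `[xmin, xmax] x [ymin, ymax]` with the polygon: any polygon vertex inside
#' the rectangle, any rectangle corner inside the polygon, or any pair of
#' crossing edges.
#'
#' @param xmin,ymin,xmax,ymax rectangle bounds (metres).
#' @param poly two-column vertex matrix, not closed.
#' @return logical scalar.
#' @keywords internal
rect_intersects_polygon <- function(xmin, ymin, xmax, ymax, poly) {
  # cheap bounding-box rejection
  if (max(poly[, 1]) < xmin || min(poly[, 1]) > xmax ||
      max(poly[, 2]) < ymin || min(poly[, 2]) > ymax) return(FALSE)
  if (any(poly[, 1] >= xmin & poly[, 1] <= xmax &
          poly[, 2] >= ymin & poly[, 2] <= ymax)) return(TRUE)
  corners <- rbind(c(xmin, ymin), c(xmax, ymin), c(xmax, ymax), c(xmin, ymax))
  if (any(point_in_polygon(corners[, 1], corners[, 2], poly))) return(TRUE)
  n <- nrow(poly)
  rect_edges <- list(list(corners[1, ], corners[2, ]),
                     list(corners[2, ], corners[3, ]),
                     list(corners[3, ], corners[4, ]),
                     list(corners[4, ], corners[1, ]))
  j <- n
  for (i in seq_len(n)) {
    for (e in rect_edges) {
      if (segments_intersect(poly[j, ], poly[i, ], e[[1]], e[[2]]))
        return(TRUE)
    }
    j <- i
  }
  FALSE
}
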