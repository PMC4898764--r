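## Planar geometry for polygon rings and polylines (projected metre
## coordinates throughout). A ring is an n x 2 coordinate matrix; it may be
## open (first != last vertex) or explicitly closed.

closeRing <- function(ring) {
  ring <- as.matrix(ring)
  storage.mode(ring) <- "double"
  if (ncol(ring) != 2L) stop("ring must be a two-column coordinate matrix")
  if (nrow(ring) < 3L) stop("ring needs at least 3 vertices")
  if (!isTRUE(all.equal(ring[1L, ], ring[nrow(ring), ],
                        check.attributes = FALSE)))
    ring <- rbind(ring, ring[1L, ])
  ring
}

#' Polygon geometry from a ring
#'
#' Shoelace area, ring-length perimeter, and area-weighted centroid of a
#' simple polygon ring. Vertex order (cw/ccw) does not matter; the area is
#' returned unsigned.
#'
#' @param ring n x 2 coordinate matrix (m), open or closed.
#' @return list with `area` (m^2), `perimeter` (m), `centroid` (length-2).
#' @export
#' @examples
#' ringGeometry(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
ringGeometry <- function(ring) {
  ring <- closeRing(ring)
  # work relative to the first vertex: projected coordinates are large
  # (~1e6 m) and the raw cross products would lose ~6 digits to cancellation
  x <- ring[, 1L] - ring[1L, 1L]; y <- ring[, 2L] - ring[1L, 2L]
  n <- nrow(ring)
  cross <- x[-n] * y[-1L] - x[-1L] * y[-n]
  signedA <- sum(cross) / 2
  area <- abs(signedA)
  if (is.na(area) || area <= 0) stop("degenerate ring: zero area")
  per <- sum(sqrt(diff(x)^2 + diff(y)^2))
  cx <- sum((x[-n] + x[-1L]) * cross) / (6 * signedA)
  cy <- sum((y[-n] + y[-1L]) * cross) / (6 * signedA)
  list(area = area, perimeter = per,
       centroid = c(cx + ring[1L, 1L], cy + ring[1L, 2L]))
}

segmentsIntersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) -
    (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

#' Test a ring for self-intersection
#'
#' Checks every pair of non-adjacent edges for a proper crossing (O(n^2);
#' rings here have tens of vertices).
#'
#' @param ring n x 2 coordinate matrix.
#' @return TRUE if any two non-adjacent edges cross.
#' @export
isSelfIntersecting <- function(ring) {
  ring <- closeRing(ring)
  n <- nrow(ring) - 1L   # edges
  if (n < 4L) return(FALSE)
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      if (segmentsIntersect(ring[i, ], ring[i + 1L, ],
                            ring[j, ], ring[j + 1L, ]))
        return(TRUE)
    }
  }
  FALSE
}

pointSegmentDistance <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  len2 <- dx^2 + dy^2
  t <- ifelse(len2 > 0, ((px - ax) * dx + (py - ay) * dy) / len2, 0)
  t <- pmin(1, pmax(0, t))
  sqrt((px - (ax + t * dx))^2 + (py - (ay + t * dy))^2)
}

#' Distance from points to a polyline
#'
#' Shortest Euclidean distance from each point to any segment of a polyline;
#' used for the distance-to-flightline covariate.
#'
#' @param x,y point coordinates (m).
#' @param line k x 2 coordinate matrix of polyline vertices.
#' @return numeric vector of distances (m).
#' @export
distanceToPolyline <- function(x, y, line) {
  line <- as.matrix(line)
  if (ncol(line) != 2L || nrow(line) < 2L)
    stop("line must be a >= 2-row, two-column coordinate matrix")
  d <- rep(Inf, length(x))
  for (i in seq_len(nrow(line) - 1L)) {
    d <- pmin(d, pointSegmentDistance(x, y, line[i, 1], line[i, 2],
                                      line[i + 1L, 1], line[i + 1L, 2]))
  }
  d
}

looksGeographic <- function(x, y) {
  all(abs(x) <= 360) && all(abs(y) <= 90)
}
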