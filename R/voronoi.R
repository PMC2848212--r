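# Voronoi tessellation of centroids inside a bounding rectangle, by
# half-plane clipping: each cell starts as the rectangle and is cut by the
# perpendicular bisector against every other site. O(n^2 * vertices), ample
# for the few hundred municipalities these analyses involve.

#' Voronoi polygons of area centroids within a rectangle
#'
#' Computes the Voronoi cell of every centroid clipped to the bounding
#' rectangle `[0, extent[1]] x [0, extent[2]]`. Used to give synthetic
#' municipalities a surface area and a polygon to shade on choropleth maps
#' when no real administrative boundaries are available.
#'
#' @param centroids Two-column matrix/data frame of (x, y) in km.
#' @param extent Numeric length-2: rectangle side lengths (km). Defaults to
#'   the bounding box of the centroids.
#' @return List with `polygons` (list of closed two-column coordinate
#'   matrices, one per centroid) and `areas` (numeric vector of cell surface
#'   areas in km^2).
#' @export
voronoi_polygons <- function(centroids, extent = NULL) {
  xy <- as.matrix(centroids)
  n <- nrow(xy)
  if (is.null(extent)) {
    extent <- c(max(xy[, 1]), max(xy[, 2]))
  }
  rect <- cbind(c(0, extent[1], extent[1], 0), c(0, 0, extent[2], extent[2]))
  polys <- vector("list", n)
  for (i in seq_len(n)) {
    cell <- rect
    p <- xy[i, ]
    for (j in seq_len(n)) {
      if (j == i || nrow(cell) == 0L) next
      q <- xy[j, ]
      # half-plane of points nearer p than q: a . x <= b
      a <- q - p
      b <- sum((q + p) * a) / 2
      cell <- clip_halfplane(cell, a, b)
    }
    polys[[i]] <- cell
  }
  list(polygons = polys, areas = vapply(polys, polygon_area, numeric(1)))
}

# Sutherland-Hodgman clip of a convex polygon against {x : a . x <= b}.
clip_halfplane <- function(poly, a, b) {
  m <- nrow(poly)
  if (m == 0L) return(poly)
  s <- as.vector(poly %*% a) - b
  out <- matrix(numeric(0), 0, 2)
  for (k in seq_len(m)) {
    k2 <- if (k == m) 1L else k + 1L
    in1 <- s[k] <= 1e-12
    in2 <- s[k2] <= 1e-12
    if (in1) out <- rbind(out, poly[k, ])
    if (xor(in1, in2)) {
      t <- s[k] / (s[k] - s[k2])
      out <- rbind(out, poly[k, ] + t * (poly[k2, ] - poly[k, ]))
    }
  }
  out
}

polygon_area <- function(poly) {
  m <- nrow(poly)
  if (m < 3L) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}
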