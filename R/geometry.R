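#' Planar geometry primitives
#'
#' Minimal vector-geometry support for the risk-surface and home-range
#' stages: points, polylines and polygons in projected meters, with
#' point-to-geometry distance and point-in-polygon tests. Geometries are
#' coordinate matrices (columns x, y); polygons are implicitly closed.
#'
#' @param type one of "point", "polyline", "polygon".
#' @param coords two-column numeric matrix of vertices (x, y).
#' @return an object of class `geometry`.
#' @export
geometry <- function(type = c("point", "polyline", "polygon"), coords) {
  type <- match.arg(type)
  coords <- matrix(as.numeric(coords), ncol = 2L,
                   dimnames = list(NULL, c("x", "y")))
  if (nrow(coords) == 0L) stop("empty geometry")
  if (type == "polyline" && nrow(coords) < 2L)
    stop("a polyline needs at least 2 vertices")
  if (type == "polygon" && nrow(coords) < 3L)
    stop("a polygon needs at least 3 vertices")
  structure(list(type = type, coords = coords), class = "geometry")
}

# distance from each point (px, py) to segment (x1,y1)-(x2,y2)
dist_point_segment <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return(sqrt((px - x1)^2 + (py - y1)^2))
  t <- ((px - x1) * dx + (py - y1) * dy) / len2
  t <- pmin(pmax(t, 0), 1)
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

# minimum distance from points to a chain of segments (closed if close = TRUE)
dist_to_chain <- function(px, py, coords, close = FALSE) {
  n <- nrow(coords)
  if (n == 1L) return(sqrt((px - coords[1, 1])^2 + (py - coords[1, 2])^2))
  idx2 <- if (close) c(seq_len(n)[-1L], 1L) else seq_len(n)[-1L]
  idx1 <- if (close) seq_len(n) else seq_len(n - 1L)
  d <- rep(Inf, length(px))
  for (k in seq_along(idx1)) {
    d <- pmin(d, dist_point_segment(px, py,
                                    coords[idx1[k], 1], coords[idx1[k], 2],
                                    coords[idx2[k], 1], coords[idx2[k], 2]))
  }
  d
}

#' Point-in-polygon test (even-odd ray casting)
#'
#' Boundary points count as inside.
#'
#' @param px,py point coordinates, vectorized.
#' @param coords polygon vertex matrix (implicitly closed).
#' @return logical vector.
#' @export
point_in_polygon <- function(px, py, coords) {
  n <- nrow(coords)
  xs <- coords[, 1]; ys <- coords[, 2]
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- xs[i]; yi <- ys[i]; xj <- xs[j]; yj <- ys[j]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  on_edge <- dist_to_chain(px, py, coords, close = TRUE) < 1e-9
  inside | on_edge
}

#' Distance from points to a geometry
#'
#' Euclidean distance to the nearest point of the geometry; zero inside
#' polygons.
#'
#' @param px,py point coordinates, vectorized.
#' @param geom a [geometry()].
#' @return numeric vector of distances (m).
#' @export
dist_to_geometry <- function(px, py, geom) {
  co <- geom$coords
  switch(geom$type,
    point = {
      d <- rep(Inf, length(px))
      for (k in seq_len(nrow(co)))
        d <- pmin(d, sqrt((px - co[k, 1])^2 + (py - co[k, 2])^2))
      d
    },
    polyline = dist_to_chain(px, py, co),
    polygon = {
      d <- dist_to_chain(px, py, co, close = TRUE)
      d[point_in_polygon(px, py, co)] <- 0
      d
    }
  )
}
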