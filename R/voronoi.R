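# Bounded Voronoi tessellation by half-plane clipping.
#
# Each cell starts as the bounding square and is clipped against the
# perpendicular bisector of its seed and every other seed
# (Sutherland-Hodgman).  O(n^2) but exact and dependency-free; intended for
# the few-hundred-tract geographies this package simulates.

# Clip a convex polygon (matrix of vertices, open ring) against the
# half-plane {p : a . p <= b}.
clip_halfplane <- function(poly, a, b) {
  n <- nrow(poly)
  if (n == 0) return(poly)
  val <- poly %*% a - b
  keep <- val <= 1e-12
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    p1 <- poly[i, ]; p2 <- poly[j, ]
    in1 <- keep[i]; in2 <- keep[j]
    if (in1) out <- rbind(out, p1)
    if (xor(in1, in2)) {
      t <- val[i] / (val[i] - val[j])
      out <- rbind(out, p1 + t * (p2 - p1))
    }
  }
  out
}

# Voronoi cells of `points` (n x 2) clipped to [0, extent]^2.
# Returns a list of vertex matrices (open rings, counter-clockwise).
voronoi_cells <- function(points, extent) {
  square <- rbind(
    c(0, 0), c(extent, 0), c(extent, extent), c(0, extent)
  )
  n <- nrow(points)
  lapply(seq_len(n), function(i) {
    cell <- square
    for (j in seq_len(n)) {
      if (j == i) next
      # keep the side of the bisector nearer to point i
      a <- points[j, ] - points[i, ]
      m <- (points[i, ] + points[j, ]) / 2
      cell <- clip_halfplane(cell, a, sum(a * m))
      if (nrow(cell) == 0) break
    }
    cell
  })
}

polygon_area <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(0)
  j <- c(2:n, 1L)
  abs(sum(poly[, 1] * poly[j, 2] - poly[j, 1] * poly[, 2])) / 2
}

# Ray-casting point-in-polygon; boundary points count as inside.
point_in_polygon <- function(pt, poly) {
  n <- nrow(poly)
  x <- pt[1]; y <- pt[2]
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    # on-edge check
    d <- abs((xj - xi) * (y - yi) - (yj - yi) * (x - xi))
    seg_len2 <- (xj - xi)^2 + (yj - yi)^2
    if (seg_len2 > 0 && d <= 1e-9 * sqrt(seg_len2)) {
      tt <- ((x - xi) * (xj - xi) + (y - yi) * (yj - yi)) / seg_len2
      if (tt >= -1e-12 && tt <= 1 + 1e-12) return(TRUE)
    }
    if ((yi > y) != (yj > y)) {
      xcross <- xi + (y - yi) / (yj - yi) * (xj - xi)
      if (x < xcross) inside <- !inside
    }
    j <- i
  }
  inside
}
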