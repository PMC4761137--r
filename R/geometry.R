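# Planar polygon primitives. Polygons are two-column (x, y) matrices holding
# one open ring (first vertex not repeated), vertices in counter-clockwise
# order, coordinates in metres.

poly_close <- function(p) rbind(p, p[1, , drop = FALSE])

#' Polygon area (shoelace formula)
#' @param p Two-column vertex matrix (open ring).
#' @return Area in square metres (positive for counter-clockwise rings).
#' @export
poly_area <- function(p) {
  n <- nrow(p)
  if (n < 3) return(0)
  x <- p[, 1]; y <- p[, 2]
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

poly_signed_area <- function(p) {
  n <- nrow(p)
  x <- p[, 1]; y <- p[, 2]
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

poly_centroid <- function(p) {
  n <- nrow(p)
  x <- p[, 1]; y <- p[, 2]
  j <- c(n, seq_len(n - 1))
  cr <- x[j] * y - x * y[j]
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(p))
  c(sum((x[j] + x) * cr) / (6 * a), sum((y[j] + y) * cr) / (6 * a))
}

poly_bbox <- function(p) c(min(p[, 1]), min(p[, 2]), max(p[, 1]), max(p[, 2]))

# ensure counter-clockwise orientation
poly_ccw <- function(p) if (poly_signed_area(p) < 0) p[rev(seq_len(nrow(p))), , drop = FALSE] else p

#' Points in polygon
#'
#' Wrapper around \code{mgcv::in.out}; handles general simple polygons.
#' @param poly Two-column vertex matrix (open ring).
#' @param pts Two-column point matrix.
#' @return Logical vector.
#' @export
point_in_poly <- function(poly, pts) {
  if (!is.matrix(pts)) pts <- matrix(pts, ncol = 2)
  if (nrow(pts) == 0) return(logical(0))
  mgcv::in.out(poly_close(unname(poly)), unname(pts))
}

# Clip a convex polygon by the half-plane { z : (z - m) . nrm <= 0 }.
# Sutherland-Hodgman step; returns a matrix with 0 rows if nothing remains.
clip_halfplane <- function(p, m, nrm) {
  n <- nrow(p)
  d <- (p[, 1] - m[1]) * nrm[1] + (p[, 2] - m[2]) * nrm[2]
  if (all(d <= 0)) return(p)
  if (all(d >= 0)) return(p[0, , drop = FALSE])
  out <- matrix(NA_real_, n + 4, 2)
  k <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    di <- d[i]; dj <- d[j]
    if (di <= 0) { k <- k + 1L; out[k, ] <- p[i, ] }
    if ((di < 0 && dj > 0) || (di > 0 && dj < 0)) {
      t <- di / (di - dj)
      k <- k + 1L
      out[k, ] <- p[i, ] + t * (p[j, ] - p[i, ])
    }
  }
  out[seq_len(k), , drop = FALSE]
}

# Voronoi cell of seed i within a convex boundary polygon, considering the
# given competitor seeds. Exact for convex boundaries.
voronoi_cell <- function(seed, others, boundary) {
  cell <- boundary
  if (is.null(others) || nrow(others) == 0) return(cell)
  d2 <- (others[, 1] - seed[1])^2 + (others[, 2] - seed[2])^2
  ord <- order(d2)
  for (k in ord) {
    if (nrow(cell) == 0) break
    # prune: competitor cannot cut the cell if its bisector is farther than
    # every current vertex
    rmax2 <- max((cell[, 1] - seed[1])^2 + (cell[, 2] - seed[2])^2)
    if (d2[k] > 4 * rmax2) break
    m <- (seed + others[k, ]) / 2
    nrm <- others[k, ] - seed
    cell <- clip_halfplane(cell, m, nrm)
  }
  cell
}

# Voronoi tessellation of seed points within a convex boundary polygon.
# Returns a list of polygons (one per seed, possibly empty).
voronoi_tessellation <- function(seeds, boundary) {
  n <- nrow(seeds)
  lapply(seq_len(n), function(i) {
    voronoi_cell(seeds[i, ], seeds[-i, , drop = FALSE], boundary)
  })
}

rect_poly <- function(x0, y0, x1, y1) {
  cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
}

# Minimum distance between two polygon boundaries (vertex-to-edge, both ways).
# Zero if they share a point; adequate for non-crossing tessellation members.
poly_boundary_dist <- function(a, b) {
  min(points_to_segments_dist(a, b), points_to_segments_dist(b, a))
}

points_to_segments_dist <- function(pts, poly) {
  n <- nrow(poly)
  j <- c(seq_len(n)[-1], 1L)
  ax <- poly[, 1]; ay <- poly[, 2]
  bx <- poly[j, 1]; by <- poly[j, 2]
  dx <- bx - ax; dy <- by - ay
  len2 <- pmax(dx^2 + dy^2, 1e-300)
  dmin <- Inf
  for (i in seq_len(nrow(pts))) {
    t <- pmin(1, pmax(0, ((pts[i, 1] - ax) * dx + (pts[i, 2] - ay) * dy) / len2))
    qx <- ax + t * dx; qy <- ay + t * dy
    dmin <- min(dmin, min((pts[i, 1] - qx)^2 + (pts[i, 2] - qy)^2))
  }
  sqrt(dmin)
}

# simple-polygon check: no two non-adjacent edges intersect
poly_is_simple <- function(p, tol = 1e-9) {
  n <- nrow(p)
  if (n < 3) return(FALSE)
  pc <- poly_close(p)
  seg_int <- function(p1, p2, p3, p4) {
    d1 <- cross2(p4 - p3, p1 - p3); d2 <- cross2(p4 - p3, p2 - p3)
    d3 <- cross2(p2 - p1, p3 - p1); d4 <- cross2(p2 - p1, p4 - p1)
    (d1 * d2 < -tol) && (d3 * d4 < -tol)
  }
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next
      if (seg_int(pc[i, ], pc[i + 1, ], pc[j, ], pc[j + 1, ])) return(FALSE)
    }
  }
  TRUE
}

cross2 <- function(u, v) u[1] * v[2] - u[2] * v[1]

# uniform random points inside a convex polygon (fan triangulation)
runif_in_poly <- function(n, poly) {
  m <- nrow(poly)
  if (m < 3 || n == 0) return(matrix(numeric(0), 0, 2))
  tri <- lapply(2:(m - 1), function(i) poly[c(1, i, i + 1), , drop = FALSE])
  areas <- vapply(tri, poly_area, 0)
  pick <- sample.int(length(tri), n, replace = TRUE, prob = pmax(areas, 1e-300))
  u1 <- runif(n); u2 <- runif(n)
  sw <- u1 + u2 > 1
  u1[sw] <- 1 - u1[sw]; u2[sw] <- 1 - u2[sw]
  out <- matrix(0, n, 2)
  for (k in seq_len(n)) {
    tk <- tri[[pick[k]]]
    out[k, ] <- tk[1, ] + u1[k] * (tk[2, ] - tk[1, ]) + u2[k] * (tk[3, ] - tk[1, ])
  }
  out
}
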