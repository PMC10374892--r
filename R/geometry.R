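# Plane geometry primitives shared by rasterization, layout compilation and
# metrology. All coordinates are in micrometres. Polygons are n x 2 matrices
# of vertices, implicitly closed (first vertex is not repeated).

#' Signed area of a polygon (shoelace formula)
#'
#' Positive for counter-clockwise vertex order.
#'
#' @param v n x 2 matrix of vertices in um.
#' @return Signed area in um^2.
#' @keywords internal
polygon_signed_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Polygon area (absolute)
#' @param v n x 2 vertex matrix.
#' @return Area in um^2.
#' @export
polygon_area <- function(v) abs(polygon_signed_area(v))

#' Polygon centroid
#' @param v n x 2 vertex matrix.
#' @return Length-2 numeric, centroid in um.
#' @export
polygon_centroid <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(v))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

#' Force counter-clockwise vertex order
#' @param v n x 2 vertex matrix.
#' @return Vertex matrix with positive signed area.
#' @keywords internal
ensure_ccw <- function(v) {
  if (polygon_signed_area(v) < 0) v[rev(seq_len(nrow(v))), , drop = FALSE] else v
}

#' Point-in-polygon test
#'
#' Thin wrapper around [mgcv::in.out()] so every module shares one predicate.
#'
#' @param pts m x 2 matrix of query points.
#' @param v n x 2 polygon vertex matrix.
#' @return Logical vector of length m.
#' @keywords internal
points_in_polygon <- function(pts, v) {
  bnd <- rbind(v, v[1, ])
  mgcv::in.out(bnd, as.matrix(pts))
}

#' Clip a polygon to an axis-aligned rectangle (Sutherland-Hodgman)
#'
#' Exact for convex clip windows; the subject polygon may be concave. Used by
#' the layout tiler, where tiles partition the plane so clipped pieces sum to
#' the original area.
#'
#' @param v n x 2 subject polygon.
#' @param xlim,ylim Rectangle extents, length-2 numeric each.
#' @return Clipped vertex matrix, or NULL when the intersection is empty.
#' @keywords internal
clip_polygon_rect <- function(v, xlim, ylim) {
  clip_half <- function(poly, inside, intersect) {
    if (is.null(poly) || nrow(poly) == 0) return(NULL)
    n <- nrow(poly)
    out <- vector("list", 2L * n)
    k <- 0L
    for (i in seq_len(n)) {
      cur <- poly[i, ]
      prv <- poly[if (i == 1L) n else i - 1L, ]
      ci <- inside(cur); pi <- inside(prv)
      if (ci) {
        if (!pi) { k <- k + 1L; out[[k]] <- intersect(prv, cur) }
        k <- k + 1L; out[[k]] <- cur
      } else if (pi) {
        k <- k + 1L; out[[k]] <- intersect(prv, cur)
      }
    }
    if (k == 0L) return(NULL)
    do.call(rbind, out[seq_len(k)])
  }
  ix <- function(p, q, val, axis) {
    t <- (val - p[axis]) / (q[axis] - p[axis])
    p + t * (q - p)
  }
  v <- clip_half(v, function(p) p[1] >= xlim[1], function(p, q) ix(p, q, xlim[1], 1))
  v <- clip_half(v, function(p) p[1] <= xlim[2], function(p, q) ix(p, q, xlim[2], 1))
  v <- clip_half(v, function(p) p[2] >= ylim[1], function(p, q) ix(p, q, ylim[1], 2))
  v <- clip_half(v, function(p) p[2] <= ylim[2], function(p, q) ix(p, q, ylim[2], 2))
  if (is.null(v) || nrow(v) < 3L || polygon_area(v) < 1e-9) return(NULL)
  v
}

# Proper-crossing test between segments p1-p2 and p3-p4 (shared endpoints do
# not count). Used by the simplicity check after corner remapping.
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

#' Test whether a polygon is simple (non-self-intersecting)
#' @param v n x 2 vertex matrix.
#' @return TRUE when no two non-adjacent edges properly cross.
#' @keywords internal
polygon_is_simple <- function(v) {
  n <- nrow(v)
  if (n < 3L) return(FALSE)
  nxt <- c(seq_len(n)[-1], 1L)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      # skip adjacent edges (share a vertex)
      if (j == i || nxt[i] == j || nxt[j] == i) next
      if (segments_cross(v[i, ], v[nxt[i], ], v[j, ], v[nxt[j], ])) return(FALSE)
    }
  }
  TRUE
}

#' Distance from points to a polygon boundary
#'
#' Unsigned Euclidean distance from each query point to the nearest point on
#' any polygon edge.
#'
#' @param pts m x 2 matrix of query points.
#' @param v n x 2 polygon vertex matrix.
#' @return Numeric vector of length m (um).
#' @keywords internal
dist_to_polygon_edge <- function(pts, v) {
  pts <- as.matrix(pts)
  n <- nrow(v)
  dmin <- rep(Inf, nrow(pts))
  for (i in seq_len(n)) {
    a <- v[i, ]; b <- v[if (i == n) 1L else i + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 < 1e-18) next
    t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
    t <- pmin(1, pmax(0, t))
    dx <- pts[, 1] - (a[1] + t * ab[1])
    dy <- pts[, 2] - (a[2] + t * ab[2])
    dmin <- pmin(dmin, sqrt(dx * dx + dy * dy))
  }
  dmin
}

#' Intersect a ray with a polygon
#'
#' Ray starts at `origin` in direction `dir`; returns all positive ray
#' parameters where the ray crosses a polygon edge, sorted ascending.
#'
#' @param origin,dir Length-2 numerics.
#' @param v n x 2 polygon vertex matrix.
#' @return Numeric vector of distances along the ray (possibly empty).
#' @keywords internal
ray_polygon_hits <- function(origin, dir, v) {
  n <- nrow(v)
  hits <- numeric(0)
  for (i in seq_len(n)) {
    a <- v[i, ]; b <- v[if (i == n) 1L else i + 1L, ]
    e <- b - a
    den <- dir[1] * (-e[2]) - dir[2] * (-e[1])
    if (abs(den) < 1e-12) next
    rhs <- a - origin
    t <- (rhs[1] * (-e[2]) - rhs[2] * (-e[1])) / den
    u <- (dir[1] * rhs[2] - dir[2] * rhs[1]) / den
    if (t > 1e-9 && u >= -1e-9 && u <= 1 + 1e-9) hits <- c(hits, t)
  }
  sort(hits)
}

# --- exact Euclidean distance transform (Felzenszwalb & Huttenlocher) -------

# 1-D squared distance transform of sampled function f.
dt1d <- function(f) {
  n <- length(f)
  d <- numeric(n)
  vidx <- integer(n)
  z <- numeric(n + 1L)
  k <- 1L
  vidx[1L] <- 1L
  z[1L] <- -Inf; z[2L] <- Inf
  for (q in 2:n) {
    repeat {
      vk <- vidx[k]
      s <- ((f[q] + q * q) - (f[vk] + vk * vk)) / (2 * q - 2 * vk)
      if (s <= z[k]) { k <- k - 1L } else break
    }
    k <- k + 1L
    vidx[k] <- q
    z[k] <- s
    z[k + 1L] <- Inf
  }
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1L] < q) k <- k + 1L
    vk <- vidx[k]
    d[q] <- (q - vk)^2 + f[vk]
  }
  d
}

#' Exact Euclidean distance transform of a binary matrix
#'
#' Distance from every cell centre to the nearest TRUE cell centre, in
#' physical units. Cells that are TRUE get distance 0. An all-FALSE input
#' returns Inf everywhere.
#'
#' @param mask Logical matrix.
#' @param spacing Cell pitch (um per cell).
#' @return Numeric matrix of distances (um).
#' @export
distance_transform <- function(mask, spacing = 1) {
  stopifnot(is.matrix(mask))
  if (!any(mask)) return(matrix(Inf, nrow(mask), ncol(mask)))
  big <- 1e18  # finite stand-in for +Inf so parabola intersections stay defined
  f <- ifelse(mask, 0, big)
  for (j in seq_len(ncol(f))) f[, j] <- dt1d(f[, j])
  for (i in seq_len(nrow(f))) f[i, ] <- dt1d(f[i, ])
  d <- sqrt(f) * spacing
  d[d > sqrt(big) / 2 * spacing] <- Inf
  d
}

#' Binary dilation by a Euclidean disc
#'
#' @param mask Logical matrix.
#' @param radius Dilation radius in the same units as `spacing`.
#' @param spacing Cell pitch.
#' @return Logical matrix.
#' @keywords internal
dilate_mask <- function(mask, radius, spacing = 1) {
  if (radius <= 0) return(mask)
  distance_transform(mask, spacing) <= radius + 1e-9
}
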