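# Planar cross-sections of triangle meshes and 2D polygon utilities.
# Sections support the canal centerline (area centroids) and the
# inscribed-diameter profile (maximum inscribed circles).

# signed area (shoelace); vertices are rows of a k x 2 matrix, implicit closure
poly_area_signed <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

poly_centroid2d <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(p))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# even-odd rule point-in-polygon, vectorized over query points
points_in_polygon <- function(pts, poly) {
  n <- nrow(poly)
  x <- pts[, 1]; y <- pts[, 2]
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# minimum distance from each query point to the polygon boundary
dist_to_boundary <- function(pts, poly) {
  n <- nrow(poly)
  best <- rep(Inf, nrow(pts))
  nxt <- c(seq_len(n)[-1], 1L)
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[nxt[i], ]
    ab <- b - a
    l2 <- sum(ab^2)
    if (l2 < 1e-24) next
    t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / l2
    t <- pmin(1, pmax(0, t))
    dx <- pts[, 1] - (a[1] + t * ab[1])
    dy <- pts[, 2] - (a[2] + t * ab[2])
    best <- pmin(best, dx * dx + dy * dy)
  }
  sqrt(best)
}

#' Maximum inscribed circle of a planar polygon
#'
#' Finds the largest circle centered anywhere inside the polygon, by
#' maximizing distance-to-boundary over a point grid refined around the
#' running optimum until the grid pitch is below `tol` (default 0.005 mm,
#' giving the inscribed diameter to about 0.01 mm).
#'
#' @param poly k x 2 matrix of polygon vertices (mm, implicit closure).
#' @param tol grid refinement pitch at convergence (mm).
#' @return List with `center` (length-2) and `radius` (mm).
#' @export
max_inscribed_circle <- function(poly, tol = 0.005) {
  if (abs(poly_area_signed(poly)) < 1e-6) {
    fc_abort("degenerate polygon (area < 1e-6 mm^2)", "femcurve_section_error")
  }
  rng_x <- range(poly[, 1]); rng_y <- range(poly[, 2])
  nx <- 41L
  gx <- seq(rng_x[1], rng_x[2], length.out = nx)
  gy <- seq(rng_y[1], rng_y[2], length.out = nx)
  pts <- cbind(rep(gx, times = nx), rep(gy, each = nx))
  keep <- points_in_polygon(pts, poly)
  if (!any(keep)) {
    # extremely thin polygon: fall back to the centroid
    pts <- matrix(poly_centroid2d(poly), 1, 2)
  } else {
    pts <- pts[keep, , drop = FALSE]
  }
  d <- dist_to_boundary(pts, poly)
  best <- pts[which.max(d), ]
  h <- max(diff(rng_x), diff(rng_y)) / (nx - 1)
  while (h > tol) {
    h <- h / 4
    gx <- seq(best[1] - 4 * h, best[1] + 4 * h, by = h)
    gy <- seq(best[2] - 4 * h, best[2] + 4 * h, by = h)
    pts <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
    keep <- points_in_polygon(pts, poly)
    pts <- rbind(matrix(best, 1, 2), pts[keep, , drop = FALSE])
    d <- dist_to_boundary(pts, poly)
    best <- pts[which.max(d), ]
  }
  list(center = as.numeric(best),
       radius = max(dist_to_boundary(matrix(best, 1, 2), poly)))
}

# Unique-edge structure of a mesh: unique undirected edges (ulo, uhi) and
# the edge id of each face corner. Computed once per mesh and reused across
# many slicing planes.
mesh_edge_info <- function(mesh) {
  f <- mesh$faces
  ea <- c(f[, 1], f[, 2], f[, 3])
  eb <- c(f[, 2], f[, 3], f[, 1])
  lo <- pmin(ea, eb); hi <- pmax(ea, eb)
  code <- (lo - 1) * as.numeric(nrow(mesh$vertices)) + hi
  first <- !duplicated(code)
  list(ulo = lo[first], uhi = hi[first],
       eid = match(code, code[first]), m = nrow(f))
}

# All closed intersection loops of a mesh with the plane through `point`
# with unit `normal`. Intersections are computed once per mesh edge so the
# chained loops are exact. Returns a list of loops, each with points3d,
# points2d (in-plane coordinates), area, centroid3d.
slice_mesh <- function(mesh, point, normal, edges = NULL) {
  n <- unitize(normal)
  v <- mesh$vertices
  f <- mesh$faces
  d <- as.numeric(v %*% n) - sum(point * n)
  scale <- max(abs(d), 1)
  d[abs(d) < 1e-12 * scale] <- 1e-12 * scale  # nudge vertices off the plane
  sgn <- d > 0

  if (is.null(edges)) edges <- mesh_edge_info(mesh)
  ulo <- edges$ulo; uhi <- edges$uhi; eid <- edges$eid
  crossing <- sgn[ulo] != sgn[uhi]
  if (!any(crossing)) return(list())
  t <- d[ulo] / (d[ulo] - d[uhi])
  ipt <- v[ulo, , drop = FALSE] +
    (v[uhi, , drop = FALSE] - v[ulo, , drop = FALSE]) * t
  # per-face crossing edge pairs -> segments between edge ids
  m <- nrow(f)
  e1 <- eid[seq_len(m)]; e2 <- eid[m + seq_len(m)]; e3 <- eid[2 * m + seq_len(m)]
  c1 <- crossing[e1]; c2 <- crossing[e2]; c3 <- crossing[e3]
  nc <- c1 + c2 + c3
  segs <- cbind(
    ifelse(c1, e1, ifelse(c2, e2, NA_integer_)),
    ifelse(c3, e3, ifelse(c2, e2, NA_integer_))
  )[nc == 2L, , drop = FALSE]
  if (nrow(segs) == 0) return(list())

  # chain segments into loops via shared edge ids
  used <- rep(FALSE, nrow(segs))
  adj <- split(rep(seq_len(nrow(segs)), 2L), c(segs[, 1], segs[, 2]))
  e1b <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1b <- unitize(e1b - sum(e1b * n) * n)
  e2b <- c(n[2] * e1b[3] - n[3] * e1b[2],
           n[3] * e1b[1] - n[1] * e1b[3],
           n[1] * e1b[2] - n[2] * e1b[1])
  loops <- list()
  for (s0 in seq_len(nrow(segs))) {
    if (used[s0]) next
    used[s0] <- TRUE
    start <- segs[s0, 1]
    cur <- segs[s0, 2]
    chain <- c(start, cur)
    repeat {
      cand <- adj[[as.character(cur)]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0) break
      s <- cand[1]
      used[s] <- TRUE
      cur <- if (segs[s, 1] == cur) segs[s, 2] else segs[s, 1]
      if (cur == start) break
      chain <- c(chain, cur)
    }
    if (length(chain) < 3 || cur != start) next  # open chain: discard
    p3 <- ipt[chain, , drop = FALSE]
    rel <- sweep(p3, 2L, point, "-")
    p2 <- cbind(as.numeric(rel %*% e1b), as.numeric(rel %*% e2b))
    a <- abs(poly_area_signed(p2))
    if (a < 1e-12) next
    c2d <- poly_centroid2d(p2)
    c3d <- point + c2d[1] * e1b + c2d[2] * e2b
    loops[[length(loops) + 1L]] <- list(
      points3d = p3, points2d = p2, area = a,
      centroid3d = as.numeric(c3d), centroid2d = c2d,
      basis = rbind(e1b, e2b), normal = n, origin = point
    )
  }
  loops
}

#' Cross-section of the canal at a point
#'
#' Intersects the mesh with the plane through `point` normal to `tangent`
#' and returns the closed cross-section loop whose area centroid is nearest
#' to `point` (canals can intersect a plane in several loops near the ends).
#'
#' @param mesh a watertight [fem_mesh].
#' @param point length-3 point on the cutting plane (mm).
#' @param tangent length-3 plane normal (the local canal direction).
#' @param edges optional precomputed edge structure (internal cache used
#'   when many sections of the same mesh are cut).
#' @return A section object: list with `points3d`, `points2d`, `area`,
#'   `centroid3d`, `centroid2d`, `basis`, `normal`, `origin`.
#' @export
section_at <- function(mesh, point, tangent, edges = NULL) {
  loops <- slice_mesh(mesh, point, tangent, edges = edges)
  if (length(loops) == 0) {
    fc_abort("cutting plane does not intersect the mesh",
             "femcurve_section_error")
  }
  d2 <- vapply(loops, function(l) sum((l$centroid3d - point)^2), numeric(1))
  loops[[which.min(d2)]]
}
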