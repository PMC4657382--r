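# Shared fixtures built in code. Expensive objects (meshes, measured
# records) are memoized so several test files can reuse them.

.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

default_femur <- function() {
  memo("default_femur", make_femur_meshes(femur_params()))
}

default_record <- function() {
  memo("default_record", {
    fem <- default_femur()
    measure_femur(fem$cortex, fem$canal, side = "left")
  })
}

# axis-aligned capped cylinder along +z, base at z = 0
cylinder_mesh <- function(radius = 5, length = 100, n_c = 48L, n_a = 30L) {
  rings <- lapply(seq(0, length, length.out = n_a), function(z) {
    femcurve:::ring_vertices(c(0, 0, z), radius, c(1, 0, 0), c(0, 1, 0), n_c)
  })
  femcurve:::capped_tube_mesh(rings, c(0, 0, 0), c(0, 0, length))
}

# elliptical tube along +z with semi-axes a (x) and b (y)
elliptical_tube_mesh <- function(a = 6, b = 4, length = 60, n_c = 64L, n_a = 20L) {
  phi <- 0.31 + 2 * pi * (seq_len(n_c) - 1L) / n_c
  rings <- lapply(seq(0, length, length.out = n_a), function(z) {
    cbind(a * cos(phi), b * sin(phi), z)
  })
  femcurve:::capped_tube_mesh(rings, c(0, 0, 0), c(0, 0, length))
}

box_mesh <- function(lx = 40, ly = 20, lz = 60) {
  v <- as.matrix(expand.grid(x = c(0, lx), y = c(0, ly), z = c(0, lz)))
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),  # z = 0
    c(5, 6, 7), c(6, 8, 7),  # z = lz
    c(1, 2, 5), c(2, 6, 5),  # y = 0
    c(3, 7, 4), c(4, 7, 8),  # y = ly
    c(1, 5, 3), c(3, 5, 7),  # x = 0
    c(2, 4, 6), c(4, 8, 6)   # x = lx
  )
  femcurve:::orient_outward(fem_mesh(v, f))
}

# geodesic sphere from subdivided octahedron
sphere_mesh <- function(radius = 10, center = c(0, 0, 0), levels = 3L) {
  v <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
             c(0, 0, 1), c(0, 0, -1))
  f <- rbind(c(1, 3, 5), c(3, 2, 5), c(2, 4, 5), c(4, 1, 5),
             c(3, 1, 6), c(2, 3, 6), c(4, 2, 6), c(1, 4, 6))
  for (l in seq_len(levels)) {
    nf <- nrow(f)
    newf <- matrix(0L, 4 * nf, 3)
    midkey <- list()
    get_mid <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      if (!is.null(midkey[[key]])) return(midkey[[key]])
      m <- (v[i, ] + v[j, ]) / sqrt(sum((v[i, ] + v[j, ])^2))
      v <<- rbind(v, m)
      midkey[[key]] <<- nrow(v)
      nrow(v)
    }
    for (k in seq_len(nf)) {
      a <- f[k, 1]; b <- f[k, 2]; c_ <- f[k, 3]
      ab <- get_mid(a, b); bc <- get_mid(b, c_); ca <- get_mid(c_, a)
      newf[4 * k - 3, ] <- c(a, ab, ca)
      newf[4 * k - 2, ] <- c(ab, b, bc)
      newf[4 * k - 1, ] <- c(ca, bc, c_)
      newf[4 * k, ] <- c(ab, bc, ca)
    }
    f <- newf
  }
  fem_mesh(sweep(v * radius, 2L, center, "+"), f)
}

# independent circumcenter of 3 points in 3D (perpendicular-bisector
# construction; oracle for circle radii)
circumradius_3d <- function(p) {
  a <- p[1, ]; b <- p[2, ]; c_ <- p[3, ]
  ab <- b - a; ac <- c_ - a
  cr <- c(ab[2] * ac[3] - ab[3] * ac[2],
          ab[3] * ac[1] - ab[1] * ac[3],
          ab[1] * ac[2] - ab[2] * ac[1])
  d2 <- 2 * sum(cr^2)
  u <- sum(ac^2) * (sum(ab^2) * ac - sum(ab * ac) * ab)
  w <- sum(ab^2) * (sum(ac^2) * ab - sum(ab * ac) * ac)
  ctr <- a + (u + w) / d2
  sqrt(sum((a - ctr)^2))
}

# brute-force geometric circle fit: multi-start Nelder-Mead/BFGS over the
# in-plane parameters, independent of the package's solver
brute_circle_radius <- function(p2, n_starts = 100L, seed = 1L) {
  set.seed(seed)
  obj <- function(q) {
    di <- sqrt((p2[, 1] - q[1])^2 + (p2[, 2] - q[2])^2)
    sum((di - q[3])^2)
  }
  ctr <- colMeans(p2)
  sc <- max(dist(p2))
  best <- NULL
  for (s in seq_len(n_starts)) {
    st <- c(ctr + runif(2, -2, 2) * sc, runif(1, 0.5, 40) * sc)
    o <- stats::optim(st, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
    o <- stats::optim(o$par, obj, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  best$par[3]
}

# project 3D points into the total-least-squares plane (for oracles)
inplane_coords <- function(pts) {
  pl <- fit_plane(pts)
  n <- pl$normal
  e1 <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- e1 - sum(e1 * n) * n
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  rel <- sweep(pts, 2L, pl$centroid)
  cbind(as.numeric(rel %*% e1), as.numeric(rel %*% e2))
}
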