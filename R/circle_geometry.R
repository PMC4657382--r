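#' Total-least-squares plane fit
#'
#' Fits the plane minimizing the sum of squared orthogonal distances (the
#' smallest principal direction of the centered points). The normal sign is
#' fixed so its medial (+x) component is non-negative, with ties broken
#' toward anterior (+y) and then superior (+z), so that downstream angle
#' conventions are reproducible.
#'
#' @param points n x 3 matrix (n >= 3, not collinear), mm.
#' @return List with `centroid` (length 3) and `normal` (unit length 3).
#' @export
fit_plane <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3) {
    fc_abort("plane fit needs at least 3 points", "femcurve_degeneracy_error")
  }
  ctr <- colMeans(points)
  x <- sweep(points, 2L, ctr, "-")
  sv <- svd(x)
  if (sv$d[2] < 1e-9 * max(sv$d[1], .Machine$double.eps)) {
    fc_abort("points are collinear; plane is undefined",
             "femcurve_degeneracy_error")
  }
  n <- sv$v[, 3]
  s <- sign(n[1])
  if (s == 0) s <- sign(n[2])
  if (s == 0) s <- sign(n[3])
  if (s == 0) s <- 1
  list(centroid = as.numeric(ctr), normal = as.numeric(n * s))
}

# exact circumcircle of 3 points in 2D; returns center and radius
circumcircle_2d <- function(p) {
  ax <- p[1, 1]; ay <- p[1, 2]
  bx <- p[2, 1]; by <- p[2, 2]
  cx <- p[3, 1]; cy <- p[3, 2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  scale2 <- max(1, max(abs(p))^2)
  if (abs(d) < 1e-9 * scale2) {
    return(list(center = c(NA_real_, NA_real_), radius = Inf))
  }
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  list(center = c(ux, uy), radius = sqrt((ax - ux)^2 + (ay - uy)^2))
}

# algebraic (Kasa) circle fit in 2D: linear least squares of
# x^2 + y^2 + D x + E y + F = 0
circle_fit_algebraic <- function(p) {
  A <- cbind(p[, 1], p[, 2], 1)
  b <- -(p[, 1]^2 + p[, 2]^2)
  sol <- qr.solve(A, b)
  cx <- -sol[1] / 2; cy <- -sol[2] / 2
  r2 <- cx^2 + cy^2 - sol[3]
  if (!is.finite(r2) || r2 <= 0) {
    fc_abort("algebraic circle fit degenerate", "femcurve_degeneracy_error")
  }
  c(cx, cy, sqrt(r2))
}

# geometric (orthogonal-residual) refinement by Gauss-Newton with a
# Levenberg damping fallback; par = (cx, cy, r)
circle_fit_geometric <- function(p, par, tol = 1e-10, max_iter = 200L) {
  obj <- function(q) {
    di <- sqrt((p[, 1] - q[1])^2 + (p[, 2] - q[2])^2)
    sum((di - q[3])^2)
  }
  lambda <- 0
  f_old <- obj(par)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    dx <- p[, 1] - par[1]; dy <- p[, 2] - par[2]
    di <- sqrt(dx^2 + dy^2)
    di[di < 1e-300] <- 1e-300
    r_i <- di - par[3]
    J <- cbind(-dx / di, -dy / di, -1)
    A <- crossprod(J) + lambda * diag(3)
    g <- crossprod(J, r_i)
    step <- tryCatch(solve(A, g), error = function(e) NULL)
    if (is.null(step)) { lambda <- max(lambda * 10, 1e-8); next }
    cand <- par - as.numeric(step)
    f_new <- obj(cand)
    if (f_new <= f_old) {
      rel <- abs(f_old - f_new) / max(f_old, 1e-300)
      par <- cand
      f_old <- f_new
      lambda <- lambda / 4
      if (rel < tol || max(abs(step)) < tol * max(abs(par), 1)) {
        converged <- TRUE
        break
      }
    } else {
      lambda <- max(lambda * 10, 1e-8)
      if (lambda > 1e12) break
    }
  }
  list(par = par, converged = converged, sse = f_old)
}

#' Fit a circle to 3D points: the radius of femoral curvature
#'
#' Projects the points onto their total-least-squares plane, initializes
#' with the algebraic (linearized) circle fit and refines by geometric
#' least squares, minimizing the sum of squared radial residuals to a
#' relative tolerance of 1e-10. Applied to the canal centerline, the fitted
#' radius is the radius of femoral curvature (RFC) and the fitted plane is
#' the curvature plane whose tilt from the coronal plane is the banking
#' angle.
#'
#' @param points n x 3 matrix (n >= 3, not collinear), mm.
#' @return A `fem_circle`: list with `center` (3), `radius` (mm), `normal`
#'   (unit, medial component >= 0), `rmse` (in-plane radial RMSE, mm), and
#'   `converged`.
#' @examples
#' pts <- cbind(cos(seq(0, 2 * pi, length.out = 20)),
#'              sin(seq(0, 2 * pi, length.out = 20)), 0)
#' fit_circle_3d(pts)$radius
#' @export
fit_circle_3d <- function(points) {
  points <- as.matrix(points)
  pl <- fit_plane(points)
  n <- pl$normal
  e1 <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unitize(e1 - sum(e1 * n) * n)
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  rel <- sweep(points, 2L, pl$centroid, "-")
  p2 <- cbind(as.numeric(rel %*% e1), as.numeric(rel %*% e2))
  par0 <- circle_fit_algebraic(p2)
  fit <- circle_fit_geometric(p2, par0)
  if (!fit$converged) {
    warning("geometric circle fit did not converge in 200 iterations; ",
            "returning algebraic fit", call. = FALSE)
    fit$par <- par0
    di <- sqrt((p2[, 1] - par0[1])^2 + (p2[, 2] - par0[2])^2)
    fit$sse <- sum((di - par0[3])^2)
  }
  center <- pl$centroid + fit$par[1] * e1 + fit$par[2] * e2
  structure(list(
    center = as.numeric(center),
    radius = fit$par[3],
    normal = n,
    rmse = sqrt(fit$sse / nrow(points)),
    converged = fit$converged
  ), class = "fem_circle")
}

#' @export
print.fem_circle <- function(x, ...) {
  cat(sprintf("<fem_circle> radius %.3f mm, rmse %.4g mm, normal (%.4f, %.4f, %.4f)\n",
              x$radius, x$rmse, x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

#' @export
glance.fem_circle <- function(x, ...) {
  tibble::tibble(radius = x$radius, rmse = x$rmse, converged = x$converged,
                 normal_x = x$normal[1], normal_y = x$normal[2],
                 normal_z = x$normal[3])
}

#' @export
apply_transform.fem_circle <- function(transform, x) {
  x$center <- as.numeric(transform$rotation %*% x$center + transform$translation)
  n <- as.numeric(transform$rotation %*% x$normal)
  s <- sign(n[1]); if (s == 0) s <- sign(n[2]); if (s == 0) s <- sign(n[3])
  if (s == 0) s <- 1
  x$normal <- n * s
  x
}

#' Orthographic anatomical projections
#'
#' Projects standardized-frame points onto the sagittal plane (dropping
#' the medial-lateral x coordinate, returning (y, z) pairs) or the coronal
#' plane (dropping the anterior-posterior y, returning (x, z) pairs).
#'
#' @param points n x 3 matrix in the standardized frame.
#' @param plane `"sagittal"` or `"coronal"`.
#' @return n x 2 matrix of projected coordinates (mm).
#' @export
project_points <- function(points, plane = c("sagittal", "coronal")) {
  plane <- match.arg(plane)
  points <- as.matrix(points)
  if (plane == "sagittal") points[, c(2, 3), drop = FALSE]
  else points[, c(1, 3), drop = FALSE]
}

#' Apex radius of a projected femoral curvature
#'
#' Closed form for the radius of curvature at the bow apex of the
#' orthographic projection of a 3D circular bow with radius `R` and banking
#' angle `beta`: the sagittal projection has apex radius `R / sin(beta)`
#' and the coronal projection `R / |cos(beta)|`. At `beta = 90` degrees the
#' coronal projection degenerates to a straight line (infinite radius);
#' likewise the sagittal projection at 0 or 180 degrees. This makes exact
#' the observation that the coronal radius grows as banking approaches 90
#' degrees from either side and shrinks beyond.
#'
#' @param R 3D radius of curvature (mm), > 0.
#' @param beta banking angle in degrees, in (0, 180).
#' @param plane `"sagittal"` or `"coronal"`.
#' @return Projected apex radius (mm); `Inf` flags a straight-line
#'   projection.
#' @examples
#' apex_projected_radius(1000, 60, "sagittal") # 1154.70
#' apex_projected_radius(1000, 60, "coronal")  # 2000
#' @export
apex_projected_radius <- function(R, beta, plane = c("sagittal", "coronal")) {
  plane <- match.arg(plane)
  check_number(R, "R", lower = 0, closed_lower = FALSE)
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) ||
      beta <= 0 || beta >= 180) {
    fc_abort("`beta` must lie strictly inside (0, 180) degrees",
             "femcurve_parameter_error")
  }
  b <- deg2rad(beta)
  if (plane == "sagittal") {
    s <- sin(b)
    if (s < 1e-12) return(Inf)
    R / s
  } else {
    c_ <- abs(cos(b))
    if (c_ < 1e-12) return(Inf)
    R / c_
  }
}
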