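#' Rigid transforms
#'
#' A rigid transform is a proper rotation (3x3 orthonormal matrix with
#' determinant +1) followed by a translation, mapping points `x` to
#' `R x + t`. All lengths are in mm. These transforms carry meshes,
#' centerlines and fitted circles between the native (e.g. scanner) frame
#' and the standardized osteometric frame.
#'
#' @param rotation 3x3 proper rotation matrix.
#' @param translation length-3 numeric translation vector (mm).
#' @return An object of class `rigid_transform`.
#' @examples
#' tr <- rigid_transform(diag(3), c(1, 0, 0))
#' apply_transform(tr, matrix(0, 1, 3))
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  translation <- unname(as.numeric(translation))
  if (!all(dim(rotation) == c(3L, 3L)) || length(translation) != 3L) {
    fc_abort("rotation must be 3x3 and translation length 3",
             "femcurve_parameter_error")
  }
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-10 ||
      abs(det(rotation) - 1) > 1e-10) {
    fc_abort("rotation must be orthonormal with det +1 (within 1e-10)",
             "femcurve_parameter_error")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle(x$rotation)
  cat(sprintf("<rigid_transform> rotation %.4f deg, translation (%.3f, %.3f, %.3f) mm\n",
              rad2deg(ang), x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

rotation_angle <- function(R) {
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
}

# rotation taking unit vector a onto unit vector b by the minimal angle
rotation_between <- function(a, b) {
  a <- unitize(a); b <- unitize(b)
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  cth <- sum(a * b)
  if (cth > 1 - 1e-15) return(diag(3))
  if (cth < -1 + 1e-12) {
    # 180 degrees: rotate about any axis orthogonal to a
    axis <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- unitize(axis - sum(axis * a) * a)
    return(rotation_axis_angle(axis, pi))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + cth)
}

rotation_axis_angle <- function(axis, angle) {
  axis <- unitize(axis)
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Apply, compose and invert rigid transforms
#'
#' `apply_transform()` maps an n x 3 point matrix (or a [fem_mesh],
#' [fem_centerline] or [fem_circle]) through the transform;
#' `compose_transform(b, a)` returns the transform equivalent to applying
#' `a` first and then `b`; `invert_transform()` gives the inverse.
#'
#' @param transform,a,b `rigid_transform` objects.
#' @param x points (n x 3 matrix), `fem_mesh`, `fem_centerline` or
#'   `fem_circle`.
#' @return The transformed object (same class as `x`).
#' @export
apply_transform <- function(transform, x) {
  stopifnot(inherits(transform, "rigid_transform"))
  UseMethod("apply_transform", x)
}

#' @export
apply_transform.default <- function(transform, x) {
  x <- as.matrix(x)
  stopifnot(ncol(x) == 3L)
  sweep(x %*% t(transform$rotation), 2L, transform$translation, "+")
}

#' @rdname apply_transform
#' @export
compose_transform <- function(b, a) {
  rigid_transform(b$rotation %*% a$rotation,
                  as.numeric(b$rotation %*% a$translation) + b$translation)
}

#' @rdname apply_transform
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$translation))
}

#' Random rigid transform
#'
#' Draws a rotation uniformly on SO(3) (QR of a Gaussian matrix with sign
#' correction) and a translation with components uniform on
#' `[-max_translation, max_translation]`. Used to exercise pose invariance.
#'
#' @param seed integer seed.
#' @param max_translation largest translation magnitude per axis (mm).
#' @return A `rigid_transform`.
#' @export
random_rigid_transform <- function(seed, max_translation = 100) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  rigid_transform(Q, runif(3, -max_translation, max_translation))
}
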