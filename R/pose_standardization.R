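#' Settle a mesh onto the coronal support plane
#'
#' Deterministic quasi-static replacement for a gravity simulation: among
#' the convex-hull facets that are statically stable (the center of mass,
#' projected along the facet normal, falls inside the facet), the resting
#' contact is the facet with the largest support triangle among those
#' facing within 60 degrees of `down` (tilted roll-contacts have smaller
#' supports than the genuine posterior three-point facet); when no stable
#' facet faces downward, the angularly closest one is used. The mesh is rotated so that facet lies on the plane
#' y = 0 with the body in y >= 0, and translated so the contact is exactly
#' at y = 0. For a femur placed supine this brings the most posterior
#' points of both condyles and the greater trochanter into contact with the
#' coronal plane.
#'
#' @param mesh a watertight [fem_mesh].
#' @param down unit gravity direction in the mesh's current frame, or
#'   `NULL` (default) to estimate it anatomically as the direction opposite
#'   the bow apex (see [bow_apex_direction()]): the femoral bow is convex
#'   anteriorly, so gravity opposite the apex lays the bone supine from any
#'   starting orientation. Pass an explicit direction to settle
#'   non-anatomical meshes.
#' @return The [rigid_transform] that was applied (use
#'   [apply_transform()] to carry other geometry along). The transform has
#'   attribute `single_point_contact = TRUE` when the selected facet is
#'   tiny relative to the hull (near-degenerate, e.g. a sphere resting on
#'   one of many facets).
#' @export
settle_on_plane <- function(mesh, down = NULL) {
  if (!is_watertight(mesh)) {
    fc_abort("settling requires a watertight mesh (center of mass)",
             "femcurve_input_error")
  }
  down <- if (is.null(down)) -bow_apex_direction(mesh) else unitize(down)
  com <- mesh_center_of_mass(mesh)
  hull <- convex_hull_3d(mesh$vertices)
  v <- mesh$vertices
  f <- hull$faces
  n <- hull$normals

  stable <- logical(nrow(f))
  for (k in seq_len(nrow(f))) {
    a <- v[f[k, 1], ]; b <- v[f[k, 2], ]; c_ <- v[f[k, 3], ]
    nk <- n[k, ]
    q <- com + (sum((a - com) * nk)) * nk   # COM projected along the normal
    # barycentric inside test with a small tolerance
    u <- b - a; w <- c_ - a; p <- q - a
    uu <- sum(u * u); ww <- sum(w * w); uw <- sum(u * w)
    pu <- sum(p * u); pw <- sum(p * w)
    den <- uu * ww - uw * uw
    if (abs(den) < 1e-18) next
    s <- (ww * pu - uw * pw) / den
    t <- (uu * pw - uw * pu) / den
    stable[k] <- s >= -1e-9 && t >= -1e-9 && s + t <= 1 + 1e-9
  }
  if (!any(stable)) {
    fc_abort("no statically stable resting facet found", "femcurve_settling_error")
  }
  facet_area <- function(k) {
    u <- v[f[k, 2], ] - v[f[k, 1], ]; w <- v[f[k, 3], ] - v[f[k, 1], ]
    cr <- c(u[2] * w[3] - u[3] * w[2], u[3] * w[1] - u[1] * w[3],
            u[1] * w[2] - u[2] * w[1])
    sqrt(sum(cr^2)) / 2
  }
  ks <- which(stable)
  # settle toward `down`: among stable facets facing within 60 degrees of
  # the gravity direction, rest on the one with the largest contact
  # triangle (a tilted roll-contact always has a smaller support than the
  # genuine three-point facet); fall back to the angularly nearest facet
  # when none faces downward
  dots <- as.numeric(n[ks, , drop = FALSE] %*% down)
  cone <- ks[dots >= cos(pi / 3)]
  k <- if (length(cone) > 0) {
    cone[which.max(vapply(cone, facet_area, numeric(1)))]
  } else {
    ks[which.max(dots)]
  }

  hull_area <- sum(vapply(seq_len(nrow(f)), facet_area, numeric(1)))
  tiny <- facet_area(k) < 1e-3 * hull_area

  rot <- rotation_between(n[k, ], c(0, -1, 0))
  v_rot <- v %*% t(rot)
  tr <- rigid_transform(rot, c(0, -min(v_rot[, 2]), 0))
  attr(tr, "single_point_contact") <- tiny
  if (tiny) {
    warning("resting facet is near-degenerate (single-point-like contact)",
            call. = FALSE)
  }
  tr
}

#' Anterior direction estimate from the bow apex
#'
#' Estimates the anterior direction of a femur-like mesh in an arbitrary
#' pose: cross-section centroids are approximated by binning vertices along
#' the principal axis (central 70% of the bone, so head and condyles do not
#' dominate), and the apex direction is the perpendicular offset of the
#' most-bowed centroid from the end-to-end chord. The femoral shaft is
#' convex anteriorly, so this direction approximates anterior regardless of
#' pose; it seeds the gravity direction of [settle_on_plane()].
#'
#' @param mesh a [fem_mesh].
#' @param n_bins number of axial bins for the coarse centroid curve.
#' @return Unit length-3 vector in the mesh's current frame.
#' @export
bow_apex_direction <- function(mesh, n_bins = 21L) {
  v <- mesh$vertices
  axis <- prcomp(v, center = TRUE, scale. = FALSE)$rotation[, 1]
  proj <- as.numeric(v %*% axis)
  lim <- quantile(proj, c(0.15, 0.85))
  keep <- proj >= lim[1] & proj <= lim[2]
  bins <- cut(proj[keep], breaks = n_bins, labels = FALSE)
  ctr <- t(vapply(seq_len(n_bins), function(b) {
    colMeans(v[keep, , drop = FALSE][bins == b, , drop = FALSE])
  }, numeric(3)))
  ctr <- ctr[stats::complete.cases(ctr), , drop = FALSE]
  chord <- unitize(ctr[nrow(ctr), ] - ctr[1, ])
  rel <- sweep(ctr, 2L, ctr[1, ], "-")
  perp <- rel - outer(as.numeric(rel %*% chord), chord)
  k <- which.max(rowSums(perp^2))
  if (sqrt(sum(perp[k, ]^2)) < 0.5) {
    fc_abort("mesh shows no measurable bow; supply `down` explicitly",
             "femcurve_degeneracy_error")
  }
  unitize(perp[k, ])
}

#' Slide the settled femur against the axial end plate
#'
#' Second board contact: with the coronal contact preserved (motions
#' restricted to rotation about the y axis and translation in the coronal
#' plane), the bone is rotated until it rests on the two distal condylar
#' support points and translated so they lie at z = 0 with their midpoint
#' at x = 0. Candidate resting edges are the statically stable edges of the
#' (x, z) convex hull whose two support vertices are at least 10 mm apart
#' (two condyles, not a single point); among them the edge giving the
#' greatest center-of-mass height is selected, which for a femur uniquely
#' puts the distal condyles down and the (heavier, head-bearing) proximal
#' end up regardless of the starting rotation.
#'
#' @param mesh the [fem_mesh] after [settle_on_plane()] (coronal contact at
#'   y = 0).
#' @param pose1 the transform returned by the first stage (kept for the
#'   audit trail; the composite is `compose_transform(pose2, pose1)`).
#' @return The [rigid_transform] of this stage.
#' @export
slide_to_axial <- function(mesh, pose1 = NULL) {
  v <- mesh$vertices
  if (min(v[, 2]) < -1e-6) {
    fc_abort("mesh is not resting on the coronal plane; run settle_on_plane() first",
             "femcurve_state_error")
  }
  com <- mesh_center_of_mass(mesh)[c(1, 3)]
  p2 <- v[, c(1, 3), drop = FALSE]
  h <- grDevices::chull(p2)          # counter-clockwise hull vertex indices
  hp <- p2[h, , drop = FALSE]
  nh <- nrow(hp)
  best <- NULL
  for (i in seq_len(nh)) {
    a <- hp[i, ]; b <- hp[if (i == nh) 1L else i + 1L, ]
    e <- b - a
    len <- sqrt(sum(e^2))
    if (len < 10) next                     # single-point-like contact
    # stability: COM projects within the edge segment
    t <- sum((com - a) * e) / len^2
    if (t < 0 || t > 1) next
    nrm <- c(e[2], -e[1]) / len            # outward for clockwise edges
    if (sum((com - a) * nrm) > 0) nrm <- -nrm
    height <- -sum((com - a) * nrm)
    if (is.null(best) || height > best$height) {
      best <- list(a = a, b = b, nrm = nrm, height = height)
    }
  }
  if (is.null(best)) {
    fc_abort("no two-point distal contact with >= 10 mm separation found",
             "femcurve_contact_error")
  }
  # rotate about +y so the edge outward normal becomes -z
  ang <- atan2(best$nrm[1], -best$nrm[2]) # angle from (0,-1) to nrm in (x,z)
  rot <- rotation_axis_angle(c(0, 1, 0), ang)
  a3 <- c(best$a[1], 0, best$a[2])
  b3 <- c(best$b[1], 0, best$b[2])
  a_r <- as.numeric(rot %*% a3)
  b_r <- as.numeric(rot %*% b3)
  tr <- rigid_transform(rot, c(-(a_r[1] + b_r[1]) / 2, 0, -a_r[3]))
  tr
}

#' Standardize a femur onto the virtual osteometric board
#'
#' Composes the two settling stages ([settle_on_plane()] then
#' [slide_to_axial()]) on the cortex mesh and applies the identical rigid
#' transform to any accompanying geometry (canal mesh, centerline, fitted
#' circle), exactly as the canal model and centerline circle are aligned
#' with the standardized femur via the recorded transformation matrix.
#'
#' @param cortex the whole-femur [fem_mesh].
#' @param extras named list of objects to carry along ([fem_mesh],
#'   [fem_centerline], [fem_circle] or n x 3 point matrices).
#' @param down gravity direction for the first stage; `NULL` (default)
#'   estimates it from the bow so the result is independent of the initial
#'   pose.
#' @return List with `transform` (the composite [rigid_transform]),
#'   `cortex` (standardized mesh) and `extras` (transformed).
#' @export
standardize <- function(cortex, extras = list(), down = NULL) {
  t1 <- settle_on_plane(cortex, down)
  m1 <- apply_transform(t1, cortex)
  t2 <- slide_to_axial(m1, t1)
  tr <- compose_transform(t2, t1)
  list(
    transform = tr,
    cortex = apply_transform(t2, m1),
    extras = lapply(extras, function(x) apply_transform(tr, x))
  )
}

#' Femoral length of a standardized femur
#'
#' The axial extent of the standardized model: maximum z (most superior
#' point of the femoral head) minus minimum z (distal condylar contact,
#' which is 0 after standardization). This is the bounding-box property a
#' CAD package reports for the standardized model; for anatomical bows it
#' differs from the 3D point-to-point distance by well under 0.1%.
#'
#' @param cortex_std a standardized [fem_mesh] (distal contact at z = 0).
#' @return Length in mm.
#' @export
femoral_length <- function(cortex_std) {
  z <- cortex_std$vertices[, 3]
  if (min(z) < -1e-3) {
    fc_abort("mesh is not standardized (min z < -1e-3); run standardize() first",
             "femcurve_state_error")
  }
  max(z) - min(z)
}
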