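#' Parameters for a synthetic femur
#'
#' Bundles and validates the parameters of the parametric femur generator.
#' The generated geometry is a circular-arc medullary canal of radius
#' `R_curvature` whose bow apex direction lies in the transverse plane at
#' `banking` degrees from the medial direction, wrapped in a tubular canal
#' with a quadratic (single-minimum) radius profile and a cortical outer
#' surface carrying the landmark features that define the standardized
#' osteometric pose: three posterior support landmarks (two condylar, one
#' greater-trochanter) whose extremal points are exactly coplanar (the
#' coronal plane y = 0), two distal condylar landmarks exactly coplanar in
#' the axial plane z = 0, a medial epicondyle marker, and a spherical head
#' whose most superior point sets the femoral length.
#'
#' @param R_curvature radius of the canal bow circle (mm), > 0.
#' @param banking banking angle (degrees) in `[0, 180]`: 90 is a pure
#'   anterior bow, < 90 anteromedial, > 90 anterolateral apex.
#' @param arc_span angular span of the canal arc (degrees), in (0, 90).
#' @param apex_offset position of the bow apex along the arc as a fraction
#'   in (-0.5, 0.5); 0 puts the apex mid-arc.
#' @param canal_radius_min,canal_radius_max canal tube radius at the
#'   isthmus and at the ends (mm), `min <= max`.
#' @param isthmus_frac arc fraction (0, 1) of the narrowest cross-section,
#'   measured from the proximal canal end.
#' @param cortex_thickness cortical wall thickness added outside the canal
#'   (mm), > 0.
#' @param length_total femoral length: distance from the most superior head
#'   point to the distal condylar contact plane (mm).
#' @param side `"left"` or `"right"`; right femurs are exact sagittal
#'   mirror images of the left construction.
#' @param mesh_resolution named vector with `circumferential` (>= 24) and
#'   `axial` (>= 60) segment counts.
#' @param seed integer seed recorded with the parameters (mesh construction
#'   itself is deterministic).
#' @return A validated `femur_params` list.
#' @export
femur_params <- function(R_curvature = 971.44,
                         banking = 93.48,
                         arc_span = 16,
                         apex_offset = 0,
                         canal_radius_min = 5.25,
                         canal_radius_max = 7.5,
                         isthmus_frac = 0.55,
                         cortex_thickness = 5,
                         length_total = 428.07,
                         side = c("left", "right"),
                         mesh_resolution = c(circumferential = 37, axial = 110),
                         seed = 1L) {
  side <- match.arg(side)
  check_number(R_curvature, "R_curvature", lower = 0, closed_lower = FALSE)
  check_number(banking, "banking", lower = 0, upper = 180)
  check_number(arc_span, "arc_span", lower = 0, upper = 90,
               closed_lower = FALSE, closed_upper = FALSE)
  check_number(apex_offset, "apex_offset", lower = -0.5, upper = 0.5,
               closed_lower = FALSE, closed_upper = FALSE)
  check_number(canal_radius_min, "canal_radius_min", lower = 0,
               closed_lower = FALSE)
  check_number(canal_radius_max, "canal_radius_max", lower = 0,
               closed_lower = FALSE)
  check_number(isthmus_frac, "isthmus_frac", lower = 0, upper = 1,
               closed_lower = FALSE, closed_upper = FALSE)
  check_number(cortex_thickness, "cortex_thickness", lower = 0,
               closed_lower = FALSE)
  check_number(length_total, "length_total", lower = 0, closed_lower = FALSE)
  if (canal_radius_min > canal_radius_max) {
    fc_abort("canal_radius_min must be <= canal_radius_max",
             "femcurve_parameter_error")
  }
  res <- mesh_resolution
  if (is.null(names(res)) || !all(c("circumferential", "axial") %in% names(res))) {
    names(res) <- c("circumferential", "axial")[seq_along(res)]
  }
  n_c <- as.integer(res[["circumferential"]])
  n_a <- as.integer(res[["axial"]])
  if (n_c < 24L || n_a < 60L) {
    fc_abort("mesh_resolution needs >= 24 circumferential and >= 60 axial segments",
             "femcurve_parameter_error")
  }
  span_rad <- deg2rad(arc_span)
  chord <- 2 * R_curvature * sin(span_rad / 2)
  if (chord > length_total) {
    fc_abort("arc chord exceeds length_total; reduce arc_span or R_curvature",
             "femcurve_parameter_error")
  }
  arc_len <- R_curvature * span_rad
  if (arc_len / (n_a - 1) > 0.02 * arc_len) {
    fc_abort("axial resolution too low to resolve the isthmus",
             "femcurve_parameter_error")
  }
  structure(list(
    R_curvature = R_curvature, banking = banking, arc_span = arc_span,
    apex_offset = apex_offset, canal_radius_min = canal_radius_min,
    canal_radius_max = canal_radius_max, isthmus_frac = isthmus_frac,
    cortex_thickness = cortex_thickness, length_total = length_total,
    side = side,
    mesh_resolution = c(circumferential = n_c, axial = n_a),
    seed = as.integer(seed)
  ), class = "femur_params")
}

# canal bow frame for a LEFT femur (medial = +x): apex direction in the
# transverse plane at `banking` degrees from medial, arc plane spanned by
# the apex direction and the proximal-distal axis.
arc_frame <- function(banking) {
  b <- deg2rad(banking)
  list(d = c(cos(b), sin(b), 0),          # apex (bow) direction
       z = c(0, 0, 1),
       bnorm = c(sin(b), -cos(b), 0))     # unit normal of the arc plane
}

# arc angle as a function of arc fraction t in [0, 1] (t = 0 proximal)
arc_theta <- function(t, params) {
  s <- deg2rad(params$arc_span)
  (0.5 + params$apex_offset - t) * s
}

#' Analytic canal centerline arc
#'
#' Evaluates `n_points` points of the canal bow: a circular arc of radius
#' `R_curvature` centered at the origin, in the plane spanned by the
#' proximal-distal axis and the apex direction (transverse direction at
#' `banking` degrees from medial). Points run proximal to distal. This is
#' the exact curve the generated canal tube is swept along, so it serves as
#' the ground-truth oracle for centerline recovery.
#'
#' @param params a [femur_params] object.
#' @param n_points number of points (>= 3).
#' @return n x 3 matrix of points (mm).
#' @export
make_canal_arc <- function(params, n_points = 25L) {
  stopifnot(inherits(params, "femur_params"))
  if (n_points < 3L) {
    fc_abort("n_points must be >= 3", "femcurve_parameter_error")
  }
  fr <- arc_frame(params$banking)
  t <- seq(0, 1, length.out = n_points)
  th <- arc_theta(t, params)
  pts <- params$R_curvature *
    (outer(cos(th), fr$d) + outer(sin(th), fr$z))
  if (params$side == "right") pts[, 1] <- -pts[, 1]
  pts
}

# canal tube radius profile: quadratic in arc fraction with its single
# minimum at isthmus_frac, clipped at canal_radius_max
canal_radius_profile <- function(t, params) {
  r <- params$canal_radius_min +
    (params$canal_radius_max - params$canal_radius_min) *
      ((t - params$isthmus_frac) / 0.5)^2
  pmin(r, params$canal_radius_max)
}

# ring of n_c vertices of radius rho around center `ctr` in the plane
# spanned by unit vectors u, v; phase offset avoids symmetric hull slivers
ring_vertices <- function(ctr, rho, u, v, n_c, phase = 0.5671) {
  phi <- phase + 2 * pi * (seq_len(n_c) - 1L) / n_c
  sweep(outer(rho * cos(phi), u) + outer(rho * sin(phi), v), 2L, ctr, "+")
}

# closed surface from a stack of rings plus two cap centers (fan caps)
capped_tube_mesh <- function(rings, cap_start, cap_end) {
  n_c <- nrow(rings[[1]])
  K <- length(rings)
  verts <- do.call(rbind, rings)
  i_start <- nrow(verts) + 1L
  i_end <- nrow(verts) + 2L
  verts <- rbind(verts, cap_start, cap_end)
  idx <- function(i, j) (i - 1L) * n_c + ((j - 1L) %% n_c) + 1L
  faces <- vector("list", K + 1L)
  for (i in seq_len(K - 1L)) {
    j <- seq_len(n_c)
    a <- idx(i, j); b <- idx(i, j + 1L)
    c_ <- idx(i + 1L, j + 1L); d_ <- idx(i + 1L, j)
    faces[[i]] <- rbind(cbind(a, b, c_), cbind(a, c_, d_))
  }
  j <- seq_len(n_c)
  faces[[K]] <- cbind(i_start, idx(1L, j + 1L), idx(1L, j))
  faces[[K + 1L]] <- cbind(i_end, idx(K, j), idx(K, j + 1L))
  orient_outward(fem_mesh(verts, do.call(rbind, faces)))
}

#' Generate synthetic femur meshes with exact ground truth
#'
#' Builds a watertight canal mesh (tube swept along the analytic bow arc
#' with the quadratic isthmus profile) and a watertight cortex mesh: the
#' canal tube thickened by `cortex_thickness`, extended distally with a
#' condylar flare and proximally through a neck into a spherical head, and
#' decorated with landmark features placed by exact vertex displacement so
#' that (i) the three posterior landmark apexes are exactly coplanar and
#' define the ground-truth coronal plane y = 0, (ii) the two distal
#' condylar apexes are exactly coplanar and define the axial plane z = 0
#' with their midpoint at x = 0, and (iii) the most superior head point is
#' exactly at z = `length_total`. Meshes are generated directly in the
#' standardized frame, so the ground-truth standardization transform is the
#' identity. Right-side femurs are exact mirror images across the sagittal
#' plane.
#'
#' @param params a [femur_params] object.
#' @return List with `cortex` ([fem_mesh]), `canal` ([fem_mesh]) and
#'   `truth` (a `femur_truth` list: `R_curvature`, `banking`,
#'   `isthmus_diameter`, `isthmus_arc_fraction`, `femoral_length`,
#'   `standard_pose` identity [rigid_transform], `arc` description with
#'   sampled `centerline` points, and landmark locations).
#' @export
make_femur_meshes <- function(params) {
  stopifnot(inherits(params, "femur_params"))
  p <- params
  n_c <- p$mesh_resolution[["circumferential"]]
  n_a <- p$mesh_resolution[["axial"]]
  R <- p$R_curvature
  fr <- arc_frame(p$banking)
  d <- fr$d; zhat <- fr$z; bnorm <- fr$bnorm

  arc_pt <- function(th) R * (cos(th) * d + sin(th) * zhat)
  radial <- function(th) cos(th) * d + sin(th) * zhat
  tang_prox <- function(th) -sin(th) * d + cos(th) * zhat # points proximal

  th0 <- arc_theta(0, p)   # proximal canal end
  th1 <- arc_theta(1, p)   # distal canal end

  ## ---- canal mesh: tube along the arc, capped ----
  t_st <- seq(0, 1, length.out = n_a)
  th_st <- arc_theta(t_st, p)
  r_st <- canal_radius_profile(t_st, p)
  canal_rings <- lapply(seq_len(n_a), function(i) {
    th <- th_st[i]
    ring_vertices(arc_pt(th), r_st[i], radial(th), bnorm, n_c)
  })
  canal <- capped_tube_mesh(canal_rings, arc_pt(th0), arc_pt(th1))

  ## ---- cortex: distal flare + shaft + proximal neck + head dome ----
  ct <- p$cortex_thickness
  r_out <- r_st + ct
  ext_d <- 14                       # distal extension arc length (mm)
  flare <- 1.5                      # condylar flare factor
  n_d <- 8L
  r_head <- 21
  r_neck <- 0.85 * r_out[1]
  if (r_neck >= r_head) {
    fc_abort("canal too wide for the fixed head radius", "femcurve_parameter_error")
  }

  # distal extension stations (beyond the distal canal end)
  th_dist <- th1 - ext_d / R * seq_len(n_d) / n_d
  r_dist <- r_out[n_a] * (1 + (flare - 1) * seq_len(n_d) / n_d)
  th_bot <- th_dist[n_d]

  dist_rings <- lapply(seq_len(n_d), function(k) {
    ring_vertices(arc_pt(th_dist[k]), r_dist[k], radial(th_dist[k]), bnorm, n_c)
  })
  shaft_rings <- lapply(seq_len(n_a), function(i) {
    ring_vertices(arc_pt(th_st[i]), r_out[i], radial(th_st[i]), bnorm, n_c)
  })
  # minimum z of the bone below the head is set by the distal stations
  z_min_pre <- min(vapply(dist_rings, function(rg) min(rg[, 3]), numeric(1)),
                   arc_pt(th_bot)[3])

  # solve the proximal extension so that the head top lands exactly at
  # length_total above the (displaced) distal contact plane
  aoff <- sqrt(r_head^2 - r_neck^2)
  z_top_target <- p$length_total + (z_min_pre - 4)
  z_top_of <- function(ext_p) {
    th_t <- th0 + ext_p / R
    R * sin(th_t) + aoff * cos(th_t) + r_head - z_top_target
  }
  lo <- 1; hi <- 0.6 * p$length_total
  if (z_top_of(lo) > 0 || z_top_of(hi) < 0) {
    fc_abort("length_total incompatible with the arc geometry (head cannot be placed)",
             "femcurve_parameter_error")
  }
  ext_p <- stats::uniroot(z_top_of, c(lo, hi), tol = 1e-10)$root
  th_top <- th0 + ext_p / R

  n_p <- max(6L, ceiling(ext_p / (R * deg2rad(p$arc_span) / n_a)))
  th_prox <- th0 + ext_p / R * seq_len(n_p) / n_p
  u <- seq_len(n_p) / n_p
  r_prox <- r_out[1] + (r_neck - r_out[1]) * (3 * u^2 - 2 * u^3)
  prox_rings <- lapply(seq_len(n_p), function(k) {
    ring_vertices(arc_pt(th_prox[k]), r_prox[k], radial(th_prox[k]), bnorm, n_c)
  })

  # head dome: sphere of radius r_head centered on the extended tangent
  w <- tang_prox(th_top)
  P_top <- arc_pt(th_top)
  C_h <- P_top + aoff * w
  N_top <- radial(th_top)
  psi_j <- acos(-aoff / r_head)
  n_h <- 14L
  psi <- psi_j * (1 - seq_len(n_h) / (n_h + 1L))
  head_rings <- lapply(psi, function(ps) {
    ring_vertices(C_h + r_head * cos(ps) * w, r_head * sin(ps), N_top, bnorm, n_c)
  })
  pole <- C_h + r_head * w

  rings <- c(rev(dist_rings), rev(shaft_rings), prox_rings, head_rings)
  cortex <- capped_tube_mesh(rings, arc_pt(th_bot), pole)

  nv_ring <- n_c * length(rings)
  ring_offset <- function(k) (k - 1L) * n_c # rings indexed distal -> head

  # snap the head vertex nearest the sphere's true top onto it exactly,
  # so the most superior point is analytic
  top_pt <- C_h + r_head * c(0, 0, 1)
  head_first <- n_c * (n_d + n_a + n_p)
  head_ids <- head_first + seq_len(n_c * n_h)
  hv <- cortex$vertices[head_ids, , drop = FALSE]
  snap <- head_ids[which.min((hv[, 1] - top_pt[1])^2 + (hv[, 2] - top_pt[2])^2 +
                               (hv[, 3] - top_pt[3])^2)]
  cortex$vertices[snap, ] <- top_pt
  pole_id <- nv_ring + 2L
  if (cortex$vertices[pole_id, 3] > top_pt[3]) cortex$vertices[pole_id, 3] <- top_pt[3]

  ## ---- landmark displacement ----
  V <- cortex$vertices
  # distal condylar contacts: widest-x pair on the bottom rim ring
  rim_ids <- ring_offset(1L) + seq_len(n_c)
  rim <- V[rim_ids, , drop = FALSE]
  j_a <- rim_ids[which.max(rim[, 1])]
  j_b <- rim_ids[which.min(rim[, 1])]
  z_D <- z_min_pre - 4
  for (j in c(j_a, j_b)) {
    nb <- ring_neighbors(j, ring_offset(1L), n_c)
    V[nb, 3] <- pmin(V[nb, 3], z_D + 2)
    V[j, 3] <- z_D
  }

  # posterior landmarks: greater trochanter (proximal) and both condyles
  # (distal), displaced along -y to a common plane
  y_min_pre <- min(V[, 2])
  y_P <- y_min_pre - 4
  # GT sits near the top of the proximal extension (just below the neck),
  # shielding the head sphere from posterior rolling contact
  gt_ring <- n_c * (n_d + n_a) + n_c * max(1L, floor(0.85 * n_p)) - n_c # 0-offset
  gt_ids <- gt_ring + seq_len(n_c)
  gtv <- V[gt_ids, , drop = FALSE]
  j_gt <- gt_ids[which.min(gtv[, 2])]
  cond_ring <- ring_offset(max(2L, n_d - 3L))
  cond_ids <- cond_ring + seq_len(n_c)
  cv <- V[cond_ids, , drop = FALSE]
  post <- which(cv[, 2] < mean(cv[, 2]))
  j_cm <- cond_ids[post[which.max(cv[post, 1])]]
  j_cl <- cond_ids[post[which.min(cv[post, 1])]]
  for (j in c(j_gt, j_cm, j_cl)) {
    ring0 <- n_c * ((j - 1L) %/% n_c)
    nb <- ring_neighbors(j, ring0, n_c)
    V[nb, 2] <- pmin(V[nb, 2], y_P + 2)
    V[j, 2] <- y_P
  }

  # medial epicondyle marker: small outward bump on the anterior-medial
  # quadrant (anterior placement keeps it clear of any near-posterior
  # support plane), breaks mirror symmetry; shaft rings are stacked
  # distal -> proximal after the distal extension
  epi_ring <- ring_offset(n_d + max(1L, floor(0.08 * n_a)))
  epi_ids <- epi_ring + seq_len(n_c)
  epi_v <- V[epi_ids, , drop = FALSE]
  ctr_epi <- colMeans(epi_v)
  ant <- which(epi_v[, 2] > ctr_epi[2])
  j_epi <- epi_ids[ant[which.max(epi_v[ant, 1])]]
  V[j_epi, 1] <- V[j_epi, 1] + 2

  ## ---- translate into the standardized frame ----
  shift <- c(-(V[j_a, 1] + V[j_b, 1]) / 2, -y_P, -z_D)
  V <- sweep(V, 2L, shift, "+")
  cortex$vertices <- V
  canal$vertices <- sweep(canal$vertices, 2L, shift, "+")

  centerline_truth <- sweep(t(vapply(th_st, arc_pt, numeric(3))), 2L, shift, "+")
  arc_center <- shift
  landmarks <- list(posterior = V[c(j_gt, j_cm, j_cl), , drop = FALSE],
                    distal = V[c(j_a, j_b), , drop = FALSE],
                    head_top = V[snap, ])

  mirror_x <- p$side == "right"
  if (mirror_x) {
    cortex <- mirror_mesh(cortex)
    canal <- mirror_mesh(canal)
    centerline_truth[, 1] <- -centerline_truth[, 1]
    arc_center[1] <- -arc_center[1]
    d[1] <- -d[1]
    bnorm[1] <- -bnorm[1]
    landmarks <- lapply(landmarks, function(m) {
      if (is.matrix(m)) { m[, 1] <- -m[, 1]; m } else { m[1] <- -m[1]; m }
    })
  }

  # generator contract: the center of mass must rest inside the posterior
  # support triangle (stable resting pose)
  com <- mesh_center_of_mass(cortex)
  tri <- landmarks$posterior[, c(1, 3), drop = FALSE]
  if (!point_in_triangle_2d(com[c(1, 3)], tri)) {
    fc_abort("center of mass falls outside the posterior support triangle; adjust parameters",
             "femcurve_parameter_error")
  }

  truth <- structure(list(
    R_curvature = R,
    banking = p$banking,
    isthmus_diameter = 2 * p$canal_radius_min,
    isthmus_arc_fraction = p$isthmus_frac,
    femoral_length = p$length_total,
    standard_pose = rigid_transform(),
    arc = list(center = arc_center, apex_dir = d, axis = c(0, 0, 1),
               normal = bnorm, radius = R,
               theta_range = c(th0, th1)),
    centerline = centerline_truth,
    landmarks = landmarks,
    params = p
  ), class = "femur_truth")

  list(cortex = cortex, canal = canal, truth = truth)
}

ring_neighbors <- function(j, ring0, n_c) {
  pos <- j - ring0
  c(ring0 + (pos %% n_c) + 1L, ring0 + ((pos - 2L) %% n_c) + 1L)
}

point_in_triangle_2d <- function(pt, tri) {
  s <- function(a, b) (pt[1] - b[1]) * (a[2] - b[2]) - (a[1] - b[1]) * (pt[2] - b[2])
  d1 <- s(tri[1, ], tri[2, ]); d2 <- s(tri[2, ], tri[3, ]); d3 <- s(tri[3, ], tri[1, ])
  !((d1 < 0 || d2 < 0 || d3 < 0) && (d1 > 0 || d2 > 0 || d3 > 0))
}

#' Evaluate the ground-truth canal arc
#'
#' @param truth a `femur_truth` object from [make_femur_meshes()].
#' @param t arc fractions in `[0, 1]` (0 = proximal canal end).
#' @return length(t) x 3 matrix of exact arc points (mm).
#' @export
ground_truth_arc <- function(truth, t) {
  a <- truth$arc
  th <- a$theta_range[1] + t * (a$theta_range[2] - a$theta_range[1])
  pts <- a$radius * (outer(cos(th), a$apex_dir) + outer(sin(th), a$axis))
  sweep(pts, 2L, a$center, "+")
}

#' Simulate a cohort table of femur morphometrics and demographics
#'
#' Generates `n_subjects` subjects with two femurs each (left and right
#' rows). Demographics are drawn from gender-specific normal distributions
#' calibrated to a Chinese adult cohort (male fraction 0.69; heights 1.69 /
#' 1.58 m, ages 64 / 70 y, weights 69 / 62 kg for male / female); femoral
#' length follows height linearly, and the radius of femoral curvature
#' (RFC) and banking angle follow configurable linear models plus Gaussian
#' noise. Default coefficients are the regression structure relating RFC to
#' femoral length, banking angle, laterality and gender (267.36 + 2.23 x
#' length - 2.88 x banking + 57.49 x laterality - 50.3 x gender), and
#' banking to gender, age and weight. Gender is coded female = 1 / male =
#' 0, laterality left = 1 / right = 0.
#'
#' @param n_subjects number of subjects (>= 10); the table has two rows per
#'   subject.
#' @param coefficients named list of named coefficient vectors for
#'   `length`, `banking` and `rfc` (each with an `intercept` entry);
#'   defaults above.
#' @param noise_sd named vector of residual standard deviations for
#'   `length`, `banking`, `rfc` and `isthmus`; zero gives the exact linear
#'   predictor, negative values are an error.
#' @param seed integer seed.
#' @return A tibble with columns `subject_id`, `side`, `laterality`,
#'   `gender`, `age_y`, `height_m`, `weight_kg`, `length_mm`,
#'   `banking_deg`, `rfc_mm`, `isthmus_mm`.
#' @export
make_cohort_table <- function(n_subjects,
                              coefficients = cohort_default_coefficients(),
                              noise_sd = cohort_default_noise(),
                              seed = 1L) {
  if (n_subjects < 10L) {
    fc_abort("n_subjects must be >= 10", "femcurve_parameter_error")
  }
  ns <- cohort_default_noise()
  ns[names(noise_sd)] <- noise_sd
  if (any(ns < 0)) {
    fc_abort("noise_sd entries must be >= 0", "femcurve_parameter_error")
  }
  cf <- cohort_default_coefficients()
  cf[names(coefficients)] <- coefficients
  set.seed(seed)

  gender <- stats::rbinom(n_subjects, 1L, 132 / 426) # female = 1
  age <- ifelse(gender == 1L,
                pmin(85, pmax(50, rnorm(n_subjects, 69.68, 8.39))),
                pmin(85, pmax(15, rnorm(n_subjects, 64.49, 12.86))))
  height <- ifelse(gender == 1L, rnorm(n_subjects, 1.58, 0.061),
                   rnorm(n_subjects, 1.69, 0.058))
  weight <- pmax(30, ifelse(gender == 1L, rnorm(n_subjects, 62.03, 9.9),
                            rnorm(n_subjects, 68.58, 9.77)))

  df <- tibble::tibble(
    subject_id = rep(seq_len(n_subjects), each = 2L),
    side = rep(c("left", "right"), times = n_subjects),
    laterality = rep(c(1L, 0L), times = n_subjects),
    gender = rep(gender, each = 2L),
    age_y = rep(age, each = 2L),
    height_m = rep(height, each = 2L),
    weight_kg = rep(weight, each = 2L)
  )
  n <- nrow(df)
  lp <- function(cfv, data) {
    out <- rep(cfv[["intercept"]], nrow(data))
    for (nm in setdiff(names(cfv), "intercept")) {
      out <- out + cfv[[nm]] * data[[nm]]
    }
    out
  }
  df$length_mm <- lp(cf$length, df) + rnorm(n, 0, ns[["length"]])
  df$banking_deg <- lp(cf$banking, df) + rnorm(n, 0, ns[["banking"]])
  df$rfc_mm <- lp(cf$rfc, dplyr::rename(df, length = "length_mm",
                                        banking = "banking_deg")) +
    rnorm(n, 0, ns[["rfc"]])
  df$isthmus_mm <- pmax(6, lp(cf$isthmus, df) + rnorm(n, 0, ns[["isthmus"]]))
  df
}

#' @rdname make_cohort_table
#' @export
cohort_default_coefficients <- function() {
  list(
    length = c(intercept = 60, height_m = 220),
    banking = c(intercept = 59.69, gender = 5.7, age_y = 0.236,
                weight_kg = 0.157),
    rfc = c(intercept = 267.36, length = 2.23, banking = -2.88,
            laterality = 57.49, gender = -50.3),
    isthmus = c(intercept = 10.5)
  )
}

#' @rdname make_cohort_table
#' @export
cohort_default_noise <- function() {
  c(length = 10.8, banking = 11, rfc = 190, isthmus = 1.5)
}
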