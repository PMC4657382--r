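#' Banking angle of the femoral curvature
#'
#' The inclination of the femoral curvature relative to the coronal plane,
#' opening toward the medial side. The bow apex direction is taken as the
#' unit vector from the centerline chord midpoint to the arc apex (the
#' centerline point farthest from the chord), projected into the transverse
#' (x, y) plane and renormalized; the banking angle is the angle between
#' this direction and the medial direction (+x for left femurs, -x for
#' right). A pure anterior bow gives 90 degrees; an anteromedial apex less,
#' an anterolateral apex more. Using the apex direction rather than the
#' plane dihedral alone distinguishes an angle of beta from 180 - beta.
#'
#' @param circle the fitted [fem_circle] in the standardized frame (kept in
#'   the record; the angle itself is driven by the centerline bow).
#' @param centerline the standardized [fem_centerline].
#' @param side `"left"` or `"right"`.
#' @return Banking angle in degrees, in `[0, 180]`.
#' @export
banking_angle <- function(circle, centerline, side = c("left", "right")) {
  side <- match.arg(side)
  p <- centerline$points
  n <- nrow(p)
  chord0 <- p[1, ]
  u <- unitize(p[n, ] - p[1, ])
  rel <- sweep(p, 2L, chord0, "-")
  along <- as.numeric(rel %*% u)
  perp <- rel - outer(along, u)
  apex_i <- which.max(rowSums(perp^2))
  mid <- (p[1, ] + p[n, ]) / 2
  d <- p[apex_i, ] - mid
  dt <- c(d[1], d[2])
  if (sqrt(sum(dt^2)) < 1e-6) {
    fc_abort("bow apex direction has no transverse component; banking undefined",
             "femcurve_degeneracy_error")
  }
  dt <- dt / sqrt(sum(dt^2))
  m <- if (side == "left") c(1, 0) else c(-1, 0)
  rad2deg(acos(max(-1, min(1, sum(m * dt)))))
}

#' Measure a femur end to end
#'
#' Runs the full measurement pipeline on a cortex/canal mesh pair:
#' standardization on the virtual osteometric board, centerline extraction,
#' inscribed-diameter profiling and isthmus detection, 3D circle fitting
#' (radius of femoral curvature), banking angle, and femoral length.
#'
#' @param cortex whole-femur [fem_mesh].
#' @param canal canal [fem_mesh] in the same frame.
#' @param side `"left"` or `"right"`.
#' @param subject_id identifier carried into the record.
#' @param n_slices,trim_fraction centerline extraction controls.
#' @param sections if `TRUE`, also compute the sagittal three-section radii
#'   via [three_section_radii()].
#' @return A `femur_record`: list with the scalar morphometrics plus the
#'   standardized geometry (`centerline`, `circle`, `transform`,
#'   `cortex_std`, `canal_std`). Use [tidy()] for a one-row tibble.
#' @export
measure_femur <- function(cortex, canal, side = c("left", "right"),
                          subject_id = NA_character_,
                          n_slices = 96L, trim_fraction = 0.10,
                          sections = FALSE) {
  side <- match.arg(side)
  stage <- function(tag, expr) {
    tryCatch(expr, error = function(e) {
      fc_abort(sprintf("[%s] %s", tag, conditionMessage(e)),
               "femcurve_stage_error")
    })
  }
  std <- stage("standardize", standardize(cortex, list(canal = canal)))
  canal_std <- std$extras$canal
  cl <- stage("centerline",
              extract_centerline(canal_std, n_slices = n_slices,
                                 trim_fraction = trim_fraction,
                                 orient = c(0, 0, 1)))
  cl <- stage("profile", inscribed_diameter_profile(canal_std, cl))
  isth <- isthmus(cl)
  circ <- stage("circle_fit", fit_circle_3d(cl$points))
  ba <- stage("banking", banking_angle(circ, cl, side))
  len <- stage("length", femoral_length(std$cortex))
  rec <- structure(list(
    subject_id = subject_id,
    side = side,
    femoral_length = len,
    rfc = circ$radius,
    banking = ba,
    isthmus_diameter = isth$diameter,
    isthmus_arc_fraction = isth$arc_fraction,
    fit_rmse = circ$rmse,
    section_radii = NULL,
    centerline = cl,
    circle = circ,
    transform = std$transform,
    cortex_std = std$cortex,
    canal_std = canal_std
  ), class = "femur_record")
  if (sections) {
    rec$section_radii <- stage("sections", three_section_radii(cl))
  }
  rec
}

#' @export
print.femur_record <- function(x, ...) {
  cat(sprintf(paste0(
    "<femur_record> %s femur%s\n",
    "  femoral length : %8.2f mm\n",
    "  RFC            : %8.2f mm (fit rmse %.3f mm)\n",
    "  banking angle  : %8.2f deg\n",
    "  isthmus        : %8.2f mm at arc fraction %.2f\n"),
    x$side,
    if (is.na(x$subject_id)) "" else paste0(" (subject ", x$subject_id, ")"),
    x$femoral_length, x$rfc, x$fit_rmse, x$banking,
    x$isthmus_diameter, x$isthmus_arc_fraction))
  if (!is.null(x$section_radii)) {
    cat(sprintf("  sagittal sections (prox/mid/dist): %.1f / %.1f / %.1f mm\n",
                x$section_radii[1], x$section_radii[2], x$section_radii[3]))
  }
  invisible(x)
}

#' @export
tidy.femur_record <- function(x, ...) {
  tibble::tibble(
    subject_id = x$subject_id,
    side = x$side,
    length_mm = x$femoral_length,
    rfc_mm = x$rfc,
    banking_deg = x$banking,
    isthmus_mm = x$isthmus_diameter,
    fit_rmse_mm = x$fit_rmse,
    section_prox_mm = if (is.null(x$section_radii)) NA_real_ else x$section_radii[1],
    section_mid_mm = if (is.null(x$section_radii)) NA_real_ else x$section_radii[2],
    section_dist_mm = if (is.null(x$section_radii)) NA_real_ else x$section_radii[3]
  )
}

#' Sagittal three-section radii
#'
#' Projects the standardized centerline onto the sagittal plane, places
#' seven points at equal arc-length spacing between the given bounds, and
#' fits exact circumcircles to the overlapping triples {1,2,3}, {3,4,5},
#' {5,6,7} (shared endpoints divide the bow into proximal, middle and
#' distal thirds). Collinear triples return `Inf` (straight projection).
#'
#' @param centerline_std standardized [fem_centerline].
#' @param bounds fractions `(proximal, distal)` of the trimmed centerline
#'   arc length between which the seven points are spread.
#' @param plane projection plane (default sagittal; coronal exposed for the
#'   degenerate checks).
#' @return Named numeric vector `c(proximal = , middle = , distal = )` of
#'   radii in mm.
#' @export
three_section_radii <- function(centerline_std, bounds = c(0, 1),
                                plane = c("sagittal", "coronal")) {
  plane <- match.arg(plane)
  if (!(bounds[1] >= 0 && bounds[1] < bounds[2] && bounds[2] <= 1)) {
    fc_abort("bounds must satisfy 0 <= proximal < distal <= 1",
             "femcurve_parameter_error")
  }
  p2 <- project_points(centerline_std$points, plane)
  seg <- sqrt(rowSums((p2[-1, , drop = FALSE] - p2[-nrow(p2), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  targets <- (bounds[1] + (bounds[2] - bounds[1]) * (0:6) / 6) * max(s)
  pts <- t(vapply(targets, function(tt) {
    i <- findInterval(tt, s, rightmost.closed = TRUE)
    i <- min(max(i, 1L), length(s) - 1L)
    w <- (tt - s[i]) / (s[i + 1] - s[i])
    (1 - w) * p2[i, ] + w * p2[i + 1, ]
  }, numeric(2)))
  radius_of <- function(idx) circumcircle_2d(pts[idx, , drop = FALSE])$radius
  c(proximal = radius_of(1:3), middle = radius_of(3:5), distal = radius_of(5:7))
}
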