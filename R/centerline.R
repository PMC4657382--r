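#' Canal centerline objects
#'
#' A `fem_centerline` holds an ordered polyline of canal cross-section
#' centroids with cumulative arc length, unit tangents and (after
#' profiling) the inscribed diameter at each control point.
#'
#' @param points n x 3 matrix of control points (mm).
#' @param inscribed_diameter optional numeric vector of diameters (mm).
#' @return A `fem_centerline` list with `points`, `arc_length`, `tangents`
#'   and `inscribed_diameter`.
#' @export
fem_centerline <- function(points, inscribed_diameter = NULL) {
  points <- as.matrix(points)
  d <- sqrt(rowSums((points[-1, , drop = FALSE] -
                       points[-nrow(points), , drop = FALSE])^2))
  if (any(d <= 0)) {
    fc_abort("centerline points must be distinct and ordered",
             "femcurve_input_error")
  }
  structure(list(
    points = points,
    arc_length = c(0, cumsum(d)),
    tangents = polyline_tangents(points),
    inscribed_diameter = inscribed_diameter
  ), class = "fem_centerline")
}

polyline_tangents <- function(p) {
  n <- nrow(p)
  tn <- matrix(0, n, 3)
  tn[1, ] <- p[2, ] - p[1, ]
  tn[n, ] <- p[n, ] - p[n - 1, ]
  if (n > 2) tn[2:(n - 1), ] <- p[3:n, , drop = FALSE] - p[1:(n - 2), , drop = FALSE]
  tn / sqrt(rowSums(tn^2))
}

#' @export
print.fem_centerline <- function(x, ...) {
  cat(sprintf("<fem_centerline> %d points, arc length %.1f mm%s\n",
              nrow(x$points), max(x$arc_length),
              if (is.null(x$inscribed_diameter)) "" else
                sprintf(", min inscribed diameter %.2f mm",
                        min(x$inscribed_diameter))))
  invisible(x)
}

#' @export
apply_transform.fem_centerline <- function(transform, x) {
  fem_centerline(apply_transform.default(transform, x$points),
                 x$inscribed_diameter)
}

#' @export
tidy.fem_centerline <- function(x, ...) {
  pts <- x$points
  arc_len <- x$arc_length
  diam <- x$inscribed_diameter %||% rep(NA_real_, nrow(pts))
  tibble::tibble(
    station = seq_len(nrow(pts)),
    x = pts[, 1], y = pts[, 2], z = pts[, 3],
    arc_length_mm = arc_len,
    inscribed_diameter_mm = diam
  )
}

#' @export
autoplot.fem_centerline <- function(object, ...) {
  df <- tidy(object)
  if (all(is.na(df$inscribed_diameter_mm))) {
    fc_abort("profile the centerline with inscribed_diameter_profile() before plotting",
             "femcurve_state_error")
  }
  isth <- isthmus(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$arc_length_mm,
                                   y = .data$inscribed_diameter_mm)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::annotate("point", x = df$arc_length_mm[isth$index],
                      y = isth$diameter, colour = "red", size = 2) +
    ggplot2::labs(x = "arc length (mm)", y = "inscribed diameter (mm)",
                  title = sprintf("Canal profile; isthmus %.2f mm", isth$diameter))
}

#' Extract the medullary-canal centerline
#'
#' Slices the watertight canal mesh with `n_slices` planes evenly spaced
#' along its principal axis and takes the area centroid of the
#' cross-section nearest the axis at each station. Two refinement passes
#' re-slice every station perpendicular to the local tangent (central
#' differences), so the centroids converge onto the true canal axis even
#' where the canal is oblique to the initial axis. Finally the first and
#' last `trim_fraction` of stations are discarded, mimicking the cutting of
#' the unreliable centerline endings near the canal openings.
#'
#' @param canal_mesh a watertight [fem_mesh] of the canal.
#' @param n_slices number of slicing stations (>= 20).
#' @param trim_fraction fraction of stations dropped at each end, in
#'   `[0, 0.25]`.
#' @param orient `NULL` for the intrinsic orientation rule (the wider canal
#'   end first, measured as the mean vertex distance from the axis per
#'   half; rotation-invariant for canals with an asymmetric radius
#'   profile), or a length-3 vector: the centerline is ordered from high to
#'   low projection on this vector (use `c(0, 0, 1)` in the standardized
#'   frame for proximal-to-distal order).
#' @return A [fem_centerline] (diameters unfilled).
#' @export
extract_centerline <- function(canal_mesh, n_slices = 96L, trim_fraction = 0.10,
                               orient = NULL) {
  if (!is_watertight(canal_mesh)) {
    fc_abort("canal mesh must be watertight", "femcurve_input_error")
  }
  if (n_slices < 20L) {
    fc_abort("n_slices must be >= 20", "femcurve_parameter_error")
  }
  check_number(trim_fraction, "trim_fraction", lower = 0, upper = 0.25)

  v <- canal_mesh$vertices
  pc <- prcomp(v, center = TRUE, scale. = FALSE)
  axis <- pc$rotation[, 1]
  if (!is.null(orient)) {
    if (sum(axis * orient) < 0) axis <- -axis
  } else {
    # intrinsic ordering: wider half of the canal first
    pr <- as.numeric(v %*% axis)
    ctr0 <- colMeans(v)
    perp <- v - outer(pr, axis) -
      matrix(ctr0 - sum(ctr0 * axis) * axis, nrow(v), 3, byrow = TRUE)
    rad <- sqrt(rowSums(perp^2))
    hi <- pr >= median(pr)
    if (mean(rad[hi]) < mean(rad[!hi])) axis <- -axis
  }
  edges <- mesh_edge_info(canal_mesh)
  proj <- as.numeric(v %*% axis)
  lim <- range(proj)
  half <- (lim[2] - lim[1]) / n_slices / 2
  stations <- seq(lim[2] - half, lim[1] + half, length.out = n_slices)

  centroids <- matrix(NA_real_, n_slices, 3)
  ok <- rep(FALSE, n_slices)
  ctr <- colMeans(v)
  for (i in seq_len(n_slices)) {
    origin <- ctr + (stations[i] - sum(ctr * axis)) * axis
    loops <- slice_mesh(canal_mesh, origin, axis, edges = edges)
    if (length(loops) == 0) next
    d2 <- vapply(loops, function(l) sum((l$centroid3d - origin)^2), numeric(1))
    centroids[i, ] <- loops[[which.min(d2)]]$centroid3d
    ok[i] <- TRUE
  }
  if (mean(!ok) > 0.20) {
    fc_abort("more than 20% of slices produced no cross-section",
             "femcurve_extraction_error")
  }
  if (any(!ok)) {
    warning(sprintf("%d of %d slices had no cross-section and were skipped",
                    sum(!ok), n_slices), call. = FALSE)
  }
  pts <- centroids[ok, , drop = FALSE]

  # refinement: re-slice each station perpendicular to the local tangent
  for (pass in 1:2) {
    tang <- polyline_tangents(pts)
    for (i in seq_len(nrow(pts))) {
      loops <- slice_mesh(canal_mesh, pts[i, ], tang[i, ], edges = edges)
      if (length(loops) == 0) next
      d2 <- vapply(loops, function(l) sum((l$centroid3d - pts[i, ])^2),
                   numeric(1))
      pts[i, ] <- loops[[which.min(d2)]]$centroid3d
    }
  }

  n_drop <- floor(trim_fraction * nrow(pts))
  if (n_drop > 0) pts <- pts[(n_drop + 1):(nrow(pts) - n_drop), , drop = FALSE]
  if (nrow(pts) < 10L) {
    fc_abort("fewer than 10 centerline points after trimming",
             "femcurve_extraction_error")
  }
  fem_centerline(pts)
}

#' Inscribed-diameter profile along the centerline
#'
#' At every centerline control point, cuts the canal perpendicular to the
#' local tangent and measures twice the radius of the maximum inscribed
#' circle of the cross-section polygon (the largest circle centered
#' anywhere inside the section, found to about 0.01 mm).
#'
#' @param canal_mesh the watertight canal [fem_mesh] the centerline was
#'   extracted from.
#' @param cl a [fem_centerline].
#' @return The centerline with `inscribed_diameter` filled.
#' @export
inscribed_diameter_profile <- function(canal_mesh, cl) {
  stopifnot(inherits(cl, "fem_centerline"))
  n <- nrow(cl$points)
  edges <- mesh_edge_info(canal_mesh)
  diam <- numeric(n)
  for (i in seq_len(n)) {
    sec <- section_at(canal_mesh, cl$points[i, ], cl$tangents[i, ], edges = edges)
    if (sec$area < 1e-6) {
      fc_abort("degenerate cross-section polygon", "femcurve_section_error")
    }
    diam[i] <- 2 * max_inscribed_circle(sec$points2d)$radius
  }
  cl$inscribed_diameter <- diam
  cl
}

#' Isthmus of the canal
#'
#' The control point with the smallest inscribed diameter; ties are broken
#' toward the smallest arc length (most proximal station).
#'
#' @param cl a profiled [fem_centerline].
#' @return List with `index`, `diameter` (mm) and `arc_fraction` (position
#'   along the trimmed centerline in `[0, 1]`).
#' @export
isthmus <- function(cl) {
  stopifnot(inherits(cl, "fem_centerline"))
  if (is.null(cl$inscribed_diameter)) {
    fc_abort("inscribed diameters missing; run inscribed_diameter_profile() first",
             "femcurve_state_error")
  }
  i <- which.min(cl$inscribed_diameter) # which.min takes the first minimum
  list(index = i, diameter = cl$inscribed_diameter[i],
       arc_fraction = cl$arc_length[i] / max(cl$arc_length))
}
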