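# in-plane reference basis of a fitted circle (deterministic, so arc
# fractions are reproducible across runs)
circle_basis <- function(circle) {
  n <- circle$normal
  e1 <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unitize(e1 - sum(e1 * n) * n)
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

#' Angular range of the canal along the fitted circle
#'
#' Projects points (canal mesh vertices or centerline control points) onto
#' the plane of the fitted circle and returns the continuous angular
#' interval they span, as fractions of the full circle in the circle's
#' reference basis. Used to restrict the nail-surrogate torus to the canal
#' region.
#'
#' @param circle a [fem_circle].
#' @param points n x 3 matrix, or a [fem_mesh] / [fem_centerline].
#' @return Numeric `c(lo, hi)` arc fractions (`hi > lo`, possibly spanning
#'   across 0).
#' @export
canal_arc_range <- function(circle, points) {
  if (inherits(points, "fem_mesh")) points <- points$vertices
  if (inherits(points, "fem_centerline")) points <- points$points
  bs <- circle_basis(circle)
  rel <- sweep(as.matrix(points), 2L, circle$center, "-")
  ang <- atan2(as.numeric(rel %*% bs$e2), as.numeric(rel %*% bs$e1))
  # unwrap about the circular mean so the interval is contiguous
  mean_ang <- atan2(mean(sin(ang)), mean(cos(ang)))
  ang <- mean_ang + ((ang - mean_ang + pi) %% (2 * pi)) - pi
  range(ang) / (2 * pi)
}

#' Build the intramedullary-nail surrogate torus
#'
#' Constructs a watertight (partial) torus mesh whose centerline is the
#' fitted canal circle restricted to `arc_range` and whose tube diameter is
#' the isthmus diameter: the geometric surrogate for an anatomically
#' curved intramedullary nail.
#'
#' @param circle a [fem_circle] (the fitted canal circle).
#' @param tube_diameter tube diameter (mm), in `(0, 2 * radius)`.
#' @param arc_range `c(lo, hi)` arc fractions of the full circle
#'   (`hi - lo >= 1` builds the closed torus).
#' @param n_u,n_v segments along the arc and around the tube.
#' @return A `fem_torus` (also a [fem_mesh]) with the generating
#'   parameters attached.
#' @export
build_torus <- function(circle, tube_diameter, arc_range = c(0, 1),
                        n_u = 96L, n_v = 32L) {
  stopifnot(inherits(circle, "fem_circle"))
  if (!is.numeric(tube_diameter) || tube_diameter <= 0 ||
      tube_diameter >= 2 * circle$radius) {
    fc_abort("tube_diameter must lie in (0, 2 * circle radius)",
             "femcurve_parameter_error")
  }
  if (arc_range[2] <= arc_range[1]) {
    fc_abort("arc_range must have hi > lo", "femcurve_parameter_error")
  }
  bs <- circle_basis(circle)
  r_t <- tube_diameter / 2
  closed <- (arc_range[2] - arc_range[1]) >= 1 - 1e-12
  if (closed) arc_range <- c(0, 1)
  u <- if (closed) 2 * pi * (seq_len(n_u) - 1L) / n_u
       else 2 * pi * seq(arc_range[1], arc_range[2], length.out = n_u)
  phi <- 2 * pi * (seq_len(n_v) - 1L) / n_v
  rings <- lapply(u, function(uu) {
    rad_out <- cos(uu) * bs$e1 + sin(uu) * bs$e2
    ctr <- circle$center + circle$radius * rad_out
    sweep(outer(r_t * cos(phi), rad_out) + outer(r_t * sin(phi), circle$normal),
          2L, ctr, "+")
  })
  if (closed) {
    verts <- do.call(rbind, rings)
    idx <- function(i, j) ((i - 1L) %% n_u) * n_v + ((j - 1L) %% n_v) + 1L
    fl <- vector("list", n_u)
    for (i in seq_len(n_u)) {
      j <- seq_len(n_v)
      a <- idx(i, j); b <- idx(i, j + 1L)
      c_ <- idx(i + 1L, j + 1L); d_ <- idx(i + 1L, j)
      fl[[i]] <- rbind(cbind(a, b, c_), cbind(a, c_, d_))
    }
    mesh <- orient_outward(fem_mesh(verts, do.call(rbind, fl)))
  } else {
    cap1 <- circle$center + circle$radius *
      (cos(u[1]) * bs$e1 + sin(u[1]) * bs$e2)
    cap2 <- circle$center + circle$radius *
      (cos(u[n_u]) * bs$e1 + sin(u[n_u]) * bs$e2)
    mesh <- capped_tube_mesh(rings, cap1, cap2)
  }
  structure(mesh, class = c("fem_torus", "fem_mesh"),
            circle = circle, tube_diameter = tube_diameter,
            arc_range = arc_range, n_u = n_u, n_v = n_v)
}

#' Check torus-cortex clearance
#'
#' Samples the torus surface on a quasi-uniform parametric grid of about
#' `n_samples` points and evaluates the signed distance to the canal
#' surface (positive inside the canal). The minimum over samples is the
#' clearance margin of the nail surrogate against the inner cortex;
#' `intersects` is `TRUE` as soon as any sample lies outside the canal.
#'
#' @param torus a `fem_torus` from [build_torus()].
#' @param canal the watertight canal [fem_mesh] in the same frame.
#' @param n_samples approximate number of surface samples.
#' @param centerline optional [fem_centerline]: when given, the worst
#'   location is also reported as `worst_location_canal`, the arc-length
#'   fraction of the nearest centerline station (comparable with
#'   [isthmus()]'s `arc_fraction` regardless of the circle's angular
#'   orientation).
#' @return A `clearance_report`: list with `min_clearance` (mm, signed),
#'   `intersects`, `worst_location` (fraction along the torus arc range),
#'   `worst_location_canal` (if a centerline was given), `arc_range`,
#'   `n_samples`, and the per-station profile (`station_fraction`,
#'   `station_clearance`).
#' @export
check_clearance <- function(torus, canal, n_samples = 20000L,
                            centerline = NULL) {
  stopifnot(inherits(torus, "fem_torus"))
  if (!is_watertight(canal)) {
    fc_abort("canal mesh must be watertight", "femcurve_input_error")
  }
  circle <- attr(torus, "circle")
  r_t <- attr(torus, "tube_diameter") / 2
  arc_range <- attr(torus, "arc_range")
  bs <- circle_basis(circle)
  span <- arc_range[2] - arc_range[1]
  len_u <- 2 * pi * circle$radius * span
  len_v <- 2 * pi * r_t
  n_u <- max(16L, ceiling(sqrt(n_samples * len_u / len_v)))
  n_v <- max(8L, ceiling(n_samples / n_u))
  fr <- seq(0, 1, length.out = n_u)
  u <- 2 * pi * (arc_range[1] + fr * span)
  phi <- 2 * pi * (seq_len(n_v) - 1L) / n_v
  pts <- matrix(0, n_u * n_v, 3)
  for (i in seq_len(n_u)) {
    rad_out <- cos(u[i]) * bs$e1 + sin(u[i]) * bs$e2
    ctr <- circle$center + circle$radius * rad_out
    pts[(i - 1L) * n_v + seq_len(n_v), ] <-
      sweep(outer(r_t * cos(phi), rad_out) +
              outer(r_t * sin(phi), circle$normal), 2L, ctr, "+")
  }
  sd_ <- signed_distance(pts, canal)
  worst <- which.min(sd_)
  station <- (worst - 1L) %/% n_v + 1L
  station_min <- vapply(seq_len(n_u), function(i) {
    min(sd_[(i - 1L) * n_v + seq_len(n_v)])
  }, numeric(1))
  worst_canal <- NA_real_
  if (!is.null(centerline)) {
    d2 <- rowSums(sweep(centerline$points, 2L, pts[worst, ], "-")^2)
    worst_canal <- centerline$arc_length[which.min(d2)] /
      max(centerline$arc_length)
  }
  structure(list(
    min_clearance = sd_[worst],
    intersects = sd_[worst] < 0,
    worst_location = fr[station],
    worst_location_canal = worst_canal,
    arc_range = arc_range,
    n_samples = n_u * n_v,
    station_fraction = fr,
    station_clearance = station_min
  ), class = "clearance_report")
}

#' @export
print.clearance_report <- function(x, ...) {
  cat(sprintf("<clearance_report> min clearance %.3f mm (%s) at arc fraction %.3f\n",
              x$min_clearance,
              if (x$intersects) "INTERSECTS cortex" else "clear",
              x$worst_location))
  invisible(x)
}

#' @export
tidy.clearance_report <- function(x, ...) {
  tibble::tibble(station_fraction = x$station_fraction,
                 clearance_mm = x$station_clearance)
}

#' @export
autoplot.clearance_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$station_fraction,
                                   y = .data$clearance_mm)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "red") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "arc fraction along torus", y = "clearance (mm)",
                  title = sprintf("Nail-surrogate clearance (min %.2f mm)",
                                  object$min_clearance))
}
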