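test_that("plane fitting recovers exact and noisy planes, rejects lines", {
  set.seed(1)
  pts <- cbind(runif(50, -5, 5), runif(50, -5, 5), 3)
  pl <- fit_plane(pts)
  expect_equal(abs(pl$normal[3]), 1, tolerance = 1e-12)
  expect_equal(pl$centroid[3], 3)
  # sign convention: medial (+x) component of the normal is >= 0
  tilted <- cbind(runif(50, -5, 5), runif(50, -5, 5))
  tilted <- cbind(tilted[, 1], tilted[, 2], -0.3 * tilted[, 1])
  expect_gte(fit_plane(tilted)$normal[1], 0)

  set.seed(2)
  noisy <- cbind(runif(100, -10, 10), runif(100, -10, 10), rnorm(100, 0, 0.1))
  ang <- acos(abs(fit_plane(noisy)$normal[3])) * 180 / pi
  expect_lt(ang, 1)
  expect_error(fit_plane(cbind(1:3, 1:3, 1:3)),
               class = "femcurve_degeneracy_error")
})

test_that("circle fit is exact on circumcircles and tilted arcs", {
  tri <- rbind(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0))
  fit <- fit_circle_3d(tri)
  expect_equal(fit$center, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(fit$radius, 1, tolerance = 1e-12)
  expect_equal(abs(fit$normal[3]), 1, tolerance = 1e-12)
  expect_lt(fit$rmse, 1e-12)

  # 25 exact points on a 25-degree arc of radius 1000 in a tilted plane
  th <- seq(-12.5, 12.5, length.out = 25) * pi / 180
  arc <- cbind(1000 * cos(th), 1000 * sin(th), 0)
  arc_t <- apply_transform(random_rigid_transform(5), arc)
  fit <- fit_circle_3d(arc_t)
  expect_equal(fit$radius, 1000, tolerance = 1e-9)
  expect_lt(fit$rmse, 1e-8)
})

test_that("geometric refinement matches a multi-start brute-force minimizer", {
  th <- seq(-12.5, 12.5, length.out = 25) * pi / 180
  for (s in 1:5) {
    set.seed(s)
    arc <- cbind(1000 * cos(th), 1000 * sin(th), 0)
    arc <- apply_transform(random_rigid_transform(400 + s), arc) +
      matrix(rnorm(75, 0, 0.5), 25, 3)
    fit <- fit_circle_3d(arc)
    r_brute <- brute_circle_radius(inplane_coords(arc), n_starts = 60,
                                   seed = s)
    expect_equal(fit$radius, r_brute, tolerance = 1e-3)
  }
})

test_that("circle fit is rigid-motion equivariant and scale-covariant", {
  set.seed(9)
  th <- seq(-0.3, 0.3, length.out = 30)
  arc <- cbind(500 * cos(th), 500 * sin(th), 0) + matrix(rnorm(90, 0, 0.2), 30, 3)
  f0 <- fit_circle_3d(arc)
  tr <- random_rigid_transform(11)
  f1 <- fit_circle_3d(apply_transform(tr, arc))
  expect_equal(f1$radius, f0$radius, tolerance = 1e-9)
  expect_equal(f1$center,
               as.numeric(apply_transform(tr, matrix(f0$center, 1, 3))),
               tolerance = 1e-6)
  f2 <- fit_circle_3d(arc * 3.5)
  expect_equal(f2$radius, 3.5 * f0$radius, tolerance = 1e-9)
})

test_that("orthographic projections drop the expected coordinate", {
  expect_equal(project_points(matrix(c(3, 4, 5), 1, 3), "sagittal"),
               matrix(c(4, 5), 1, 2))
  expect_equal(project_points(matrix(c(3, 4, 5), 1, 3), "coronal"),
               matrix(c(3, 5), 1, 2))
  # pure anterior bow: sagittal projection is the circle itself,
  # coronal projection collapses to a line
  p <- femur_params(banking = 90, R_curvature = 1000)
  arc <- make_canal_arc(p, 9)
  sag <- project_points(arc, "sagittal")
  expect_equal(circumradius_3d(cbind(sag, 0)[c(1, 5, 9), ]), 1000,
               tolerance = 1e-6)
  cor_ <- project_points(arc, "coronal")
  expect_lt(max(abs(cor_[, 1] - cor_[1, 1])), 1e-9)
})

test_that("closed-form apex radii match numeric curvature of projected arcs", {
  expect_equal(apex_projected_radius(1000, 90, "sagittal"), 1000)
  expect_identical(apex_projected_radius(1000, 90, "coronal"), Inf)
  expect_equal(apex_projected_radius(1000, 60, "sagittal"), 1154.70,
               tolerance = 1e-5)
  expect_equal(apex_projected_radius(1000, 60, "coronal"), 2000,
               tolerance = 1e-9)
  expect_error(apex_projected_radius(1000, 190), class = "femcurve_parameter_error")

  # numeric curvature oracle on densely projected 4-degree arcs
  for (b in c(60, 75, 110)) {
    p <- femur_params(R_curvature = 1000, banking = b, arc_span = 4)
    arc <- make_canal_arc(p, 400)
    for (pl in c("sagittal", "coronal")) {
      pr <- project_points(arc, pl)
      fit <- fit_circle_3d(cbind(pr, 0))
      expect_equal(fit$radius, apex_projected_radius(1000, b, pl),
                   tolerance = 0.002)
    }
  }
})

test_that("coronal apex radius is monotone on either side of 90 degrees", {
  lo <- vapply(seq(20, 88, by = 4), apex_projected_radius, numeric(1),
               R = 1000, plane = "coronal")
  hi <- vapply(seq(92, 160, by = 4), apex_projected_radius, numeric(1),
               R = 1000, plane = "coronal")
  expect_true(all(diff(lo) > 0))
  expect_true(all(diff(hi) < 0))
})

test_that("span-induced bias of fitted projected radii grows monotonically", {
  errs <- vapply(c(10, 25, 40), function(span) {
    p <- femur_params(R_curvature = 1000, banking = 60, arc_span = span,
                      length_total = 800)
    pr <- project_points(make_canal_arc(p, 300), "coronal")
    abs(fit_circle_3d(cbind(pr, 0))$radius -
          apex_projected_radius(1000, 60, "coronal")) /
      apex_projected_radius(1000, 60, "coronal")
  }, numeric(1))
  expect_lt(errs[1], 0.01)
  expect_true(all(diff(errs) > 0))
})
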