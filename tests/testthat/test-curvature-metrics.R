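# banking from an analytic arc generated at a known angle, via the public
# arc generator (no mesh needed)
banking_of_arc <- function(beta, side = "left", apex_offset = 0) {
  p <- femur_params(banking = beta, apex_offset = apex_offset,
                    side = side)
  arc <- make_canal_arc(p, 41)
  cl <- fem_centerline(arc)
  banking_angle(fit_circle_3d(arc), cl, side)
}

test_that("banking angle follows the opening-direction convention", {
  expect_equal(banking_of_arc(90), 90, tolerance = 1e-9)
  expect_equal(banking_of_arc(0), 0, tolerance = 1e-9)
  expect_equal(banking_of_arc(180), 180, tolerance = 1e-9)
  expect_equal(banking_of_arc(64.16), 64.16, tolerance = 1e-9)
  # apex position along the arc does not change the angle
  expect_equal(banking_of_arc(110, apex_offset = 0.3), 110, tolerance = 1e-9)
  # side-consistency: mirrored femurs report the same angle
  expect_equal(banking_of_arc(75, side = "right"), banking_of_arc(75),
               tolerance = 0.1)
})

test_that("a degenerate transverse apex raises a degeneracy error", {
  # a bow whose apex points purely along z has no transverse component
  x <- seq(0, 100, length.out = 21)
  pts <- cbind(x, 0, 10 * (1 - ((x - 50) / 50)^2))
  cl <- fem_centerline(pts)
  expect_error(banking_angle(fit_circle_3d(pts), cl, "left"),
               class = "femcurve_degeneracy_error")
})

test_that("measure_femur recovers ground truth end to end", {
  p <- femur_params(R_curvature = 1000, banking = 95, canal_radius_min = 5,
                    canal_radius_max = 7, length_total = 430)
  fem <- make_femur_meshes(p)
  rec <- measure_femur(fem$cortex, fem$canal, side = "left")
  expect_equal(rec$rfc, 1000, tolerance = 0.005 * 1000)
  expect_equal(rec$banking, 95, tolerance = 0.5)
  expect_equal(rec$isthmus_diameter, 10, tolerance = 0.1)
  expect_equal(rec$femoral_length, 430, tolerance = 0.5)
  df <- tidy(rec)
  expect_s3_class(df, "tbl_df")
  expect_equal(nrow(df), 1L)
  expect_equal(df$rfc_mm, rec$rfc)

  # pre-rotated input gives the identical record
  tr <- random_rigid_transform(55)
  rec2 <- measure_femur(apply_transform(tr, fem$cortex),
                        apply_transform(tr, fem$canal), side = "left")
  expect_equal(rec2$rfc, rec$rfc, tolerance = 1e-6)
  expect_equal(rec2$banking, rec$banking, tolerance = 1e-4)
  expect_equal(rec2$isthmus_diameter, rec$isthmus_diameter, tolerance = 1e-4)
  expect_equal(rec2$femoral_length, rec$femoral_length, tolerance = 1e-4)
})

test_that("the scenario with banking 93.66 degrees is reproduced", {
  p <- femur_params(banking = 93.66)
  fem <- make_femur_meshes(p)
  rec <- measure_femur(fem$cortex, fem$canal, side = "left")
  expect_equal(rec$banking, 93.66, tolerance = 0.5)
})

test_that("three-section radii equal the 3D radius for a pure anterior bow", {
  p <- femur_params(R_curvature = 1000, banking = 90, apex_offset = 0)
  cl <- fem_centerline(make_canal_arc(p, 101))
  r3 <- three_section_radii(cl)
  expect_equal(unname(r3), rep(1000, 3), tolerance = 1)
  # coronal projection of the same bow is collinear: infinite radii
  rc <- three_section_radii(cl, plane = "coronal")
  expect_true(all(is.infinite(rc)))
})

test_that("three-section radii match a high-resolution projection oracle", {
  p <- femur_params(R_curvature = 1000, banking = 120, apex_offset = 0.3,
                    arc_span = 25, length_total = 520)
  cl <- fem_centerline(make_canal_arc(p, 101))
  got <- three_section_radii(cl)
  # oracle: same construction from the analytically projected arc sampled
  # two orders of magnitude more densely
  fine <- project_points(make_canal_arc(p, 10001), "sagittal")
  seg <- sqrt(rowSums((fine[-1, ] - fine[-nrow(fine), ])^2))
  s <- c(0, cumsum(seg))
  pts <- t(vapply((0:6) / 6 * max(s), function(tt) {
    i <- max(1, findInterval(tt, s, rightmost.closed = TRUE))
    i <- min(i, length(s) - 1)
    w <- (tt - s[i]) / (s[i + 1] - s[i])
    (1 - w) * fine[i, ] + w * fine[i + 1, ]
  }, numeric(2)))
  oracle <- c(circumradius_3d(cbind(pts[1:3, ], 0)),
              circumradius_3d(cbind(pts[3:5, ], 0)),
              circumradius_3d(cbind(pts[5:7, ], 0)))
  expect_equal(unname(got), oracle, tolerance = 0.005)
})

test_that("sagittal section radii converge to R as banking approaches 90", {
  errs <- vapply(c(80, 85, 89, 90), function(b) {
    p <- femur_params(R_curvature = 1000, banking = b)
    cl <- fem_centerline(make_canal_arc(p, 101))
    max(abs(three_section_radii(cl) - 1000)) / 1000
  }, numeric(1))
  expect_true(all(diff(errs[1:3]) < 0))
  # at 90 the projection is the circle itself; the residual reflects only
  # the polyline interpolation of the sampled centerline
  expect_lt(errs[4], 1e-3)
})

test_that("section bounds are validated", {
  p <- femur_params()
  cl <- fem_centerline(make_canal_arc(p, 51))
  expect_error(three_section_radii(cl, bounds = c(0.8, 0.2)),
               class = "femcurve_parameter_error")
})
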