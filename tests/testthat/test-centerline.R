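test_that("a straight cylinder yields a centerline on its axis", {
  cyl <- cylinder_mesh(radius = 5, length = 100)
  cl <- extract_centerline(cyl, n_slices = 40)
  expect_lt(max(abs(cl$points[, 1:2])), 1e-6)
  expect_true(all(diff(cl$arc_length) > 0))
  expect_gte(nrow(cl$points), 10)
})

test_that("non-watertight input is rejected", {
  cyl <- cylinder_mesh()
  open_mesh <- fem_mesh(cyl$vertices, cyl$faces[-1, ])
  expect_error(extract_centerline(open_mesh), class = "femcurve_input_error")
})

test_that("the synthetic canal centerline tracks the analytic arc", {
  p <- femur_params(R_curvature = 1000, banking = 90, canal_radius_min = 6,
                    canal_radius_max = 6)
  fem <- make_femur_meshes(p)
  cl <- extract_centerline(fem$canal, orient = c(0, 0, 1))
  arc <- fem$truth$arc
  rel <- sweep(cl$points, 2L, arc$center)
  inplane <- sqrt(as.numeric(rel %*% arc$apex_dir)^2 +
                    as.numeric(rel %*% arc$axis)^2)
  offplane <- as.numeric(rel %*% arc$normal)
  dev <- sqrt((inplane - arc$radius)^2 + offplane^2)
  expect_lt(max(dev), 0.1)
  # consecutive spacing has no gaps
  expect_lt(max(diff(cl$arc_length)), 2 * median(diff(cl$arc_length)))
})

test_that("cross-sections have the analytic area for straight and oblique cuts", {
  cyl <- cylinder_mesh(radius = 5, length = 100, n_c = 96L)
  sec <- section_at(cyl, c(0, 0, 50), c(0, 0, 1))
  expect_equal(sec$area, pi * 25, tolerance = 0.01)
  sec45 <- section_at(cyl, c(0, 0, 50), c(0, 1, 1) / sqrt(2))
  expect_equal(sec45$area, pi * 25 * sqrt(2), tolerance = 0.01)
  expect_error(section_at(cyl, c(0, 0, 500), c(0, 0, 1)),
               class = "femcurve_section_error")
})

test_that("inscribed diameters match analytic sections", {
  cyl <- cylinder_mesh(radius = 5, length = 60, n_c = 64L, n_a = 15L)
  cl <- extract_centerline(cyl, n_slices = 20, trim_fraction = 0.1)
  cl <- inscribed_diameter_profile(cyl, cl)
  expect_equal(cl$inscribed_diameter, rep(10, length(cl$inscribed_diameter)),
               tolerance = 0.005)
  # elliptical tube: inscribed circle is bounded by the minor axis
  ell <- elliptical_tube_mesh(a = 6, b = 4)
  cle <- extract_centerline(ell, n_slices = 20, trim_fraction = 0.1)
  cle <- inscribed_diameter_profile(ell, cle)
  expect_equal(median(cle$inscribed_diameter), 8, tolerance = 0.1)
})

test_that("the isthmus is found at the right location and diameter", {
  p <- femur_params(canal_radius_min = 3.6, canal_radius_max = 5.04,
                    isthmus_frac = 0.6)
  fem <- make_femur_meshes(p)
  cl <- extract_centerline(fem$canal, orient = c(0, 0, 1))
  cl <- inscribed_diameter_profile(fem$canal, cl)
  isth <- isthmus(cl)
  expect_equal(isth$diameter, 7.2, tolerance = 0.1)
  # trimmed centerline covers arc fractions [trim, 1 - trim]
  trim <- 0.10
  expected_frac <- (0.6 - trim) / (1 - 2 * trim)
  station <- 1 / length(cl$inscribed_diameter)
  expect_equal(isth$arc_fraction, expected_frac, tolerance = 2 * station)
})

test_that("isthmus ties break toward the most proximal station", {
  pts <- cbind(0, 0, seq(100, 0, length.out = 5))
  cl <- fem_centerline(pts, inscribed_diameter = c(10, 8, 7.2, 8.5, 9))
  expect_equal(isthmus(cl)$index, 3L)
  expect_equal(isthmus(cl)$diameter, 7.2)
  cl2 <- fem_centerline(pts[1:3, ], inscribed_diameter = c(9, 9, 9))
  expect_equal(isthmus(cl2)$index, 1L)
  expect_error(isthmus(fem_centerline(pts)), class = "femcurve_state_error")
})

test_that("extraction is rigid-motion equivariant", {
  p <- femur_params(isthmus_frac = 0.6)
  fem <- make_femur_meshes(p)
  cl0 <- extract_centerline(fem$canal, n_slices = 48)
  tr <- random_rigid_transform(77)
  cl1 <- extract_centerline(apply_transform(tr, fem$canal), n_slices = 48)
  expect_equal(cl1$points, apply_transform(tr, cl0)$points, tolerance = 1e-6)
})

test_that("isthmus diameter is stable under trimming and slice density", {
  fem <- default_femur()
  d <- vapply(c(0.05, 0.15), function(tf) {
    cl <- extract_centerline(fem$canal, n_slices = 64, trim_fraction = tf,
                             orient = c(0, 0, 1))
    cl <- inscribed_diameter_profile(fem$canal, cl)
    isthmus(cl)$diameter
  }, numeric(1))
  expect_lt(abs(diff(d)), 0.05)
  # doubling slices changes the downstream fitted radius by < 0.2%
  r <- vapply(c(48, 96), function(ns) {
    cl <- extract_centerline(fem$canal, n_slices = ns, orient = c(0, 0, 1))
    fit_circle_3d(cl$points)$radius
  }, numeric(1))
  expect_lt(abs(diff(r)) / r[2], 0.002)
})
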