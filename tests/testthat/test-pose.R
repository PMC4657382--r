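test_that("a slightly tilted box settles exactly flat", {
  m <- box_mesh(40, 20, 60)
  tilt <- femcurve:::rotation_axis_angle(c(1, 0, 0), 5 * pi / 180)
  mt <- apply_transform(rigid_transform(tilt, c(0, 3, 0)), m)
  tr <- settle_on_plane(mt, down = c(0, -1, 0))
  v <- apply_transform(tr, mt)$vertices
  expect_equal(min(v[, 2]), 0, tolerance = 1e-9)
  expect_equal(sum(v[, 2] < 1e-9), 4L) # a full face in contact
})

test_that("a sphere settles with a single-point-contact flag", {
  s <- sphere_mesh(radius = 10, center = c(0, 5, 0), levels = 4L)
  expect_warning(tr <- settle_on_plane(s, down = c(0, -1, 0)),
                 "single-point")
  expect_true(attr(tr, "single_point_contact"))
})

test_that("randomly posed femurs settle onto the posterior landmarks", {
  fem <- default_femur()
  lm_post <- fem$truth$landmarks$posterior
  lm_dist <- fem$truth$landmarks$distal
  for (s in c(21, 22, 23)) {
    tr <- random_rigid_transform(s)
    posed <- apply_transform(tr, fem$cortex)
    res <- standardize(posed)
    back <- compose_transform(res$transform, tr)
    expect_lt(max(abs(apply_transform(back, lm_post)[, 2])), 1e-3)
    expect_lt(max(abs(apply_transform(back, lm_dist)[, 3])), 1e-3)
    # full pose recovery: composite transform is the identity
    expect_lt(femcurve:::rotation_angle(back$rotation) * 180 / pi, 0.2)
    expect_lt(sqrt(sum(back$translation^2)), 0.5)
  }
})

test_that("sliding to the axial plate is the identity on standardized femurs", {
  fem <- default_femur()
  tr <- slide_to_axial(fem$cortex)
  expect_lt(femcurve:::rotation_angle(tr$rotation), 1e-6)
  expect_lt(max(abs(tr$translation)), 1e-6)

  # re-rotated 7 degrees about y: both distal landmarks return to z = 0
  rot7 <- femcurve:::rotation_axis_angle(c(0, 1, 0), 7 * pi / 180)
  posed <- apply_transform(rigid_transform(rot7), fem$cortex)
  tr2 <- slide_to_axial(posed)
  lm <- apply_transform(tr2, apply_transform(rigid_transform(rot7),
                                             fem$truth$landmarks$distal))
  expect_lt(max(abs(lm[, 3])), 1e-3)
})

test_that("a mesh without a two-point distal contact raises a contact error", {
  s <- sphere_mesh(radius = 4, center = c(0, 4, 0))
  expect_error(slide_to_axial(s), class = "femcurve_contact_error")
  # unsettled input is rejected too
  fem <- default_femur()
  low <- apply_transform(rigid_transform(diag(3), c(0, -5, 0)), fem$cortex)
  expect_error(slide_to_axial(low), class = "femcurve_state_error")
})

test_that("standardization is idempotent and carries extras consistently", {
  fem <- default_femur()
  res <- standardize(fem$cortex, list(canal = fem$canal))
  expect_lt(femcurve:::rotation_angle(res$transform$rotation) * 180 / pi, 1e-6)
  # the transformed canal stays inside the cortex
  cl_pts <- ground_truth_arc(fem$truth, seq(0.1, 0.9, length.out = 15))
  d <- signed_distance(apply_transform(res$transform, cl_pts), res$cortex)
  expect_true(all(d > 0))
})

test_that("femoral length equals the axial extent", {
  fem <- default_femur()
  res <- standardize(fem$cortex)
  expect_equal(femoral_length(res$cortex), 428.07, tolerance = 0.5)
  s <- sphere_mesh(radius = 10, center = c(0, 0, 10), levels = 4L)
  expect_equal(femoral_length(s), 20, tolerance = 0.01)
  shifted <- apply_transform(rigid_transform(diag(3), c(0, 0, -5)), s)
  expect_error(femoral_length(shifted), class = "femcurve_state_error")
})

test_that("the bow apex direction points anterior in any pose", {
  fem <- default_femur()
  d0 <- bow_apex_direction(fem$cortex)
  b <- femur_params()$banking * pi / 180
  expect_gt(sum(d0 * c(cos(b), sin(b), 0)), 0.97)
  tr <- random_rigid_transform(31)
  d1 <- bow_apex_direction(apply_transform(tr, fem$cortex))
  expect_equal(as.numeric(tr$rotation %*% d0), d1, tolerance = 1e-6)
  expect_error(bow_apex_direction(cylinder_mesh()),
               class = "femcurve_degeneracy_error")
})
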