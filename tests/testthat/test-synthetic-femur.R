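test_that("parameter validation rejects inconsistent femur specifications", {
  expect_error(femur_params(R_curvature = -1), class = "femcurve_parameter_error")
  expect_error(femur_params(banking = 200), class = "femcurve_parameter_error")
  expect_error(femur_params(canal_radius_min = 8, canal_radius_max = 5),
               class = "femcurve_parameter_error")
  expect_error(femur_params(arc_span = 95), class = "femcurve_parameter_error")
  # chord longer than the bone
  expect_error(femur_params(R_curvature = 2000, arc_span = 30, length_total = 400),
               class = "femcurve_parameter_error")
  expect_error(femur_params(mesh_resolution = c(circumferential = 10, axial = 110)),
               class = "femcurve_parameter_error")
})

test_that("canal arc lies in the plane dictated by the banking angle", {
  p90 <- femur_params(R_curvature = 1000, banking = 90, arc_span = 24)
  a90 <- make_canal_arc(p90, 7)
  expect_equal(max(abs(a90[, 1])), 0) # pure anterior bow: no medial-lateral
  p0 <- femur_params(R_curvature = 1000, banking = 0, arc_span = 24)
  a0 <- make_canal_arc(p0, 7)
  expect_equal(max(abs(a0[, 2])), 0)  # coronal-plane bow: no anterior-posterior
  expect_equal(circumradius_3d(a90[c(1, 4, 7), ]), 1000, tolerance = 1e-9)
})

test_that("arc points sit exactly on the circle for cohort-mean parameters", {
  p <- femur_params(R_curvature = 971.44, banking = 93.48, arc_span = 25,
                    length_total = 500)
  arc <- make_canal_arc(p, 25)
  r <- circumradius_3d(arc[c(2, 13, 24), ])
  ctr <- colMeans(arc) # not the center; use analytic instead
  # distance of every point from the circumcenter of any 3 points
  a <- arc[1, ]; b <- arc[12, ]; c_ <- arc[25, ]
  ab <- b - a; ac <- c_ - a
  cr <- c(ab[2] * ac[3] - ab[3] * ac[2], ab[3] * ac[1] - ab[1] * ac[3],
          ab[1] * ac[2] - ab[2] * ac[1])
  u <- sum(ac^2) * (sum(ab^2) * ac - sum(ab * ac) * ab)
  w <- sum(ab^2) * (sum(ac^2) * ab - sum(ab * ac) * ac)
  center <- a + (u + w) / (2 * sum(cr^2))
  d <- sqrt(rowSums(sweep(arc, 2L, center)^2))
  expect_equal(max(abs(d - 971.44)), 0, tolerance = 1e-9)
  expect_equal(r, 971.44, tolerance = 1e-9)
})

test_that("generated meshes are watertight, nested, and carry exact truth", {
  fem <- default_femur()
  expect_true(is_watertight(fem$cortex))
  expect_true(is_watertight(fem$canal))
  expect_lt(mesh_volume(fem$canal), mesh_volume(fem$cortex))
  expect_equal(fem$truth$femoral_length, 428.07)
  expect_equal(fem$truth$isthmus_diameter, 10.5)
  # landmark planes are exact
  expect_equal(fem$truth$landmarks$posterior[, 2], rep(0, 3))
  expect_equal(fem$truth$landmarks$distal[, 3], rep(0, 2))
  expect_equal(mean(fem$truth$landmarks$distal[, 1]), 0, tolerance = 1e-9)
  expect_equal(max(fem$cortex$vertices[, 3]), 428.07)
  # the isthmus truth follows the radius profile: min radius 3.6 gives 7.20
  fem72 <- make_femur_meshes(femur_params(canal_radius_min = 3.6,
                                          canal_radius_max = 5.04))
  expect_equal(fem72$truth$isthmus_diameter, 7.2)
})

test_that("every canal vertex lies at the profile radius from the arc", {
  fem <- default_femur()
  p <- femur_params()
  n_c <- p$mesh_resolution[["circumferential"]]
  n_a <- p$mesh_resolution[["axial"]]
  t_st <- seq(0, 1, length.out = n_a)
  arc <- ground_truth_arc(fem$truth, t_st)
  r_t <- femcurve:::canal_radius_profile(t_st, p)
  worst <- 0
  for (i in seq_len(n_a)) {
    ring <- fem$canal$vertices[(i - 1) * n_c + seq_len(n_c), , drop = FALSE]
    d <- sqrt(rowSums(sweep(ring, 2L, arc[i, ])^2))
    worst <- max(worst, max(abs(d - r_t[i])))
  }
  expect_lt(worst, 1e-6)
})

test_that("left and right femurs are exact mirror images", {
  pl <- femur_params(side = "left")
  pr <- femur_params(side = "right")
  left <- make_femur_meshes(pl)
  right <- make_femur_meshes(pr)
  for (part in c("cortex", "canal")) {
    vl <- left[[part]]$vertices
    vr <- right[[part]]$vertices
    expect_equal(vr[, 1], -vl[, 1], tolerance = 1e-9)
    expect_equal(vr[, 2:3], vl[, 2:3], tolerance = 1e-9)
    expect_true(is_watertight(right[[part]]))
  }
  expect_equal(right$truth$banking, left$truth$banking)
})

test_that("cohort simulation is deterministic and exact at zero noise", {
  t1 <- make_cohort_table(30, seed = 213L)
  t2 <- make_cohort_table(30, seed = 213L)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 60L)
  expect_setequal(unique(t1$laterality), c(0L, 1L))

  t0 <- make_cohort_table(50, noise_sd = c(length = 0, banking = 0,
                                           rfc = 0, isthmus = 0),
                          seed = 7L)
  cf <- cohort_default_coefficients()$rfc
  pred <- cf[["intercept"]] + cf[["length"]] * t0$length_mm +
    cf[["banking"]] * t0$banking_deg + cf[["laterality"]] * t0$laterality +
    cf[["gender"]] * t0$gender
  expect_equal(t0$rfc_mm, pred)
  expect_error(make_cohort_table(50, noise_sd = c(rfc = -1)),
               class = "femcurve_parameter_error")
  expect_error(make_cohort_table(5), class = "femcurve_parameter_error")
})

test_that("OLS on simulated cohorts recovers the length coefficient", {
  hits <- 0L
  n_rep <- 200L
  for (r in seq_len(n_rep)) {
    tab <- make_cohort_table(500, seed = 10000L + r)
    fit <- lm(rfc_mm ~ length_mm + banking_deg + laterality + gender,
              data = tab)
    ci <- confint(fit)["length_mm", ]
    hits <- hits + (ci[1] <= 2.23 && 2.23 <= ci[2])
  }
  expect_gte(hits / n_rep, 0.93)
})
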