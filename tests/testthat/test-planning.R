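test_that("single sharp beam with no attenuation paints the swept cylinder", {
  target <- sphere_mask(24, 4, 20)
  body <- toy_mask(24, 4)
  spec <- plan_spec(target, prescription_Gy = 10, gantry_angles_deg = 0,
                    aperture_margin_mm = 0, penumbra_sigma_mm = 0,
                    attenuation_per_cm = 0)
  dose <- compute_plan_dose(spec, body)
  # target voxels project inside their own aperture: full prescription
  expect_true(all(abs(dose$data[target$data] - 10) < 1e-9))
  # far off-axis (outside the projected cylinder): zero
  P <- grid_coords(target)
  lateral <- sqrt(P[, 1]^2 + P[, 3]^2)
  expect_true(all(dose$data[lateral > 35] < 1e-9))
  # on-axis behind the target (inside the swept cylinder): full prescription
  behind <- lateral < 10 & abs(P[, 2]) > 30
  expect_true(all(abs(dose$data[behind] - 10) < 1e-9))
})

test_that("dose operator is linear in prescription and peaks on target", {
  ph <- coarse_phantom()
  ptv <- expand_margin(ph$masks[[1]]$gtv, 5)
  body <- ph$masks[[1]]$body
  d1 <- compute_plan_dose(plan_spec(ptv, prescription_Gy = 25), body)
  d2 <- compute_plan_dose(plan_spec(ptv, prescription_Gy = 50), body)
  expect_equal(d2$data, 2 * d1$data, tolerance = 1e-12)
  expect_true(all(d1$data >= 0))

  # centre of a five-field crossfire beats any point 5 cm off-axis
  ctr <- mask_centroid(ph$masks[[1]]$gtv)
  at <- function(p) sample_grid(d2, matrix(p, 1))
  centre <- at(ctr)
  for (off in list(c(50, 0, 0), c(0, 50, 0), c(-50, 35, 0)))
    expect_gte(centre, at(ctr + off))
})

test_that("empty targets and bad parameters are rejected", {
  empty <- toy_mask(8, 2, function(P) rep(FALSE, nrow(P)))
  body <- toy_mask(8, 2)
  expect_error(compute_plan_dose(plan_spec(empty), body), "empty")
  expect_error(plan_spec(empty, prescription_Gy = 0), "prescription")
  expect_error(plan_spec(empty, gantry_angles_deg = c(0, 360)), "distinct")
})

test_that("coverage normalization hits the objective exactly", {
  mask <- toy_mask(10, 2)
  # uniform 40 Gy, prescription 50: pure rescale, V50 = 100%
  uni <- toy_grid(40, 10, 2)
  nu <- normalize_to_coverage(uni, mask, 0.95, 50)
  expect_equal(attr(nu, "scale"), 1.25)
  expect_true(all(nu$data >= 50 - 1e-9))

  # linear ramp 0..100: brute-force percentile oracle
  n <- 10^3
  ramp <- voxel_grid(array(seq(0, 100, length.out = n), c(10, 10, 10)),
                     c(2, 2, 2))
  nr <- normalize_to_coverage(ramp, mask, 0.95, 50)
  v <- sort(nr$data, decreasing = TRUE)
  k <- ceiling(0.95 * n)
  expect_equal(v[k], 50)
  expect_gte(mean(nr$data >= 50), 0.95)
  expect_lt(mean(nr$data >= 50 + 1e-6), 0.95 + 1 / n)

  # idempotence and the already-satisfying case
  nn <- normalize_to_coverage(nr, mask, 0.95, 50)
  expect_equal(attr(nn, "scale"), 1)
  expect_error(normalize_to_coverage(toy_grid(0, 10, 2), mask, 0.95, 50),
               "zero")
  expect_error(normalize_to_coverage(uni, mask, 1.2, 50), "coverage")
})

test_that("3D plan: coverage objective, PTV geometry, constraint report", {
  ph <- coarse_phantom()
  p3 <- build_3d_plan(ph)
  expect_gte(mean(p3$dose$data[p3$ptv$data] >= 50), 0.95)
  expect_equal(dose_at_volume(compute_dvh(p3$dose, p3$ptv), 0.95), 50)
  expect_s3_class(p3$report, "data.frame")
  expect_true(all(c("constraint", "limit", "value", "pass") %in%
                    names(p3$report)))

  # merged-target PTV exceeds every per-phase PTV under motion
  p4 <- build_4d_phase_plans(ph)
  per_phase <- vapply(p4$ptvs, mask_volume_cm3, 0)
  expect_gt(mask_volume_cm3(p3$ptv), max(per_phase))
  expect_gt(mask_volume_cm3(p3$ptv), mean(per_phase))
})

test_that("each 4D phase plan meets its phase prescription", {
  ph <- coarse_phantom()
  p4 <- build_4d_phase_plans(ph)
  expect_equal(p4$phase_prescription_Gy, 5)
  for (p in seq_along(p4$doses)) {
    cov <- mean(p4$doses[[p]]$data[p4$ptvs[[p]]$data] >= 5)
    expect_gte(cov, 0.95)
  }
})

test_that("without motion the 3D and summed 4D doses coincide", {
  ph <- generate_phantom(coarse_config(motion_amplitude_mm = c(0, 0, 0)))
  p3 <- build_3d_plan(ph)
  p4 <- build_4d_phase_plans(ph)
  expect_identical(p3$ptv$data, p4$ptvs[[1]]$data)
  s <- Reduce(`+`, lapply(p4$doses, `[[`, "data"))
  expect_lte(max(abs(s - p3$dose$data)), 0.01 * 50)
})
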