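test_that("zero motion collapses all phases onto the reference", {
  cfg <- coarse_config(motion_amplitude_mm = c(0, 0, 0), noise_sd = 0)
  ph <- generate_phantom(cfg)
  for (p in 2:cfg$n_phases) {
    expect_identical(ph$images[[p]]$data, ph$images[[1]]$data)
    expect_identical(ph$masks[[p]]$gtv$data, ph$masks[[1]]$gtv$data)
    expect_equal(max(abs(ph$true_fields[[p]]$u)), 0)
  }
})

test_that("identical seeds give bit-identical phantoms", {
  cfg <- coarse_config(seed = 42)
  a <- generate_phantom(cfg)
  b <- generate_phantom(cfg)
  expect_identical(a$images, b$images)
  expect_identical(a$masks, b$masks)
  expect_identical(a$true_fields, b$true_fields)
  d <- generate_phantom(coarse_config(seed = 43))
  expect_false(identical(a$images, d$images))
})

test_that("GTV centroid follows the cosine trajectory within half a voxel", {
  ph <- default_phantom()
  cfg <- ph$config
  c0 <- mask_centroid(ph$masks[[1]]$gtv)
  for (p in c(2, 4, 6, 9)) {
    shift <- mask_centroid(ph$masks[[p]]$gtv) - c0
    expected <- cfg$motion_amplitude_mm / 2 *
      (cos(2 * pi * (p - 1) / cfg$n_phases) - 1)
    expect_true(all(abs(shift - expected) <= 0.5 * cfg$spacing_mm),
                info = sprintf("phase %d: shift (%s) vs expected (%s)",
                               p - 1, toString(round(shift, 2)),
                               toString(round(expected, 2))))
  }
})

test_that("masks and ground-truth fields are mutually consistent", {
  ph <- default_phantom()
  # warping the phase-5 (largest excursion) GTV back through the true field
  # must reproduce the reference GTV
  gtv5 <- ph$masks[[6]]$gtv
  w <- warp_dose(voxel_grid(array(as.numeric(gtv5$data), dim(gtv5$data)),
                            gtv5$spacing, gtv5$origin), ph$true_fields[[6]])
  warped <- voxel_grid(w$data >= 0.5, w$spacing, w$origin)
  expect_gte(dice(warped, ph$masks[[1]]$gtv), 0.95)
})

test_that("liver volume is stable across phases and fields do not fold", {
  ph <- default_phantom()
  lv <- vapply(ph$masks, function(m) mask_volume_cm3(m$liver), 0)
  expect_lte(diff(range(lv)) / max(lv), 0.10)
  for (p in c(4, 6)) {
    jac <- jacobian_determinant(ph$true_fields[[p]])
    expect_gt(min(jac[ph$masks[[1]]$liver$data]), 0)
  }
})

test_that("folding amplitudes are rejected with a diagnostic", {
  cfg <- coarse_config(motion_amplitude_mm = c(0, 0, 200),
                       motion_sigma_mm = 50)
  expect_error(generate_phantom(cfg), "fold")
})

test_that("config invariants are enforced", {
  expect_error(phantom_config(n_phases = 1), "n_phases")
  expect_error(phantom_config(spacing_mm = c(1, -1, 1)), "spacing")
  expect_error(phantom_config(motion_amplitude_mm = c(-1, 0, 0)), "amplitude")
  expect_error(phantom_config(liver_volume_cm3 = 0), "liver_volume")
})

test_that("ITV union is idempotent, additive on disjoint sets, and grows with motion", {
  m1 <- sphere_mask(16, 2, 6)
  expect_identical(union_itv(rep(list(m1), 10))$data, m1$data)

  m2 <- sphere_mask(16, 2, 6, center = c(14, 0, 0))
  expect_equal(sum(union_itv(list(m1, m2))$data),
               sum(m1$data) + sum(m2$data))

  ph <- coarse_phantom()
  gtvs <- lapply(ph$masks, `[[`, "gtv")
  itv <- union_itv(gtvs)
  for (g in gtvs) expect_gt(sum(itv$data), sum(g$data))

  shifted <- voxel_grid(m1$data, m1$spacing, m1$origin + 1)
  expect_error(union_itv(list(m1, shifted)), "lattice")
})

test_that("margin expansion matches a brute-force distance scan", {
  # single voxel, 5 mm margin, 1 mm isotropic grid
  g <- toy_mask(13, 1, function(P) rowSums(P^2) == 0)
  ex <- expand_margin(g, 5)
  P <- grid_coords(g)
  expect_equal(sum(ex$data), sum(rowSums(P^2) <= 25 + 1e-9))
  expect_identical(expand_margin(g, 0)$data, g$data)
  expect_error(expand_margin(g, -1), "non-negative")

  # anisotropic spacing: brute-force oracle over all voxel pairs
  m <- sphere_mask(10, c(1, 1, 1), 2.5)
  m$spacing <- c(1, 2, 3)
  P <- grid_coords(m)
  inside <- which(m$data)
  d2 <- vapply(seq_len(nrow(P)), function(i) {
    min(colSums((t(P[inside, , drop = FALSE]) - P[i, ])^2))
  }, 0)
  ex <- expand_margin(m, 3.2)
  expect_identical(as.logical(ex$data), d2 <= 3.2^2 + 1e-9)
})

test_that("expanding a sphere approximates the analytic volume at fine spacing", {
  r <- 10; margin <- 5
  m <- sphere_mask(36, 1, r)
  ex <- expand_margin(m, margin)
  analytic <- 4 / 3 * pi * (r + margin)^3 / 1000
  expect_lt(abs(mask_volume_cm3(ex) - analytic) / analytic, 0.05)
})
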