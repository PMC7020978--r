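test_that("normal liver is the liver minus the PTV", {
  liver <- sphere_mask(20, 4, 30)
  ptv <- sphere_mask(20, 4, 12)
  nl <- normal_liver(liver, ptv)
  expect_equal(sum(nl$data), sum(liver$data) - sum(ptv$data))

  far <- sphere_mask(20, 4, 6, center = c(36, 0, 0))
  expect_identical(normal_liver(liver, far)$data & liver$data,
                   normal_liver(liver, far)$data)
  expect_equal(sum(normal_liver(liver, far)$data),
               sum(liver$data) - sum(liver$data & far$data))

  expect_error(normal_liver(ptv, liver), "empty")
})

test_that("phantom liver and normal-liver volumes match the cohort means", {
  ph <- default_phantom()
  p3 <- default_plan3()
  liver <- mask_volume_cm3(ph$masks[[1]]$liver)
  expect_lt(abs(liver - 1177.52) / 1177.52, 0.02)
  nl <- normal_liver(ph$masks[[1]]$liver, p3$ptv)
  expect_lt(abs(mask_volume_cm3(nl) - 1008) / 1008, 0.03)
})

test_that("DVH reproduces uniform and two-level analytic cases", {
  mask <- toy_mask(10, 2)
  uni <- compute_dvh(toy_grid(10, 10, 2), mask)
  expect_equal(dvh_vx(uni, c(5, 10, 15)), c(100, 100, 0))
  m <- dvh_metrics(uni)
  expect_equal(m[["Dmean"]], 10, tolerance = 0.1)
  expect_equal(m[["Dmax"]], 10)

  # half the volume at 40 Gy, half at 0
  half <- array(0, c(10, 10, 10)); half[1:5, , ] <- 40
  hd <- compute_dvh(voxel_grid(half, 2), mask)
  hm <- dvh_metrics(hd)
  expect_equal(hm[["V30"]], 50)
  expect_equal(hm[["Dmax"]], 40)
  expect_equal(hm[["Dmean"]], 20, tolerance = 0.1)
  expect_equal(hd$dmean_Gy, 20)

  expect_error(compute_dvh(toy_grid(1, 10, 2),
                           toy_mask(10, 2, function(P) rep(FALSE, nrow(P)))),
               "empty")
})

test_that("every Vx equals a brute-force voxel count on random grids", {
  set.seed(11)
  for (rep in 1:3) {
    d <- voxel_grid(array(runif(32^3, 0, 60), c(32, 32, 32)), 2)
    mk <- toy_mask(32, 2, function(P) runif(nrow(P)) < 0.4)
    dvh <- compute_dvh(d, mk)
    vals <- d$data[mk$data]
    for (x in seq(5, 40, 5))
      expect_equal(dvh_vx(dvh, x), 100 * mean(vals >= x))
    m <- dvh_metrics(dvh)
    expect_lte(abs(m[["Dmean"]] - mean(vals)), dvh$bin_width_Gy)
    expect_equal(m[["Dmax"]], max(vals))
    # monotone non-increasing in x, and Dmean <= Dmax
    vx <- dvh_vx(dvh, seq(5, 40, 5))
    expect_true(all(diff(vx) <= 0))
    expect_lte(m[["Dmean"]], m[["Dmax"]])
  }
})

test_that("DVH converges under grid refinement", {
  # same analytic dose field sampled at two resolutions
  build <- function(n) {
    g <- voxel_grid(array(0, c(n, n, n)), 48 / n)
    P <- grid_coords(g)
    dose <- 50 * exp(-(P[, 1]^2 + P[, 2]^2 + P[, 3]^2) / (2 * 12^2))
    list(dose = voxel_grid(array(dose, c(n, n, n)), 48 / n, g$origin),
         mask = voxel_grid(array(rowSums(P^2) <= 20^2, c(n, n, n)),
                           48 / n, g$origin))
  }
  lo <- build(32); hi <- build(64)
  vx_lo <- dvh_vx(compute_dvh(lo$dose, lo$mask), seq(5, 40, 5))
  vx_hi <- dvh_vx(compute_dvh(hi$dose, hi$mask), seq(5, 40, 5))
  expect_true(all(abs(vx_lo - vx_hi) <= 1))
})

test_that("dose_at_volume inverts the cumulative curve", {
  mask <- toy_mask(10, 2)
  uni <- compute_dvh(toy_grid(10, 10, 2), mask)
  expect_equal(dose_at_volume(uni, 0.95), 10)
  expect_equal(dose_at_volume(uni, 1), 10)
  ramp <- voxel_grid(array(seq(0, 100, length.out = 1000), c(10, 10, 10)), 2)
  rd <- compute_dvh(ramp, mask)
  d95 <- dose_at_volume(rd, 0.95)
  expect_gte(mean(ramp$data >= d95), 0.95)
  expect_lt(mean(ramp$data >= d95 + 0.1), 0.95)
})

test_that("DVH CSV round-trip preserves the curve", {
  set.seed(3)
  d <- voxel_grid(array(runif(16^3, 0, 55), c(16, 16, 16)), 3)
  mask <- toy_mask(16, 3)
  dvh <- compute_dvh(d, mask, structure = "liver")
  path <- tempfile(fileext = ".csv")
  write_dvh(dvh, path)
  back <- read_dvh(path, structure = "liver")
  expect_equal(back$cum_frac, dvh$cum_frac)
  expect_equal(back$volume_cm3, dvh$volume_cm3, tolerance = 1e-6)
  expect_equal(dvh_vx(back, seq(5, 40, 5)), dvh_vx(dvh, seq(5, 40, 5)))
})
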