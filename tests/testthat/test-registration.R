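test_that("rigid registration recovers identity, translation and rotation", {
  ph <- coarse_phantom()
  fx <- ph$images[[1]]
  P <- grid_coords(fx)

  r0 <- register_rigid(fx, fx)
  expect_lte(sqrt(sum(r0$translation^2)), 0.1)

  # harness moves the anatomy by a known 6 mm S-I shift:
  # mv(x) = fx(x - shift), so the fixed-to-moving map is x + shift
  shift <- c(0, 0, -6)
  mv <- voxel_grid(array(sample_grid(fx, sweep(P, 2, shift, "-"),
                                     clamp = TRUE), dim(fx$data)),
                   fx$spacing, fx$origin)
  r1 <- register_rigid(fx, mv)
  expect_lte(max(abs(r1$translation - shift)), 0.5)

  # harness applies a known 5 degree rotation about S-I
  tr <- dose4d:::rigid_transform(c(0, 0, 0), c(0, 0, -5),
                                 dose4d:::grid_center(fx))
  mv2 <- voxel_grid(array(sample_grid(fx, apply_rigid(tr, P), clamp = TRUE),
                          dim(fx$data)), fx$spacing, fx$origin)
  r2 <- register_rigid(fx, mv2)
  expect_lte(abs(r2$rotation_deg[3] - 5), 1)
})

test_that("rigid registration rejects non-overlapping volumes", {
  a <- toy_grid(1, 8, 2)
  b <- toy_grid(1, 8, 2)
  b$origin <- b$origin + 100
  expect_error(register_rigid(a, b), "overlap")
})

test_that("FFD on identical images stays near the identity", {
  ph <- coarse_phantom()
  fx <- ph$images[[1]]
  f <- register_ffd(fx, fx, ffd_params(max_iterations = 10))
  expect_lte(max(abs(f$u)), 0.2)
})

test_that("FFD recovers the phantom ground-truth field inside the liver", {
  ph <- coarse_phantom()
  fx <- ph$images[[1]]
  liver <- ph$masks[[1]]$liver$data
  f <- register_ffd(fx, ph$images[[4]], ffd_params())
  err <- sqrt(apply((f$u - ph$true_fields[[4]]$u)^2, 1:3, sum))
  expect_lte(mean(err[liver]), 2)
  # and it must be a real improvement over not registering at all
  mag <- sqrt(apply(ph$true_fields[[4]]$u^2, 1:3, sum))
  expect_lt(mean(err[liver]), 0.25 * mean(mag[liver]))
})

test_that("the accepted FFD objective sequence is non-increasing and SSD drops", {
  ph <- coarse_phantom()
  fx <- ph$images[[1]]
  mv <- ph$images[[6]]
  f <- register_ffd(fx, mv, ffd_params())
  traces <- attr(f, "trace")
  expect_gt(sum(lengths(traces)), 1)
  for (tr in traces) if (length(tr) > 1) expect_true(all(diff(tr) <= 0))
  # post-registration SSD <= pre-registration SSD on the full grid
  P <- grid_coords(fx)
  pre <- mean((as.numeric(mv$data) - as.numeric(fx$data))^2)
  warped <- sample_grid(mv, P + matrix(c(f$u), ncol = 3), clamp = TRUE)
  post <- mean((warped - as.numeric(fx$data))^2)
  expect_lte(post, pre)
})

test_that("hitting the iteration cap warns and flags, never fails silently", {
  ph <- coarse_phantom()
  expect_warning(
    f <- register_ffd(ph$images[[1]], ph$images[[6]],
                      ffd_params(max_iterations = 2, convergence_tol = 1e-12)),
    "iteration cap")
  expect_false(attr(f, "converged"))
})

test_that("field inversion: zero, constant, and phantom round-trip cases", {
  z <- disp_field(array(0, c(8, 8, 8, 3)), c(4, 4, 4))
  expect_equal(max(abs(invert_field(z)$u)), 0)

  cu <- array(0, c(8, 8, 8, 3))
  cu[, , , 3] <- 7
  ci <- invert_field(disp_field(cu, c(4, 4, 4)))
  expect_lt(max(abs(ci$u[, , , 3] + 7)), 1e-6)
  expect_lt(max(abs(ci$u[, , , 1:2])), 1e-6)

  ph <- coarse_phantom()
  f <- ph$true_fields[[6]]
  inv <- invert_field(f)
  rt <- compose_fields(inv, f)  # x -> T^-1(T(x)) should be ~identity
  mag <- sqrt(apply(rt$u^2, 1:3, sum))
  expect_lte(mean(mag[ph$masks[[1]]$liver$data]), 0.5)
})

test_that("folding fields are rejected by inversion", {
  n <- 12
  u <- array(0, c(n, n, n, 3))
  # displacement gradient < -1 along x folds the map
  x <- seq(0, n - 1) * 2
  u[, , , 1] <- array(rep(-1.6 * x, times = n * n), c(n, n, n))
  expect_error(invert_field(disp_field(u, c(2, 2, 2))), "fold")
})
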