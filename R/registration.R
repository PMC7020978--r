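# Intensity-based registration
# ----------------------------
# Rigid (6 DOF) initialisation followed by a cubic B-spline free-form
# deformation (FFD) refined coarse-to-fine, both minimising the mean squared
# intensity difference (SSD).  The phantom is mono-modal, so SSD is adequate;
# the metric lives behind one function and could be swapped.  The FFD
# objective carries a bending-energy penalty evaluated on the control
# lattice, which keeps the map smooth and prevents folding at respiratory
# amplitudes.

#' FFD registration parameters
#'
#' @param control_spacing_mm B-spline control point spacing (mm).
#' @param pyramid_levels Number of multiresolution levels (>= 1); level k is
#'   downsampled by `2^(pyramid_levels - k)`.
#' @param max_iterations Gradient-descent iteration cap per level (scalar or
#'   one per level, coarsest first).
#' @param step_size_mm Initial control-point step (mm); adapted by
#'   backtracking so the objective never increases across accepted steps.
#' @param convergence_tol Relative objective decrease below which a level
#'   stops.
#' @param regularization_weight Weight of the bending-energy penalty.
#' @export
ffd_params <- function(control_spacing_mm = 32,
                       pyramid_levels = 3,
                       max_iterations = c(80, 50, 30),
                       step_size_mm = 2,
                       convergence_tol = 1e-4,
                       regularization_weight = 0.05) {
  if (control_spacing_mm <= 0) stop("`control_spacing_mm` must be > 0")
  if (pyramid_levels < 1) stop("`pyramid_levels` must be >= 1")
  if (convergence_tol <= 0) stop("`convergence_tol` must be > 0")
  if (length(max_iterations) == 1L)
    max_iterations <- rep(max_iterations, pyramid_levels)
  if (length(max_iterations) != pyramid_levels)
    stop("`max_iterations` must be scalar or one per level")
  structure(list(control_spacing_mm = control_spacing_mm,
                 pyramid_levels = as.integer(pyramid_levels),
                 max_iterations = as.integer(max_iterations),
                 step_size_mm = step_size_mm,
                 convergence_tol = convergence_tol,
                 regularization_weight = regularization_weight),
            class = "ffd_params")
}

# Block-average downsampling by an integer factor (per-axis extents are
# truncated to a multiple of the factor).
downsample_grid <- function(grid, factor) {
  if (factor == 1L) return(grid)
  d <- dim(grid$data)
  nd <- d %/% factor
  acc <- array(0, nd)
  for (dz in seq_len(factor)) for (dy in seq_len(factor)) for (dx in seq_len(factor))
    acc <- acc + grid$data[seq(dx, by = factor, length.out = nd[1]),
                           seq(dy, by = factor, length.out = nd[2]),
                           seq(dz, by = factor, length.out = nd[3])]
  voxel_grid(acc / factor^3, grid$spacing * factor,
             grid$origin + (factor - 1) / 2 * grid$spacing)
}

#' Rigid transform constructor
#'
#' Maps world point x to `R (x - center) + center + translation`, rotations
#' applied in x-y-z order (degrees).
#'
#' @param translation Length-3 translation (mm).
#' @param rotation_deg Length-3 rotation about x, y, z axes (degrees).
#' @param center Rotation centre (mm).
#' @export
rigid_transform <- function(translation = c(0, 0, 0),
                            rotation_deg = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  structure(list(translation = as.numeric(translation),
                 rotation_deg = as.numeric(rotation_deg),
                 center = as.numeric(center)),
            class = "rigid_transform")
}

rotation_matrix <- function(rotation_deg) {
  r <- rotation_deg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Apply a rigid transform to world points
#' @param transform A [rigid_transform()].
#' @param pts n-by-3 matrix of world mm points.
#' @export
apply_rigid <- function(transform, pts) {
  R <- rotation_matrix(transform$rotation_deg)
  sweep(sweep(pts, 2, transform$center, "-") %*% t(R), 2,
        transform$center + transform$translation, "+")
}

grid_center <- function(grid) grid$origin + (dim(grid$data) - 1) / 2 * grid$spacing

#' Rigid (translation + rotation) SSD registration
#'
#' Estimates the 6-DOF transform mapping fixed-image coordinates to
#' moving-image coordinates by Nelder-Mead minimisation of the mean squared
#' intensity difference on a downsampled lattice.
#'
#' @param fixed,moving `voxel_grid` images with overlapping fields of view.
#' @param max_voxels_per_axis Downsampling target for the optimisation
#'   lattice.
#' @param maxit Nelder-Mead iteration cap.
#' @return A [rigid_transform()] with attribute `ssd` (final objective).
#' @export
register_rigid <- function(fixed, moving, max_voxels_per_axis = 32,
                           maxit = 400) {
  lo_f <- fixed$origin; hi_f <- fixed$origin + (dim(fixed$data) - 1) * fixed$spacing
  lo_m <- moving$origin; hi_m <- moving$origin + (dim(moving$data) - 1) * moving$spacing
  if (any(pmin(hi_f, hi_m) <= pmax(lo_f, lo_m)))
    stop("fixed and moving fields of view do not overlap")
  f <- max(1L, ceiling(max(dim(fixed$data)) / max_voxels_per_axis))
  fx <- downsample_grid(fixed, f)
  mv <- downsample_grid(moving, f)
  P <- grid_coords(fx)
  fvals <- as.numeric(fx$data)
  ctr <- grid_center(fixed)
  obj <- function(par) {
    tr <- rigid_transform(par[1:3], par[4:6], ctr)
    w <- sample_grid(mv, apply_rigid(tr, P), clamp = TRUE)
    mean((w - fvals)^2)
  }
  # translation-only pre-fit stabilises the joint 6-DOF search
  fit0 <- stats::optim(c(0, 0, 0), function(p) obj(c(p, 0, 0, 0)),
                       method = "Nelder-Mead",
                       control = list(maxit = maxit))
  fit <- stats::optim(c(fit0$par, 0, 0, 0), obj, method = "Nelder-Mead",
                      control = list(maxit = maxit,
                                     reltol = 1e-10,
                                     parscale = c(1, 1, 1, 0.5, 0.5, 0.5)))
  out <- rigid_transform(fit$par[1:3], fit$par[4:6], ctr)
  attr(out, "ssd") <- fit$value
  out
}

# Control lattice covering the world extent of a grid with enough margin that
# every domain point has full cubic support.
make_lattice <- function(grid, csp) {
  lo <- grid$origin
  hi <- grid$origin + (dim(grid$data) - 1) * grid$spacing
  nc <- ceiling((hi - lo) / csp) + 4
  list(cdim = as.integer(nc), corigin = lo - csp, cspacing = rep(csp, 3))
}

# Second difference of a 3D array along its first axis.
ax_diff2 <- function(a) {
  n1 <- dim(a)[1]
  a[3:n1, , , drop = FALSE] - 2 * a[2:(n1 - 1), , , drop = FALSE] +
    a[1:(n1 - 2), , , drop = FALSE]
}

# Bending-energy surrogate on the control lattice: sum of squared second
# differences of the coefficients along each axis, averaged per control point.
bending_penalty <- function(coef_mat, cdim) {
  n <- prod(cdim)
  e <- 0
  for (comp in 1:3) {
    a <- array(coef_mat[, comp], cdim)
    e <- e + sum(ax_diff2(a)^2) +
      sum(ax_diff2(aperm(a, c(2, 1, 3)))^2) +
      sum(ax_diff2(aperm(a, c(3, 2, 1)))^2)
  }
  e / n
}

second_diff_grad <- function(a) {
  # gradient of sum(ax_diff2(a)^2) w.r.t. a
  d2 <- ax_diff2(a)
  n1 <- dim(a)[1]
  g <- array(0, dim(a))
  g[seq_len(n1 - 2), , ] <- g[seq_len(n1 - 2), , , drop = FALSE] + 2 * d2
  g[1 + seq_len(n1 - 2), , ] <- g[1 + seq_len(n1 - 2), , , drop = FALSE] - 4 * d2
  g[2 + seq_len(n1 - 2), , ] <- g[2 + seq_len(n1 - 2), , , drop = FALSE] + 2 * d2
  g
}

bending_grad <- function(coef_mat, cdim) {
  n <- prod(cdim)
  out <- matrix(0, n, 3)
  for (comp in 1:3) {
    a <- array(coef_mat[, comp], cdim)
    g <- second_diff_grad(a) +
      aperm(second_diff_grad(aperm(a, c(2, 1, 3))), c(2, 1, 3)) +
      aperm(second_diff_grad(aperm(a, c(3, 2, 1))), c(3, 2, 1))
    out[, comp] <- as.numeric(g) / n
  }
  out
}

# Central-difference gradient volumes (per mm) of an image.
image_gradient <- function(grid) {
  a <- grid$data
  d <- dim(a)
  gr <- vector("list", 3)
  for (ax in 1:3) {
    ip <- im <- a
    idx_hi <- c(2:d[ax], d[ax])
    idx_lo <- c(1, 1:(d[ax] - 1))
    if (ax == 1) { ip <- a[idx_hi, , ]; im <- a[idx_lo, , ] }
    if (ax == 2) { ip <- a[, idx_hi, ]; im <- a[, idx_lo, ] }
    if (ax == 3) { ip <- a[, , idx_hi]; im <- a[, , idx_lo] }
    gr[[ax]] <- voxel_grid((ip - im) / (2 * grid$spacing[ax]),
                           grid$spacing, grid$origin)
  }
  gr
}

#' B-spline free-form deformable registration
#'
#' Coarse-to-fine gradient descent on SSD plus a bending-energy penalty over
#' a cubic B-spline control lattice.  The accepted-objective sequence is
#' non-increasing by construction (backtracking line search).  If an
#' iteration cap is hit before the tolerance, the best-so-far field is
#' returned with attribute `converged = FALSE` and a warning.
#'
#' @param fixed,moving `voxel_grid` images on the same lattice.
#' @param params An [ffd_params()].
#' @param init Optional [rigid_transform()] initialisation (e.g. from
#'   [register_rigid()]); it is composed into the returned field.
#' @return A `disp_field` on the fixed lattice (pull convention), with
#'   attributes `converged`, `objective` (final value) and `trace`.
#' @export
register_ffd <- function(fixed, moving, params = ffd_params(), init = NULL) {
  stopifnot(inherits(params, "ffd_params"))
  if (!is.null(init)) {
    # resample the moving image through the rigid transform once, then
    # compose the transform back into the final field
    P <- grid_coords(fixed)
    mv_r <- voxel_grid(array(sample_grid(moving, apply_rigid(init, P),
                                         clamp = TRUE),
                             dim(fixed$data)), fixed$spacing, fixed$origin)
    moving_use <- mv_r
  } else moving_use <- moving
  lat <- make_lattice(fixed, params$control_spacing_mm)
  coef <- matrix(0, prod(lat$cdim), 3)
  lambda <- params$regularization_weight
  traces <- vector("list", params$pyramid_levels)
  converged <- TRUE
  for (lev in seq_len(params$pyramid_levels)) {
    fac <- 2^(params$pyramid_levels - lev)
    fx <- downsample_grid(fixed, fac)
    mv <- downsample_grid(moving_use, fac)
    P <- grid_coords(fx)
    fvals <- as.numeric(fx$data)
    n <- length(fvals)
    grads <- image_gradient(mv)
    objective <- function(cf) {
      u <- cpp_ffd_eval(cf, lat$cdim, lat$corigin, lat$cspacing, P)
      w <- sample_grid(mv, P + u, clamp = TRUE)
      mean((w - fvals)^2) + lambda * bending_penalty(cf, lat$cdim)
    }
    obj <- objective(coef)
    step <- params$step_size_mm
    rel <- Inf
    it <- 0L
    trace <- numeric(0)
    for (it in seq_len(params$max_iterations[lev])) {
      u <- cpp_ffd_eval(coef, lat$cdim, lat$corigin, lat$cspacing, P)
      pts <- P + u
      w <- sample_grid(mv, pts, clamp = TRUE)
      r <- w - fvals
      G <- cbind(sample_grid(grads[[1]], pts, clamp = TRUE),
                 sample_grid(grads[[2]], pts, clamp = TRUE),
                 sample_grid(grads[[3]], pts, clamp = TRUE))
      gc_mat <- cpp_ffd_backproject(2 * r / n * G, lat$cdim, lat$corigin,
                                    lat$cspacing, pts) +
        lambda * bending_grad(coef, lat$cdim)
      gmax <- max(abs(gc_mat))
      if (gmax == 0) break
      accepted <- FALSE
      for (bt in 1:12) {
        cand <- coef - (step / gmax) * gc_mat
        obj_new <- objective(cand)
        if (obj_new < obj) { accepted <- TRUE; break }
        step <- step / 2
      }
      if (!accepted) break
      rel <- (obj - obj_new) / max(obj, .Machine$double.eps)
      coef <- cand
      obj <- obj_new
      trace <- c(trace, obj)
      step <- min(step * 1.25, 4 * params$step_size_mm)
      if (rel < params$convergence_tol) break
    }
    traces[[lev]] <- trace
    if (lev == params$pyramid_levels &&
        params$max_iterations[lev] > 0 && it >= params$max_iterations[lev] &&
        is.finite(rel) && rel >= params$convergence_tol) {
      converged <- FALSE
      warning("FFD registration hit the iteration cap before tolerance; ",
              "returning best-so-far field")
    }
  }
  Pf <- grid_coords(fixed)
  u <- cpp_ffd_eval(coef, lat$cdim, lat$corigin, lat$cspacing, Pf)
  if (!is.null(init)) {
    # total map: x -> T_rigid(x + u_ffd(x))
    u <- apply_rigid(init, Pf + u) - Pf
  }
  out <- disp_field(array(u, c(dim(fixed$data), 3)), fixed$spacing,
                    fixed$origin)
  attr(out, "converged") <- converged
  fin <- traces[[params$pyramid_levels]]
  attr(out, "objective") <- if (length(fin)) fin[length(fin)] else NA_real_
  attr(out, "trace") <- traces  # per-level accepted-objective sequences
  out
}

#' Per-voxel Jacobian determinant of the map x + u(x)
#'
#' Central differences on the field lattice; values <= 0 indicate folding.
#'
#' @param field A `disp_field`.
#' @return 3D array of determinants.
#' @export
jacobian_determinant <- function(field) {
  d <- dim(field$u)[1:3]
  J <- array(0, c(d, 3, 3))
  for (comp in 1:3) {
    g <- image_gradient(voxel_grid(field$u[, , , comp], field$spacing,
                                   field$origin))
    for (ax in 1:3) J[, , , comp, ax] <- g[[ax]]$data
  }
  a11 <- 1 + J[, , , 1, 1]; a12 <- J[, , , 1, 2]; a13 <- J[, , , 1, 3]
  a21 <- J[, , , 2, 1]; a22 <- 1 + J[, , , 2, 2]; a23 <- J[, , , 2, 3]
  a31 <- J[, , , 3, 1]; a32 <- J[, , , 3, 2]; a33 <- 1 + J[, , , 3, 3]
  a11 * (a22 * a33 - a23 * a32) - a12 * (a21 * a33 - a23 * a31) +
    a13 * (a21 * a32 - a22 * a31)
}

#' Invert a displacement field by fixed-point iteration
#'
#' Solves `v(x) = -u(x + v(x))`; valid when the map `x + u(x)` is
#' diffeomorphic on its support, which is checked via the Jacobian
#' determinant.
#'
#' @param field A `disp_field`.
#' @param n_iter Maximum fixed-point iterations.
#' @param tol Stop when the maximum update is below this (mm).
#' @export
invert_field <- function(field, n_iter = 30, tol = 1e-3) {
  if (min(jacobian_determinant(field)) <= 0)
    stop("field folds (non-positive Jacobian determinant); not invertible")
  P <- grid_coords(field)
  v <- -matrix(c(field$u), ncol = 3)
  for (it in seq_len(n_iter)) {
    s <- sample_field(field, P + v)
    if (max(abs(-s - v)) < tol) { v <- -s; break }
    v <- -s
  }
  disp_field(array(v, dim(field$u)), field$spacing, field$origin)
}

#' Compose two displacement fields
#'
#' Returns the field of the composite map `x -> T_outer(T_inner(x))`, i.e.
#' `u(x) = u_inner(x) + u_outer(x + u_inner(x))`.
#'
#' @param outer,inner `disp_field` objects on one lattice.
#' @export
compose_fields <- function(outer, inner) {
  stop_if_grid_mismatch(list(data = outer$u[, , , 1], spacing = outer$spacing,
                             origin = outer$origin),
                        list(data = inner$u[, , , 1], spacing = inner$spacing,
                             origin = inner$origin), "fields")
  P <- grid_coords(inner)
  ui <- matrix(c(inner$u), ncol = 3)
  uo <- sample_field(outer, P + ui)
  disp_field(array(ui + uo, dim(inner$u)), inner$spacing, inner$origin)
}
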