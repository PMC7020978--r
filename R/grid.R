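#' @useDynLib dose4d, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats pnorm quantile rnorm runif sd setNames
#' @importFrom utils head read.csv write.csv
NULL

# Coordinate conventions used throughout the package
# --------------------------------------------------
# Array axis 1 = x (patient left positive), axis 2 = y (anterior positive),
# axis 3 = z (superior positive).  All world coordinates are millimetres,
# voxel-centre convention: the centre of voxel (i, j, k) (1-based R indices)
# sits at origin + (i - 1, j - 1, k - 1) * spacing.  Displacement fields use
# the pull convention: a field defined on the reference grid maps reference
# coordinates x to the corresponding moving-phase location x + u(x).

#' Axis-aligned 3D scalar volume
#'
#' Container for images, dose grids (Gy) and binary masks: a 3D array plus
#' voxel spacing and the world position of the first voxel centre.
#'
#' @param data 3D numeric or logical array.
#' @param spacing Per-axis voxel size in mm (length 3, all > 0).
#' @param origin World coordinate (mm) of the centre of voxel `[1, 1, 1]`.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(data, spacing = c(1, 1, 1), origin = NULL) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive values (mm)")
  if (is.null(origin)) {
    # centre the volume on the world origin
    origin <- -(dim(data) - 1) / 2 * spacing
  }
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (mm)")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_grid> %d x %d x %d voxels, spacing %s mm, %s\n",
              d[1], d[2], d[3], paste(format(x$spacing), collapse = " x "),
              if (is.logical(x$data))
                sprintf("mask (%s cm3)", format(mask_volume_cm3(x), digits = 6))
              else sprintf("range [%.3g, %.3g]",
                           min(x$data), max(x$data))))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$data)

same_lattice <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stop_if_grid_mismatch <- function(a, b, what = "grids") {
  if (!same_lattice(a, b))
    stop(sprintf("%s do not share a lattice (shape/spacing/origin)", what))
  invisible(TRUE)
}

#' World coordinates of every voxel centre
#'
#' @param grid A `voxel_grid` (or anything with `$spacing`, `$origin` and a
#'   3D `$data`/`$u` array).
#' @return n-by-3 matrix of mm coordinates in array (column-major) order.
#' @export
grid_coords <- function(grid) {
  d <- if (!is.null(grid$data)) dim(grid$data)[1:3] else dim(grid$u)[1:3]
  x <- grid$origin[1] + (seq_len(d[1]) - 1) * grid$spacing[1]
  y <- grid$origin[2] + (seq_len(d[2]) - 1) * grid$spacing[2]
  z <- grid$origin[3] + (seq_len(d[3]) - 1) * grid$spacing[3]
  cbind(rep(x, times = d[2] * d[3]),
        rep(rep(y, each = d[1]), times = d[3]),
        rep(z, each = d[1] * d[2]))
}

world_to_index <- function(grid, pts) {
  sweep(sweep(pts, 2, grid$origin, "-"), 2, grid$spacing, "/") + 1
}

#' Volume of one voxel in cm3
#' @param grid A `voxel_grid`.
#' @export
voxel_volume_cm3 <- function(grid) prod(grid$spacing) / 1000

#' Absolute volume of a binary mask in cm3
#' @param mask A logical `voxel_grid`.
#' @export
mask_volume_cm3 <- function(mask) sum(mask$data) * voxel_volume_cm3(mask)

#' Centroid (mm, world coordinates) of a binary mask
#' @param mask A logical `voxel_grid`.
#' @export
mask_centroid <- function(mask) {
  if (!any(mask$data)) stop("empty mask has no centroid")
  idx <- which(mask$data, arr.ind = TRUE)
  colMeans(sweep(idx - 1, 2, mask$spacing, "*")) + mask$origin
}

#' Dice overlap coefficient of two masks on a shared lattice
#' @param a,b Logical `voxel_grid` masks.
#' @export
dice <- function(a, b) {
  stop_if_grid_mismatch(a, b, "masks")
  2 * sum(a$data & b$data) / (sum(a$data) + sum(b$data))
}

#' Sample a volume at arbitrary world points (trilinear)
#'
#' Out-of-volume points take `fill` (default 0); the number of such points is
#' attached as attribute `n_out`.
#'
#' @param grid A `voxel_grid`.
#' @param pts n-by-3 matrix of world mm coordinates.
#' @param fill Value for out-of-volume samples.
#' @param clamp Clamp out-of-volume points to the border instead of filling
#'   (used by the registration metric, which must stay continuous at the
#'   volume edge).
#' @export
sample_grid <- function(grid, pts, fill = 0, clamp = FALSE) {
  ijk <- world_to_index(grid, pts)
  res <- cpp_trilinear(as.numeric(grid$data), dim(grid$data),
                       ijk[, 1], ijk[, 2], ijk[, 3], fill, clamp)
  structure(res$values, n_out = res$n_out)
}

#' Displacement field on a voxel lattice
#'
#' Pull convention: the field lives on the reference lattice and `u(x)` points
#' from reference coordinates to the corresponding moving-phase location, both
#' in world mm.
#'
#' @param u 4D array `[nx, ny, nz, 3]` of mm displacements.
#' @param spacing,origin Lattice metadata as for [voxel_grid()].
#' @return Object of class `disp_field`.
#' @export
disp_field <- function(u, spacing = c(1, 1, 1), origin = NULL) {
  if (length(dim(u)) != 4L || dim(u)[4] != 3L)
    stop("`u` must be an [nx, ny, nz, 3] array")
  if (any(!is.finite(u))) stop("displacement field must be finite everywhere")
  g <- voxel_grid(array(0, dim(u)[1:3]), spacing, origin)
  structure(list(u = u, spacing = g$spacing, origin = g$origin),
            class = "disp_field")
}

#' @export
print.disp_field <- function(x, ...) {
  mag <- sqrt(x$u[, , , 1]^2 + x$u[, , , 2]^2 + x$u[, , , 3]^2)
  d <- dim(x$u)
  cat(sprintf("<disp_field> %d x %d x %d, |u| max %.2f mm, mean %.2f mm\n",
              d[1], d[2], d[3], max(mag), mean(mag)))
  invisible(x)
}

field_magnitude <- function(field) {
  sqrt(field$u[, , , 1]^2 + field$u[, , , 2]^2 + field$u[, , , 3]^2)
}

# Sample a displacement field (componentwise trilinear) at world points.
# Border clamping extends the field constantly beyond the lattice, which is
# what inversion/composition need near the volume edge.
sample_field <- function(field, pts, clamp = TRUE) {
  ijk <- world_to_index(field, pts)
  d <- dim(field$u)
  cbind(
    cpp_trilinear(as.numeric(field$u[, , , 1]), d[1:3],
                  ijk[, 1], ijk[, 2], ijk[, 3], 0, clamp)$values,
    cpp_trilinear(as.numeric(field$u[, , , 2]), d[1:3],
                  ijk[, 1], ijk[, 2], ijk[, 3], 0, clamp)$values,
    cpp_trilinear(as.numeric(field$u[, , , 3]), d[1:3],
                  ijk[, 1], ijk[, 2], ijk[, 3], 0, clamp)$values)
}

#' Isotropic Euclidean margin expansion of a mask
#'
#' A voxel belongs to the expanded mask iff its centre lies within
#' `margin_mm` of some voxel centre of the input mask, with anisotropic
#' spacing respected (exact Euclidean distance transform).
#'
#' @param mask Logical `voxel_grid`.
#' @param margin_mm Non-negative scalar margin in mm.
#' @export
expand_margin <- function(mask, margin_mm) {
  if (!is.numeric(margin_mm) || length(margin_mm) != 1L || margin_mm < 0)
    stop("`margin_mm` must be a single non-negative number")
  if (margin_mm == 0) return(mask)
  d <- cpp_edt(as.logical(mask$data), dim(mask$data), mask$spacing)
  out <- array(d <= margin_mm, dim(mask$data))
  voxel_grid(out, mask$spacing, mask$origin)
}
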