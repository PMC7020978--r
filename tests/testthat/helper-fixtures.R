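# Shared fixtures, memoised so expensive phantoms are built once per run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Coarse phantom: same world extent as the default study grid but 32^3,
# fast enough for per-module tests.
coarse_config <- function(...) {
  phantom_config(grid_shape = c(32, 32, 32), spacing_mm = c(8, 8, 6), ...)
}

coarse_phantom <- function() memo("coarse", generate_phantom(coarse_config()))

# Default-resolution study phantom (seed 42), shared by the acceptance tests.
default_phantom <- function() memo("default", generate_phantom(phantom_config()))

default_plan3 <- function() memo("plan3", build_3d_plan(default_phantom()))

# Small analytic dose/mask pair on an isotropic grid.
toy_grid <- function(value, n = 8, spacing = 1) {
  voxel_grid(array(value, c(n, n, n)), spacing)
}

toy_mask <- function(n = 8, spacing = 1, predicate = function(P) rep(TRUE, nrow(P))) {
  g <- toy_grid(0, n, spacing)
  voxel_grid(array(predicate(grid_coords(g)), c(n, n, n)), g$spacing, g$origin)
}

# Solid sphere mask of radius r (mm) centred on the world origin.
sphere_mask <- function(n, spacing, r, center = c(0, 0, 0)) {
  toy_mask(n, spacing, function(P)
    (P[, 1] - center[1])^2 + (P[, 2] - center[2])^2 +
      (P[, 3] - center[3])^2 <= r^2)
}
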