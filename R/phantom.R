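# Synthetic 4D deforming-liver phantom
# -------------------------------------
# The phantom emulates a respiration-resolved abdominal CT study: a
# liver-sized organ containing a spherical gross tumour volume (GTV) whose
# centroid follows a one-cycle cosine trajectory across the phases, embedded
# in a body with surrounding organs at risk.  Motion is a single global
# respiratory surrogate: a spatially tapered (Gaussian-windowed) translation
# whose inverse map is analytic, so phase masks are exact binary evaluations
# and ground-truth pull fields are recovered by fixed-point iteration to
# machine precision.  Amplitude defaults follow published cohort statistics
# for liver SBRT (mean GTV excursions ~3/8/12 mm L-R/A-P/S-I).

#' Phantom configuration
#'
#' @param grid_shape Voxels per axis (length 3).
#' @param spacing_mm Voxel size per axis in mm (default 4 x 4 mm in-plane,
#'   3 mm slice thickness).
#' @param liver_volume_cm3 Target liver volume; the liver ellipsoid is scaled
#'   analytically to this volume (default 1177.52 cm3, a typical cohort mean).
#' @param gtv_radius_mm GTV sphere radius (default 26 mm, chosen so the
#'   motion-merged internal target volume plus a 5 mm setup margin is close
#'   to 170 cm3).
#' @param gtv_center_mm GTV centre at the reference phase, world mm.
#' @param motion_amplitude_mm Peak-to-peak GTV centroid excursion per axis
#'   (mm); the per-phase centroid offset along each axis is
#'   `A/2 * (cos(2*pi*p/n_phases) - 1)`, i.e. zero at the reference phase and
#'   `-A` at mid-cycle.
#' @param motion_sigma_mm Standard deviation of the Gaussian spatial window
#'   (centred on the GTV) that tapers the deformation, so distant organs move
#'   less than the tumour.
#' @param n_phases Number of equally weighted respiratory phases (>= 2).
#' @param noise_sd Gaussian image-noise standard deviation (intensity units).
#' @param seed Integer seed; identical seeds give bit-identical phantoms.
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(64, 64, 64),
                           spacing_mm = c(4, 4, 3),
                           liver_volume_cm3 = 1177.52,
                           gtv_radius_mm = 26,
                           gtv_center_mm = c(-25, 0, 30),
                           motion_amplitude_mm = c(3, 8, 12),
                           motion_sigma_mm = 80,
                           n_phases = 10,
                           noise_sd = 2,
                           seed = 42) {
  cfg <- list(grid_shape = as.integer(grid_shape),
              spacing_mm = as.numeric(spacing_mm),
              liver_volume_cm3 = liver_volume_cm3,
              gtv_radius_mm = gtv_radius_mm,
              gtv_center_mm = as.numeric(gtv_center_mm),
              motion_amplitude_mm = as.numeric(motion_amplitude_mm),
              motion_sigma_mm = motion_sigma_mm,
              n_phases = as.integer(n_phases),
              noise_sd = noise_sd,
              seed = as.integer(seed))
  if (length(cfg$grid_shape) != 3L || any(cfg$grid_shape < 8))
    stop("`grid_shape` must be 3 integers >= 8")
  if (length(cfg$spacing_mm) != 3L || any(cfg$spacing_mm <= 0))
    stop("all spacings must be > 0")
  if (cfg$liver_volume_cm3 <= 0) stop("`liver_volume_cm3` must be > 0")
  if (cfg$gtv_radius_mm <= 0) stop("`gtv_radius_mm` must be > 0")
  if (length(cfg$motion_amplitude_mm) != 3L || any(cfg$motion_amplitude_mm < 0))
    stop("amplitudes must be 3 non-negative values")
  if (cfg$n_phases < 2L) stop("`n_phases` must be >= 2")
  if (cfg$noise_sd < 0) stop("`noise_sd` must be >= 0")
  class(cfg) <- "phantom_config"
  cfg
}

# Per-phase centroid offset (mm): one cosine cycle across the phases,
# zero at phase 0, -A at mid-cycle.  Rows are phases 0..n-1.
phase_offsets <- function(config) {
  p <- seq_len(config$n_phases) - 1
  f <- (cos(2 * pi * p / config$n_phases) - 1) / 2
  outer(f, config$motion_amplitude_mm)
}

# Analytic anatomy: organ shapes in reference (phase-0) coordinates.
# OARs are carved against the liver so structure masks are disjoint from it.
phantom_anatomy <- function(config) {
  # liver ellipsoid with fixed aspect ratio scaled to the target volume
  aspect <- c(1.5, 1.35, 1)
  cz <- (config$liver_volume_cm3 * 1000 * 3 / (4 * pi) / prod(aspect))^(1 / 3)
  semi_liver <- aspect * cz
  liver_c <- c(-25, 0, 10)
  ell <- function(ctr, semi) {
    force(ctr); force(semi)
    function(P) ((P[, 1] - ctr[1]) / semi[1])^2 +
      ((P[, 2] - ctr[2]) / semi[2])^2 +
      ((P[, 3] - ctr[3]) / semi[3])^2
  }
  cyl <- function(ctr_xy, r, zlim) {
    force(ctr_xy); force(r); force(zlim)
    function(P) {
      q <- ((P[, 1] - ctr_xy[1]) / r)^2 + ((P[, 2] - ctr_xy[2]) / r)^2
      q[P[, 3] < zlim[1] | P[, 3] > zlim[2]] <- Inf
      q
    }
  }
  list(
    body      = list(q = function(P) (P[, 1] / 120)^2 + (P[, 2] / 95)^2,
                     level = 35, edge_mm = 6, scale_mm = 95, carve = FALSE),
    liver     = list(q = ell(liver_c, semi_liver), level = 85, edge_mm = 3,
                     scale_mm = min(semi_liver), carve = FALSE),
    gtv       = list(q = ell(config$gtv_center_mm, rep(config$gtv_radius_mm, 3)),
                     level = 120, edge_mm = 2, scale_mm = config$gtv_radius_mm,
                     carve = FALSE),
    kidney_r  = list(q = ell(c(-45, 25, -60), c(25, 18, 30)), level = 70,
                     edge_mm = 2.5, scale_mm = 18, carve = TRUE),
    kidney_l  = list(q = ell(c(55, 25, -60), c(25, 18, 30)), level = 70,
                     edge_mm = 2.5, scale_mm = 18, carve = TRUE),
    stomach   = list(q = ell(c(80, -15, -5), c(28, 24, 32)), level = 45,
                     edge_mm = 3, scale_mm = 24, carve = TRUE),
    duodenum  = list(q = cyl(c(-20, 15), 9, c(-70, -45)), level = 58,
                     edge_mm = 2, scale_mm = 9, carve = TRUE),
    bowel     = list(q = ell(c(0, 45, -60), c(55, 35, 30)), level = 52,
                     edge_mm = 3, scale_mm = 30, carve = TRUE),
    esophagus = list(q = cyl(c(15, -65), 7, c(10, 95)), level = 42,
                     edge_mm = 2, scale_mm = 7, carve = TRUE),
    heart     = list(q = ell(c(25, -30, 72), c(35, 28, 22)), level = 65,
                     edge_mm = 3, scale_mm = 22, carve = TRUE)
  )
}

# Gaussian motion window evaluated at world points.
motion_window <- function(config, P) {
  c0 <- config$gtv_center_mm
  r2 <- (P[, 1] - c0[1])^2 + (P[, 2] - c0[2])^2 + (P[, 3] - c0[3])^2
  exp(-r2 / (2 * config$motion_sigma_mm^2))
}

# Smooth reference intensity (no noise) at world points.
phantom_intensity <- function(anat, P) {
  I <- rep(0, nrow(P))
  for (org in anat) {
    q <- org$q(P)
    # signed ~mm distance from the boundary, negative inside
    m <- (sqrt(pmax(q, 0)) - 1) * org$scale_mm
    s <- stats::plogis(-m / org$edge_mm)
    I <- I + (org$level - I) * s
  }
  # low-frequency texture inside the body so intensity-based registration has
  # gradient information away from organ boundaries
  tex <- 8 * sin(2 * pi * P[, 1] / 53) * sin(2 * pi * P[, 2] / 61) *
    sin(2 * pi * P[, 3] / 47)
  inb <- stats::plogis(-(sqrt(anat$body$q(P)) - 1) * 95 / 6)
  I + tex * inb
}

# Binary structure masks at (possibly displaced) world points.
phantom_masks <- function(anat, P, dims, spacing, origin) {
  inside <- lapply(anat, function(org) org$q(P) <= 1)
  for (nm in names(anat))
    if (anat[[nm]]$carve) inside[[nm]] <- inside[[nm]] & !inside$liver
  inside$bowel <- inside$bowel & !inside$duodenum
  lapply(inside, function(v) voxel_grid(array(v, dims), spacing, origin))
}

#' Generate a deterministic 4D deforming-liver phantom
#'
#' Produces one image, one structure set, and (for non-reference phases) one
#' ground-truth pull displacement field per respiratory phase.  The inverse
#' deformation is analytic (a Gaussian-windowed translation), so masks are
#' exact and the forward pull fields are solved by fixed-point iteration;
#' the map is diffeomorphic whenever the amplitude is below the folding
#' limit, which is checked and enforced.
#'
#' @param config A [phantom_config()].
#' @return Object of class `phase_set` with elements `images`, `masks`
#'   (one structure set per phase), `true_fields` (`NULL` for the reference
#'   phase), `offsets` (per-phase centroid offsets, mm), `config` and
#'   `reference_phase` (0-based index, always 0).
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  # folding limit of the Gaussian-windowed translation:
  # max |grad d| = |delta| * exp(-1/2) / sigma must stay < 1
  amax <- sqrt(sum(config$motion_amplitude_mm^2))
  lip <- amax * exp(-0.5) / config$motion_sigma_mm
  if (lip >= 0.95)
    stop(sprintf(paste0("motion amplitude |A| = %.1f mm would fold the ",
                        "deformation (Lipschitz bound %.2f >= 0.95) at ",
                        "motion_sigma_mm = %.0f; reduce the amplitude or ",
                        "widen the window"), amax, lip, config$motion_sigma_mm))
  set.seed(config$seed)
  dims <- config$grid_shape
  template <- voxel_grid(array(0, dims), config$spacing_mm)
  P <- grid_coords(template)
  anat <- phantom_anatomy(config)
  offsets <- phase_offsets(config)
  g <- motion_window(config, P)

  images <- vector("list", config$n_phases)
  masks <- vector("list", config$n_phases)
  true_fields <- vector("list", config$n_phases)
  for (p in seq_len(config$n_phases)) {
    delta <- offsets[p, ]
    # inverse map: reference coords of the anatomy seen at phase-p point y
    Q <- P - cbind(g * delta[1], g * delta[2], g * delta[3])
    img <- phantom_intensity(anat, Q)
    if (config$noise_sd > 0)
      img <- img + rnorm(length(img), sd = config$noise_sd)
    images[[p]] <- voxel_grid(array(img, dims), config$spacing_mm,
                              template$origin)
    masks[[p]] <- phantom_masks(anat, Q, dims, config$spacing_mm,
                                template$origin)
    if (p > 1L) {
      # forward pull field: u(x) = d(x + u(x)), contraction by the Lipschitz
      # bound above, so plain fixed-point iteration converges geometrically
      u <- cbind(g * delta[1], g * delta[2], g * delta[3])
      for (it in 1:14) {
        gw <- motion_window(config, P + u)
        u_new <- cbind(gw * delta[1], gw * delta[2], gw * delta[3])
        if (max(abs(u_new - u)) < 1e-10) { u <- u_new; break }
        u <- u_new
      }
      true_fields[[p]] <- disp_field(array(u, c(dims, 3)), config$spacing_mm,
                                     template$origin)
    }
  }
  names(images) <- names(masks) <- paste0("CT", (seq_len(config$n_phases) - 1) * 10)
  structure(list(config = config, reference_phase = 0L, images = images,
                 masks = masks, true_fields = true_fields, offsets = offsets),
            class = "phase_set")
}

#' @export
print.phase_set <- function(x, ...) {
  cat(sprintf(paste0("<phase_set> %d phases, grid %s, liver %.1f cm3, ",
                     "GTV %.1f cm3, |A| = %.1f mm\n"),
              x$config$n_phases,
              paste(x$config$grid_shape, collapse = "x"),
              mask_volume_cm3(x$masks[[1]]$liver),
              mask_volume_cm3(x$masks[[1]]$gtv),
              sqrt(sum(x$config$motion_amplitude_mm^2))))
  invisible(x)
}

#' Internal target volume: voxelwise union of per-phase GTV masks
#'
#' @param per_phase_gtv List of logical `voxel_grid` masks on one lattice.
#' @return Logical `voxel_grid`, the union (ITV).
#' @export
union_itv <- function(per_phase_gtv) {
  if (length(per_phase_gtv) < 1L) stop("need at least one mask")
  out <- per_phase_gtv[[1]]
  for (m in per_phase_gtv[-1]) {
    stop_if_grid_mismatch(out, m, "GTV masks")
    out$data <- out$data | m$data
  }
  out
}
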