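# NIfTI and manifest I/O
# ----------------------
# Volumes (images, dose, masks) travel as scalar NIfTI; displacement fields
# as 4D NIfTI with the vector component last.  The world origin/spacing are
# carried in the NIfTI header (sform); axis order matches the package
# convention (x, y, z).

grid_to_nifti <- function(data, spacing, origin) {
  img <- RNifti::asNifti(data)
  d <- if (length(dim(data)) == 4L) dim(data)[1:3] else dim(data)
  xf <- diag(c(spacing, 1))
  xf[1:3, 4] <- origin
  RNifti::`sform<-`(img, structure(xf, code = 2L))
}

nifti_geometry <- function(img) {
  xf <- RNifti::xform(img)
  list(spacing = diag(xf)[1:3], origin = xf[1:3, 4])
}

#' Write a volume as NIfTI
#'
#' @param grid A `voxel_grid`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @export
write_voxel_grid <- function(grid, path) {
  dat <- if (is.logical(grid$data)) array(as.integer(grid$data),
                                          dim(grid$data)) else grid$data
  RNifti::writeNifti(grid_to_nifti(dat, grid$spacing, grid$origin), path)
  invisible(path)
}

#' Read a volume written by [write_voxel_grid()]
#'
#' @param path NIfTI path.
#' @param mask Interpret voxels as a binary mask (`!= 0`)?
#' @export
read_voxel_grid <- function(path, mask = FALSE) {
  img <- RNifti::readNifti(path)
  geo <- nifti_geometry(img)
  dat <- array(as.numeric(img), dim(img))
  if (mask) dat <- array(dat != 0, dim(dat))
  voxel_grid(dat, geo$spacing, geo$origin)
}

#' Write a displacement field as 4D NIfTI (mm, pull convention)
#'
#' @param field A `disp_field`.
#' @param path Output path.
#' @export
write_disp_field <- function(field, path) {
  RNifti::writeNifti(grid_to_nifti(field$u, field$spacing, field$origin),
                     path)
  invisible(path)
}

#' Read a displacement field written by [write_disp_field()]
#' @param path NIfTI path.
#' @export
read_disp_field <- function(path) {
  img <- RNifti::readNifti(path)
  geo <- nifti_geometry(img)
  disp_field(array(as.numeric(img), dim(img)), geo$spacing, geo$origin)
}

#' Write a phantom phase set to a directory
#'
#' Per-phase images, label maps (one integer label per structure) and
#' ground-truth displacement fields as NIfTI, plus a JSON manifest recording
#' the configuration, seed and file listing.
#'
#' @param phase_set A [generate_phantom()] result.
#' @param dir Output directory.
#' @export
write_phase_set <- function(phase_set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- phase_set$config
  phases <- names(phase_set$images)
  structs <- names(phase_set$masks[[1]])
  files <- list()
  for (p in seq_along(phases)) {
    fimg <- sprintf("image_%s.nii.gz", phases[p])
    write_voxel_grid(phase_set$images[[p]], file.path(dir, fimg))
    # bit-flag label map: structures nest (GTV inside liver inside body),
    # so each structure owns one bit rather than one exclusive label
    lab <- array(0L, dim(phase_set$images[[p]]$data))
    for (s in seq_along(structs))
      lab <- lab + bitwShiftL(1L, s - 1L) *
        array(as.integer(phase_set$masks[[p]][[s]]$data), dim(lab))
    flab <- sprintf("labels_%s.nii.gz", phases[p])
    write_voxel_grid(voxel_grid(lab, cfg$spacing_mm,
                                phase_set$images[[p]]$origin),
                     file.path(dir, flab))
    entry <- list(image = fimg, labels = flab)
    if (p - 1L != phase_set$reference_phase) {
      ffld <- sprintf("field_%s.nii.gz", phases[p])
      write_disp_field(phase_set$true_fields[[p]], file.path(dir, ffld))
      entry$field <- ffld
    }
    files[[phases[p]]] <- entry
  }
  manifest <- list(config = unclass(cfg),
                   reference_phase = phase_set$reference_phase,
                   label_order = structs, phases = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a phase set written by [write_phase_set()]
#' @param dir Directory containing `manifest.json`.
#' @export
read_phase_set <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  cfg <- do.call(phantom_config, man$config)
  phases <- names(man$phases)
  images <- list(); masks <- list(); true_fields <- vector("list", length(phases))
  for (p in seq_along(phases)) {
    ent <- man$phases[[p]]
    images[[phases[p]]] <- read_voxel_grid(file.path(dir, ent$image))
    lab <- read_voxel_grid(file.path(dir, ent$labels))
    masks[[phases[p]]] <- setNames(lapply(seq_along(man$label_order),
      function(s) voxel_grid(
        array(bitwAnd(as.integer(lab$data), bitwShiftL(1L, s - 1L)) > 0L,
              dim(lab$data)),
        lab$spacing, lab$origin)), man$label_order)
    if (!is.null(ent$field))
      true_fields[[p]] <- read_disp_field(file.path(dir, ent$field))
  }
  structure(list(config = cfg, reference_phase = man$reference_phase,
                 images = images, masks = masks, true_fields = true_fields,
                 offsets = phase_offsets(cfg)),
            class = "phase_set")
}

#' Read a study configuration from YAML
#'
#' Recognised top-level keys: `phantom` (passed to [phantom_config()]),
#' `ffd` ([ffd_params()]), `plan` (margin, prescription, beam settings) and
#' `cohort` (`n_patients`, `master_seed`, `motion_scale`).
#'
#' @param path YAML file.
#' @return List with elements `phantom`, `ffd`, `plan`, `cohort`.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  list(phantom = do.call(phantom_config, y$phantom %||% list()),
       ffd = do.call(ffd_params, y$ffd %||% list()),
       plan = y$plan %||% list(),
       cohort = y$cohort %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
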