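# Analytic multi-beam dose surrogate
# ----------------------------------
# Stands in for a treatment planning system's dose engine.  Each coplanar
# beam projects the target (plus a beam's-eye-view margin) into an aperture;
# dose falls off laterally with a Gaussian penumbra at the aperture edge and
# exponentially with radiological depth from the body surface.  This is not a
# transport calculation: it preserves the geometric mechanism under study --
# the irradiated bath scales with the aperture, and the aperture scales with
# the target volume -- which is what drives the 3D-vs-4D comparison.

#' Beam/plan specification for the dose surrogate
#'
#' @param target_mask Logical `voxel_grid`; the planning target (PTV).
#' @param prescription_Gy Total prescribed dose (Gy).
#' @param gantry_angles_deg Distinct coplanar gantry angles (degrees; 0 =
#'   anterior, rotating about the S-I axis). Default five equispaced fields.
#' @param aperture_margin_mm Beam's-eye-view margin added around the
#'   projected target.
#' @param penumbra_sigma_mm Lateral Gaussian falloff scale at the aperture
#'   edge.
#' @param attenuation_per_cm Exponential depth-dose factor per cm of tissue.
#' @export
plan_spec <- function(target_mask,
                      prescription_Gy = 50,
                      gantry_angles_deg = c(0, 72, 144, 216, 288),
                      aperture_margin_mm = 5,
                      penumbra_sigma_mm = 5,
                      attenuation_per_cm = 0.04) {
  if (prescription_Gy <= 0) stop("`prescription_Gy` must be > 0")
  if (anyDuplicated(gantry_angles_deg %% 360))
    stop("gantry angles must be distinct")
  if (length(gantry_angles_deg) < 1L) stop("need at least one beam")
  if (aperture_margin_mm < 0 || penumbra_sigma_mm < 0 ||
      attenuation_per_cm < 0)
    stop("margin, penumbra and attenuation must all be >= 0")
  structure(list(target_mask = target_mask,
                 prescription_Gy = prescription_Gy,
                 gantry_angles_deg = as.numeric(gantry_angles_deg),
                 aperture_margin_mm = aperture_margin_mm,
                 penumbra_sigma_mm = penumbra_sigma_mm,
                 attenuation_per_cm = attenuation_per_cm),
            class = "plan_spec")
}

# One beam's dose factor field (unit central dose) on the body grid.
beam_dose_factor <- function(theta_deg, target_mask, body_mask,
                             aperture_margin_mm, penumbra_sigma_mm,
                             attenuation_per_mm, bev_cell_mm = 2) {
  P <- grid_coords(target_mask)
  th <- theta_deg * pi / 180
  # BEV coordinates: p (lateral), q (S-I); s increases along beam travel
  p <- P[, 1] * cos(th) + P[, 2] * sin(th)
  q <- P[, 3]
  s <- P[, 1] * sin(th) - P[, 2] * cos(th)
  h <- bev_cell_mm
  p0 <- min(p) - 4 * penumbra_sigma_mm - aperture_margin_mm - 2 * h
  q0 <- min(q) - 4 * penumbra_sigma_mm - aperture_margin_mm - 2 * h
  np <- ceiling((max(p) - p0 + 4 * penumbra_sigma_mm + aperture_margin_mm +
                   2 * h) / h) + 1
  nq <- ceiling((max(q) - q0 + 4 * penumbra_sigma_mm + aperture_margin_mm +
                   2 * h) / h) + 1
  ci <- pmin(pmax(floor((p - p0) / h) + 1L, 1L), np)
  cj <- pmin(pmax(floor((q - q0) / h) + 1L, 1L), nq)
  cell <- ci + (cj - 1L) * np
  tsel <- as.logical(target_mask$data)
  ap <- logical(np * nq)
  ap[cell[tsel]] <- TRUE
  # aperture = projected target dilated by the BEV margin (2D EDT)
  d_out <- cpp_edt(ap, c(np, nq, 1L), c(h, h, 1))
  ap_m <- d_out <= aperture_margin_mm
  d_out <- cpp_edt(ap_m, c(np, nq, 1L), c(h, h, 1))
  d_in <- cpp_edt(!ap_m, c(np, nq, 1L), c(h, h, 1))
  signed <- d_out - d_in  # negative inside the aperture
  # bilinear sampling of the signed-distance map at each voxel's BEV coords
  sd3 <- array(rep(signed, 2), c(np, nq, 2))
  pi_idx <- (p - p0) / h + 1
  qi_idx <- (q - q0) / h + 1
  sgn <- cpp_trilinear(as.numeric(sd3), c(np, nq, 2L),
                       pi_idx, qi_idx, rep(1, length(p)), fill = 1e6)$values
  # zero penumbra degenerates to a sharp aperture indicator
  lateral <- if (penumbra_sigma_mm > 0) pnorm(-sgn / penumbra_sigma_mm)
             else as.numeric(sgn <= 0)
  # body entry depth per BEV cell: minimum s among body voxels in the cell
  bsel <- as.logical(body_mask$data)
  ord <- order(cell[bsel], s[bsel])
  cb <- cell[bsel][ord]
  sb <- s[bsel][ord]
  keep <- !duplicated(cb)
  entry <- rep(Inf, np * nq)
  entry[cb[keep]] <- sb[keep]
  depth <- pmax(s - entry[cell], 0)
  depth[!is.finite(depth)] <- 0
  lateral * exp(-attenuation_per_mm * depth)
}

#' Compute the surrogate dose for a plan
#'
#' Sums the per-beam aperture/penumbra/depth factors; each beam carries an
#' equal share of the prescription, so the (pre-normalization) central target
#' dose is close to `prescription_Gy`.  Deterministic and linear in the
#' prescription.
#'
#' @param spec A [plan_spec()].
#' @param body_mask Logical `voxel_grid` delimiting the patient surface
#'   (depth is measured from its entry boundary along each beam).
#' @return `voxel_grid` of absorbed dose (Gy).
#' @export
compute_plan_dose <- function(spec, body_mask) {
  stopifnot(inherits(spec, "plan_spec"))
  target <- spec$target_mask
  if (!any(target$data)) stop("empty planning target")
  stop_if_grid_mismatch(target, body_mask, "target and body masks")
  per_beam <- spec$prescription_Gy / length(spec$gantry_angles_deg)
  dose <- 0
  for (th in spec$gantry_angles_deg)
    dose <- dose + per_beam *
      beam_dose_factor(th, target, body_mask, spec$aperture_margin_mm,
                       spec$penumbra_sigma_mm, spec$attenuation_per_cm / 10)
  voxel_grid(array(dose, dim(target$data)), target$spacing, target$origin)
}

#' Scale a dose grid to a coverage objective
#'
#' Finds the unique scale factor under which exactly `coverage_fraction` of
#' the target voxels (up to one-voxel quantization) receive at least
#' `prescription_Gy`, i.e. D at the coverage level equals the prescription.
#' Applying the normalization twice equals applying it once.
#'
#' @param dose `voxel_grid` of dose (Gy).
#' @param target_mask Logical `voxel_grid`.
#' @param coverage_fraction Fraction of the target to be covered (0, 1);
#'   default 0.95 (the "95% of PTV receives the prescription" objective).
#' @param prescription_Gy Prescription dose (Gy).
#' @return Scaled dose `voxel_grid` with attribute `scale`.
#' @export
normalize_to_coverage <- function(dose, target_mask, coverage_fraction = 0.95,
                                  prescription_Gy = 50) {
  if (coverage_fraction <= 0 || coverage_fraction >= 1)
    stop("`coverage_fraction` must be in (0, 1)")
  stop_if_grid_mismatch(dose, target_mask, "dose and target")
  dv <- dose$data[target_mask$data]
  if (length(dv) == 0L) stop("empty target")
  k <- ceiling(coverage_fraction * length(dv))
  d_cov <- sort(dv, decreasing = TRUE)[k]
  if (d_cov <= 0) stop("coverage-level dose is zero in the target; cannot normalize")
  scale <- prescription_Gy / d_cov
  out <- voxel_grid(dose$data * scale, dose$spacing, dose$origin)
  attr(out, "scale") <- scale
  out
}

# Protocol constraints for the normal liver and luminal organs.
oar_constraint_report <- function(dose, masks, ptv) {
  nl <- normal_liver(masks$liver, ptv)
  m <- dvh_metrics(compute_dvh(dose, nl))
  rows <- list(
    c("normal_liver_Dmean_Gy", 23, m[["Dmean"]]),
    c("normal_liver_V5_pct", 86, m[["V5"]]),
    c("normal_liver_V10_pct", 68, m[["V10"]]),
    c("normal_liver_V20_pct", 49, m[["V20"]]),
    c("normal_liver_V30_pct", 28, m[["V30"]]),
    c("normal_liver_V40_pct", 20, m[["V40"]]))
  for (org in c("stomach", "duodenum")) {
    if (any(masks[[org]]$data)) {
      mm <- dvh_metrics(compute_dvh(dose, masks[[org]]))
      rows <- c(rows, list(c(paste0(org, "_Dmax_Gy"), 45, mm[["Dmax"]])))
    }
  }
  df <- data.frame(constraint = vapply(rows, `[`, "", 1),
                   limit = as.numeric(vapply(rows, `[`, "", 2)),
                   value = as.numeric(vapply(rows, `[`, "", 3)))
  df$pass <- df$value <= df$limit
  df
}

#' Build the 3D ITV-based plan on the reference phase
#'
#' Target = union of per-phase GTVs (the ITV) expanded by the setup margin;
#' one surrogate dose is computed on the reference grid and normalized so
#' that `coverage_fraction` of the PTV receives the prescription.  Organ
#' constraint violations are recorded in the report, not fatal (mirroring
#' clinical plan review).
#'
#' @param phase_set A phantom [generate_phantom()] output.
#' @param margin_mm Setup margin (mm) applied to the ITV; default 5.
#' @param prescription_Gy Total prescription (Gy); default 50.
#' @param coverage_fraction Coverage objective; default 0.95.
#' @param ... Further arguments to [plan_spec()].
#' @return List of class `plan3d`: `dose`, `ptv`, `itv`, `report`, `scale`.
#' @export
build_3d_plan <- function(phase_set, margin_mm = 5, prescription_Gy = 50,
                          coverage_fraction = 0.95, ...) {
  stopifnot(inherits(phase_set, "phase_set"))
  gtvs <- lapply(phase_set$masks, `[[`, "gtv")
  itv <- union_itv(gtvs)
  ptv <- expand_margin(itv, margin_mm)
  ref <- phase_set$reference_phase + 1L
  spec <- plan_spec(target_mask = ptv, prescription_Gy = prescription_Gy, ...)
  dose <- compute_plan_dose(spec, phase_set$masks[[ref]]$body)
  dose <- normalize_to_coverage(dose, ptv, coverage_fraction, prescription_Gy)
  report <- oar_constraint_report(dose, phase_set$masks[[ref]], ptv)
  structure(list(dose = dose, ptv = ptv, itv = itv, report = report,
                 scale = attr(dose, "scale"),
                 prescription_Gy = prescription_Gy),
            class = "plan3d")
}

#' Build the ten phase-tracked 4D plans
#'
#' Per phase: target = that phase's GTV plus the setup margin; the same
#' gantry angles as the 3D plan; each phase plan is normalized so that the
#' coverage fraction of the phase PTV receives the phase prescription.
#' Doses are stored as total physical dose: with the default 10 equally
#' weighted phases and a 50 Gy course, each phase carries 5 Gy
#' (0.5 Gy per fraction x 10 fractions), so the nominal summed total is the
#' full prescription.
#'
#' @inheritParams build_3d_plan
#' @return List of class `plan4d`: `doses` (per phase), `ptvs`,
#'   `phase_prescription_Gy`.
#' @export
build_4d_phase_plans <- function(phase_set, margin_mm = 5,
                                 prescription_Gy = 50,
                                 coverage_fraction = 0.95, ...) {
  stopifnot(inherits(phase_set, "phase_set"))
  n <- phase_set$config$n_phases
  rx_phase <- prescription_Gy / n
  doses <- vector("list", n)
  ptvs <- vector("list", n)
  for (p in seq_len(n)) {
    ptv <- expand_margin(phase_set$masks[[p]]$gtv, margin_mm)
    spec <- plan_spec(target_mask = ptv, prescription_Gy = rx_phase, ...)
    d <- compute_plan_dose(spec, phase_set$masks[[p]]$body)
    doses[[p]] <- normalize_to_coverage(d, ptv, coverage_fraction, rx_phase)
    ptvs[[p]] <- ptv
  }
  names(doses) <- names(ptvs) <- names(phase_set$images)
  structure(list(doses = doses, ptvs = ptvs,
                 phase_prescription_Gy = rx_phase,
                 prescription_Gy = prescription_Gy),
            class = "plan4d")
}

#' @export
print.plan3d <- function(x, ...) {
  cat(sprintf("<plan3d> PTV %.1f cm3 (ITV %.1f cm3), prescription %g Gy\n",
              mask_volume_cm3(x$ptv), mask_volume_cm3(x$itv),
              x$prescription_Gy))
  rep <- x$report
  rep$value <- round(rep$value, 2)
  print(rep, row.names = FALSE)
  invisible(x)
}

#' @export
print.plan4d <- function(x, ...) {
  v <- vapply(x$ptvs, mask_volume_cm3, 0)
  cat(sprintf(paste0("<plan4d> %d phase plans, per-phase PTV %.1f-%.1f cm3 ",
                     "(mean %.1f), phase prescription %g Gy\n"),
              length(x$doses), min(v), max(v), mean(v),
              x$phase_prescription_Gy))
  invisible(x)
}
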