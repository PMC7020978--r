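# Lyman-Kutcher-Burman (LKB) normal tissue complication probability
# -----------------------------------------------------------------
# The nonuniform DVH is first reduced to an equivalent uniform irradiation
# of a fractional volume v_eff at the maximum dose (Kutcher-Burman
# effective-volume reduction under the power law TD(1) = TD(v) * v^n), then
# the probit dose-response is evaluated:
#   t = (D - TD50(v)) / (m * TD50(v)),  TD50(v) = TD50(1) * v^(-n),
#   NTCP = Phi(t)  (standard normal CDF).

#' LKB model parameters for one organ endpoint
#'
#' Liver defaults: n = 0.32 (volume-effect exponent), m = 0.15 (slope of the
#' dose-complication curve) and TD50(1) = 40 Gy (whole-organ 50% tolerance
#' dose), the parameter set commonly used for radiation-induced liver
#' disease.
#'
#' @param n Volume-effect exponent (> 0).
#' @param m Slope parameter (> 0).
#' @param TD50_1_Gy Whole-organ 50% tolerance dose in Gy (> 0).
#' @param endpoint Free-text endpoint label.
#' @export
lkb_params <- function(n = 0.32, m = 0.15, TD50_1_Gy = 40,
                       endpoint = "liver: RILD") {
  if (n <= 0 || m <= 0 || TD50_1_Gy <= 0)
    stop("`n`, `m` and `TD50_1_Gy` must all be > 0")
  structure(list(n = n, m = m, TD50_1_Gy = TD50_1_Gy, endpoint = endpoint),
            class = "lkb_params")
}

#' @export
print.lkb_params <- function(x, ...) {
  cat(sprintf("<lkb_params> n = %g, m = %g, TD50(1) = %g Gy [%s]\n",
              x$n, x$m, x$TD50_1_Gy, x$endpoint))
  invisible(x)
}

#' Default LKB parameter table per organ endpoint
#'
#' The liver row is the parameter set used throughout this package.  The
#' non-liver rows are literature defaults in the tradition of the
#' Burman et al. (1991) fits to the Emami tolerance tables; they are
#' user-editable engineering defaults, not values asserted by any single
#' study, and should be replaced when an analysis targets a specific
#' endpoint.
#'
#' @return data.frame with columns `organ`, `endpoint`, `n`, `m`,
#'   `TD50_1_Gy`.
#' @export
lkb_param_table <- function() {
  data.frame(
    organ = c("liver", "kidney_l", "kidney_r", "bowel", "duodenum",
              "esophagus", "stomach", "heart"),
    endpoint = c("radiation-induced liver disease", "nephritis", "nephritis",
                 "obstruction/perforation", "obstruction/perforation",
                 "clinical stricture/perforation", "ulceration/perforation",
                 "pericarditis"),
    n = c(0.32, 0.70, 0.70, 0.15, 0.15, 0.06, 0.15, 0.35),
    m = c(0.15, 0.10, 0.10, 0.16, 0.16, 0.11, 0.14, 0.10),
    TD50_1_Gy = c(40, 28, 28, 55, 55, 68, 65, 48))
}

#' Kutcher-Burman effective-volume DVH reduction
#'
#' Reduces a nonuniform DVH to the fractional volume that, irradiated
#' uniformly at the maximum dose `D_ref`, is equivalent under the power law:
#' `v_eff = sum_i dv_i * (D_i / D_ref)^(1/n)` over differential DVH bins
#' (bin-centre doses, clipped at the exact maximum so uniform irradiation
#' reduces to `v_eff = 1` identically).
#'
#' @param dvh A [compute_dvh()] object.
#' @param n Volume-effect exponent (> 0).
#' @return List of class `effective_volume`: `v_eff` in (0, 1] and
#'   `D_ref_Gy` (the DVH maximum dose).
#' @export
effective_volume <- function(dvh, n = 0.32) {
  stopifnot(inherits(dvh, "dvh"))
  if (n <= 0) stop("`n` must be > 0")
  if (dvh$dmax_Gy <= 0)
    stop("zero-dose DVH has no reference dose for the reduction")
  dd <- dvh_differential(dvh)
  v_eff <- sum(dd$frac * (dd$dose_Gy / dvh$dmax_Gy)^(1 / n))
  structure(list(v_eff = v_eff, D_ref_Gy = dvh$dmax_Gy, n = n),
            class = "effective_volume")
}

#' LKB probit NTCP for an effective-volume reduction
#'
#' @param ev An [effective_volume()] result (or a list with `v_eff` and
#'   `D_ref_Gy`).
#' @param params An [lkb_params()].
#' @return Complication probability in `[0, 1]`.
#' @export
lkb_ntcp <- function(ev, params = lkb_params()) {
  stopifnot(inherits(params, "lkb_params"))
  if (ev$v_eff <= 0 || ev$v_eff > 1 + 1e-9)
    stop("`v_eff` must be in (0, 1]")
  td50_v <- params$TD50_1_Gy * ev$v_eff^(-params$n)
  t <- (ev$D_ref_Gy - td50_v) / (params$m * td50_v)
  pnorm(t)
}

#' NTCP straight from a dose grid and structure mask
#'
#' Composition `compute_dvh` -> `effective_volume` -> `lkb_ntcp`; also
#' returns the DVH metric bundle.
#'
#' @param dose `voxel_grid` of dose (Gy).
#' @param mask Logical `voxel_grid` of the structure.
#' @param params An [lkb_params()].
#' @param bin_width_Gy DVH bin width.
#' @return List: `ntcp`, `v_eff`, `D_ref_Gy`, `metrics`, `dvh`.
#' @export
ntcp_from_dose <- function(dose, mask, params = lkb_params(),
                           bin_width_Gy = 0.1) {
  dvh <- compute_dvh(dose, mask, bin_width_Gy)
  if (dvh$dmax_Gy <= 0) {
    # unirradiated structure: complication probability is numerically zero
    return(list(ntcp = 0, v_eff = NA_real_, D_ref_Gy = 0,
                metrics = dvh_metrics(dvh), dvh = dvh))
  }
  ev <- effective_volume(dvh, params$n)
  list(ntcp = lkb_ntcp(ev, params), v_eff = ev$v_eff,
       D_ref_Gy = ev$D_ref_Gy, metrics = dvh_metrics(dvh), dvh = dvh)
}
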