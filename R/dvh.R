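# Dose-volume histograms and the Vx / Dmean / Dmax metric family.

#' Normal liver: liver minus the planning target volume
#'
#' @param liver_mask,ptv_mask Logical `voxel_grid`s on one lattice.
#' @return Logical `voxel_grid` of the set difference.
#' @export
normal_liver <- function(liver_mask, ptv_mask) {
  stop_if_grid_mismatch(liver_mask, ptv_mask, "liver and PTV masks")
  out <- voxel_grid(liver_mask$data & !ptv_mask$data, liver_mask$spacing,
                    liver_mask$origin)
  if (!any(out$data))
    stop("normal liver is empty (PTV covers the whole liver)")
  out
}

#' Cumulative dose-volume histogram of a structure
#'
#' Voxel-counting DVH on a uniform dose grid: `cum_frac[i]` is the fraction
#' of the structure volume receiving at least `bin_edges[i]` Gy (closed
#' lower bound, so ties at a query dose count as covered).  Binary masks
#' only; no partial-volume weighting.
#'
#' @param dose `voxel_grid` of dose (Gy).
#' @param mask Non-empty logical `voxel_grid` on the same lattice.
#' @param bin_width_Gy Histogram bin width; default 0.1 Gy.
#' @param structure Optional structure name carried in the object.
#' @return Object of class `dvh`: `bin_edges_Gy`, `cum_frac`,
#'   `volume_cm3`, `dmax_Gy` and `dmean_Gy` (exact voxel statistics),
#'   `bin_width_Gy`, `structure`.
#' @export
compute_dvh <- function(dose, mask, bin_width_Gy = 0.1, structure = "") {
  stop_if_grid_mismatch(dose, mask, "dose and mask")
  v <- dose$data[mask$data]
  if (length(v) == 0L) stop("empty mask")
  if (any(v < 0)) stop("negative dose")
  n_bins <- floor(max(v) / bin_width_Gy) + 1L
  edges <- (seq_len(n_bins + 1L) - 1L) * bin_width_Gy
  idx <- pmin(floor(v / bin_width_Gy) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  # fraction receiving >= each edge; final edge exceeds the maximum, so 0
  cum <- c(rev(cumsum(rev(counts))) / length(v), 0)
  structure(list(bin_edges_Gy = edges, cum_frac = cum,
                 volume_cm3 = length(v) * voxel_volume_cm3(dose),
                 dmax_Gy = max(v), dmean_Gy = mean(v),
                 bin_width_Gy = bin_width_Gy, structure = structure),
            class = "dvh")
}

# Differential DVH: fractional volume per bin with bin-centre doses clipped
# at the exact maximum (so uniform irradiation reduces exactly).
dvh_differential <- function(dvh) {
  frac <- -diff(dvh$cum_frac)
  centers <- pmin(dvh$bin_edges_Gy[-length(dvh$bin_edges_Gy)] +
                    dvh$bin_width_Gy / 2, dvh$dmax_Gy)
  list(dose_Gy = centers, frac = frac)
}

#' Fraction of volume receiving at least a dose (in percent)
#'
#' @param dvh A `dvh`.
#' @param dose_Gy Query dose(s) in Gy.
#' @export
dvh_vx <- function(dvh, dose_Gy) {
  edges <- dvh$bin_edges_Gy
  vapply(dose_Gy, function(d) {
    if (d <= 0) return(100)
    if (d > edges[length(edges)]) return(0)
    # smallest edge >= d gives the conservative closed-bound fraction;
    # edges aligned with the query (the usual case) are exact
    i <- which(edges >= d - 1e-9)[1]
    100 * dvh$cum_frac[i]
  }, 0)
}

#' Dose received by at least a given fraction of the structure
#'
#' `dose_at_volume(dvh, 0.95)` is D95: the highest histogram edge at which
#' the covered fraction is still at least `q`.
#'
#' @param dvh A `dvh`.
#' @param q Volume fraction in (0, 1].
#' @export
dose_at_volume <- function(dvh, q) {
  stopifnot(q > 0, q <= 1)
  ok <- dvh$cum_frac >= q - 1e-12
  if (!any(ok)) return(0)
  max(dvh$bin_edges_Gy[ok])
}

#' Standard metric bundle from a DVH
#'
#' V5-V40 (percent of volume receiving at least 5..40 Gy), Dmean (first
#' moment of the differential DVH) and Dmax (exact maximum voxel dose).
#'
#' @param dvh A `dvh`.
#' @return Named numeric vector `V5, V10, ..., V40, Dmean, Dmax`.
#' @export
dvh_metrics <- function(dvh) {
  xs <- seq(5, 40, by = 5)
  vx <- dvh_vx(dvh, xs)
  dd <- dvh_differential(dvh)
  dmean <- sum(dd$dose_Gy * dd$frac)
  setNames(c(vx, dmean, dvh$dmax_Gy),
           c(paste0("V", xs), "Dmean", "Dmax"))
}

#' @export
print.dvh <- function(x, ...) {
  cat(sprintf("<dvh> %s%.1f cm3, Dmean %.2f Gy, Dmax %.2f Gy\n",
              if (nzchar(x$structure)) paste0(x$structure, ", ") else "",
              x$volume_cm3, x$dmean_Gy, x$dmax_Gy))
  invisible(x)
}

#' @export
plot.dvh <- function(x, ..., xlab = "Dose (Gy)",
                     ylab = "Volume fraction (%)") {
  graphics::plot(x$bin_edges_Gy, 100 * x$cum_frac, type = "s",
                 xlab = xlab, ylab = ylab, ylim = c(0, 100), ...)
  invisible(x)
}

#' Export a cumulative DVH as CSV
#'
#' Columns `dose_Gy`, `fraction`, `cumulative_cm3`.
#'
#' @param dvh A `dvh`.
#' @param path Output file path.
#' @export
write_dvh <- function(dvh, path) {
  df <- data.frame(dose_Gy = dvh$bin_edges_Gy, fraction = dvh$cum_frac,
                   cumulative_cm3 = dvh$cum_frac * dvh$volume_cm3)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a DVH written by [write_dvh()]
#'
#' @param path CSV file path.
#' @param structure Optional structure name.
#' @export
read_dvh <- function(path, structure = "") {
  df <- read.csv(path)
  bw <- diff(df$dose_Gy[1:2])
  dd_dose <- df$dose_Gy[-nrow(df)] + bw / 2
  frac <- -diff(df$fraction)
  dmean <- sum(dd_dose * frac)
  dmax <- max(df$dose_Gy[df$fraction > 0])
  structure(list(bin_edges_Gy = df$dose_Gy, cum_frac = df$fraction,
                 volume_cm3 = df$cumulative_cm3[1] / max(df$fraction[1], 1e-12),
                 dmax_Gy = dmax, dmean_Gy = dmean, bin_width_Gy = bw,
                 structure = structure),
            class = "dvh")
}
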