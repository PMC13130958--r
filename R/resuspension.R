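#' Erosion depth from a change in suspended sediment
#'
#' Inverts an observed SPM increase over the water column to the thickness of
#' bed sediment whose removal supplies it:
#' \deqn{ED = \Delta SPM \cdot D / (\rho_d (1 - \phi))}
#' with \eqn{\rho_d (1 - \phi)} the dry bulk density. Units: \eqn{\Delta SPM}
#' in g m^-3 and \eqn{D} in m give g m^-2 of resuspended mass; dividing by the
#' dry bulk density in g cm^-3 (equivalently \eqn{10^6} g m^-3) and converting
#' to cm divides by a further \eqn{10^4}. A negative \eqn{\Delta SPM} (net
#' deposition) yields zero erosion, flagged via attribute `no_erosion`.
#'
#' @param delta_spm Change in SPM, after minus before (g m^-3).
#' @param D Water depth (m, > 0).
#' @param phi Porosity fraction in [0, 1).
#' @param rho_d Particle density (g cm^-3, > 0), default 2.45.
#' @return Erosion depth in cm with logical attribute `no_erosion`.
#' @examples
#' erosion_depth(30, 7, 0.85)   # ~0.0571 cm
#' @export
erosion_depth <- function(delta_spm, D, phi, rho_d = 2.45) {
  if (any(D <= 0)) stop("D must be > 0", call. = FALSE)
  if (any(phi < 0 | phi >= 1)) stop("phi must lie in [0, 1)", call. = FALSE)
  if (any(rho_d <= 0)) stop("rho_d must be > 0", call. = FALSE)
  ed <- pmax(delta_spm, 0) * D / (rho_d * (1 - phi) * 1e4)
  structure(ed, no_erosion = delta_spm <= 0)
}

#' Mass of sediment resuspended per unit area
#'
#' The product of the SPM increase and the water depth. Negative changes
#' (deposition) contribute zero, flagged.
#'
#' @inheritParams erosion_depth
#' @return Mass in g m^-2 with logical attribute `no_erosion`.
#' @examples
#' mass_resuspended(30, 7)   # 210 g m-2
#' @export
mass_resuspended <- function(delta_spm, D) {
  if (any(D <= 0)) stop("D must be > 0", call. = FALSE)
  structure(pmax(delta_spm, 0) * D, no_erosion = delta_spm <= 0)
}

#' Thickness-weighted phosphorus concentration over an eroded layer
#'
#' Averages a depth profile of sediment P concentrations over the eroded
#' thickness, with the deepest reached layer weighted by the part of it that
#' is actually eroded:
#' \deqn{\bar P = [\sum_{i<n} P_i \Delta z_i + P_n (ED - \sum_{i<n} \Delta z_i)] / ED}
#' where layer \eqn{n} is the first whose cumulative bottom reaches `ED`.
#' Erosion below the sampled profile is an error — the profile is never
#' extrapolated.
#'
#' @param p Layer P concentrations, surface-down (mg g^-1).
#' @param dz Layer thicknesses (cm), same length as `p`.
#' @param ED Erosion depth (cm), `0 < ED <= sum(dz)`.
#' @return Weighted mean concentration (mg g^-1); always between the min and
#'   max of the contributing layers.
#' @examples
#' depth_weighted_p(c(1.0, 0.8, 0.6), c(1, 1, 1), 1.5)   # 0.93333
#' @export
depth_weighted_p <- function(p, dz, ED) {
  if (length(p) != length(dz) || !length(p))
    stop("p and dz must be non-empty vectors of equal length", call. = FALSE)
  if (any(dz <= 0)) stop("layer thicknesses must be > 0", call. = FALSE)
  if (anyNA(p)) stop("P profile contains missing values", call. = FALSE)
  if (!is.finite(ED) || ED <= 0) stop("ED must be > 0", call. = FALSE)
  cb <- cumsum(dz)
  if (ED > cb[length(cb)] + 1e-12)
    stop(sprintf("erosion depth %.4g cm exceeds sampled profile (%.4g cm); refusing to extrapolate",
                 ED, cb[length(cb)]), call. = FALSE)
  n <- which(cb >= ED - 1e-12)[1L]
  full <- if (n > 1L) sum(p[seq_len(n - 1L)] * dz[seq_len(n - 1L)]) else 0
  partial <- p[[n]] * (ED - if (n > 1L) cb[[n - 1L]] else 0)
  unname((full + partial) / ED)
}

#' Sediment phosphorus release from an erosion event
#'
#' Total P mobilised and bioavailable P released per unit area when a layer
#' of thickness `ED` is eroded: the thickness-weighted P concentration over
#' the eroded window times the resuspended mass (the 10^-3 converts
#' mg g^-1 x g m^-2 to g m^-2).
#'
#' @param core A [sediment_core()] with complete P fractions over the eroded
#'   window.
#' @param ED Erosion depth (cm).
#' @param M_resuspended Resuspended sediment mass (g m^-2, >= 0).
#' @return A list with `TP_sediment` and `BioP_sediment` (g m^-2);
#'   `TP_sediment >= BioP_sediment`. Both are 0 when `M_resuspended` is 0.
#' @export
sediment_p_release <- function(core, ED, M_resuspended) {
  stopifnot(inherits(core, "sediment_core"))
  if (M_resuspended < 0) stop("M_resuspended must be >= 0", call. = FALSE)
  if (M_resuspended == 0 || ED == 0)
    return(list(TP_sediment = 0, BioP_sediment = 0))
  dz <- layer_thickness(core)
  tp_bar <- depth_weighted_p(total_p(core), dz, ED)
  biop_bar <- depth_weighted_p(bioavailable_p(core), dz, ED)
  list(TP_sediment = tp_bar * M_resuspended * 1e-3,
       BioP_sediment = biop_bar * M_resuspended * 1e-3)
}

#' Water-column change across a resuspension event
#'
#' Differences two samples from the same station bracketing an event. SPM
#' changes are volumetric (g m^-3); TP and SRP changes are integrated over
#' the water column (g m^-2). The TP/SPM and SRP/SPM ratios (mg of P per g of
#' sediment loaded to the water column) characterise the P content of the
#' resuspended material; they are undefined (`NA`, flagged) when SPM did not
#' increase.
#'
#' @param before,after [water_sample()] objects, same station and depth, with
#'   `after` sampled later.
#' @return A list: `delta_spm_g_m3`, `delta_tp_g_m2`, `delta_srp_g_m2`,
#'   `tp_spm_ratio_mg_g`, `srp_spm_ratio_mg_g`, `ratios_defined`.
#' @export
water_column_delta <- function(before, after) {
  stopifnot(inherits(before, "water_sample"), inherits(after, "water_sample"))
  if (!identical(before$station_id, after$station_id))
    stop("samples are from different stations", call. = FALSE)
  if (!(after$date > before$date))
    stop("after sample must postdate before sample", call. = FALSE)
  if (abs(before$depth_m - after$depth_m) > 1e-9)
    stop("samples report different water depths", call. = FALSE)
  D <- before$depth_m
  dspm <- after$spm_g_m3 - before$spm_g_m3
  dtp <- (after$tp_g_m3 - before$tp_g_m3) * D
  dsrp <- (after$srp_g_m3 - before$srp_g_m3) * D
  ok <- !is.na(dspm) && dspm > 0
  list(delta_spm_g_m3 = dspm,
       delta_tp_g_m2 = dtp,
       delta_srp_g_m2 = dsrp,
       tp_spm_ratio_mg_g = if (ok) 1000 * (after$tp_g_m3 - before$tp_g_m3) / dspm else NA_real_,
       srp_spm_ratio_mg_g = if (ok) 1000 * (after$srp_g_m3 - before$srp_g_m3) / dspm else NA_real_,
       ratios_defined = isTRUE(ok))
}

#' Per-site event load from cores and bracketing water samples
#'
#' Runs the full site-level chain for one observed event: water-column
#' deltas, erosion depth from the core's thickness-weighted mean porosity,
#' resuspended mass, and sediment TP/BioP release over the eroded window.
#'
#' @param core A [sediment_core()] with P fractions and porosity (or dry bulk
#'   density) for the station.
#' @param before,after Bracketing [water_sample()] objects for the station.
#' @param constants A [be7_constants()] object (particle density).
#' @return One-row data frame: station, event dates, `delta_spm_g_m3`,
#'   `water_depth_m`, `erosion_depth_cm`, `m_resuspended_g_m2`,
#'   `tp_sediment_g_m2`, `biop_sediment_g_m2`, `delta_tp_water_g_m2`,
#'   `delta_srp_water_g_m2`, `tp_spm_ratio_mg_g`, `srp_spm_ratio_mg_g`.
#' @export
event_site_load <- function(core, before, after, constants = be7_constants()) {
  stopifnot(inherits(core, "sediment_core"))
  wc <- water_column_delta(before, after)
  phi <- core_mean_porosity(core, constants)
  D <- before$depth_m
  ed <- as.numeric(erosion_depth(wc$delta_spm_g_m3, D, phi,
                                 constants$particle_density))
  m <- as.numeric(mass_resuspended(wc$delta_spm_g_m3, D))
  rel <- sediment_p_release(core, ed, m)
  data.frame(station_id = before$station_id,
             date_before = format(before$date), date_after = format(after$date),
             delta_spm_g_m3 = wc$delta_spm_g_m3, water_depth_m = D,
             porosity = phi, erosion_depth_cm = ed, m_resuspended_g_m2 = m,
             tp_sediment_g_m2 = rel$TP_sediment,
             biop_sediment_g_m2 = rel$BioP_sediment,
             delta_tp_water_g_m2 = wc$delta_tp_g_m2,
             delta_srp_water_g_m2 = wc$delta_srp_g_m2,
             tp_spm_ratio_mg_g = wc$tp_spm_ratio_mg_g,
             srp_spm_ratio_mg_g = wc$srp_spm_ratio_mg_g)
}

#' Thickness-weighted mean porosity of a core
#'
#' Porosity per layer is taken as measured where present, otherwise derived
#' from dry bulk density via [porosity_from_bulk_density()].
#'
#' @param core A [sediment_core()].
#' @param constants A [be7_constants()] object.
#' @return Mean porosity weighted by layer thickness.
#' @export
core_mean_porosity <- function(core, constants = be7_constants()) {
  stopifnot(inherits(core, "sediment_core"))
  phi <- core$porosity
  rb <- core$rho_b_g_cm3
  fill <- is.na(phi) & !is.na(rb)
  if (any(fill))
    phi[fill] <- porosity_from_bulk_density(rb[fill], constants$particle_density)
  if (all(is.na(phi)))
    stop("core carries neither porosity nor dry bulk density", call. = FALSE)
  dz <- layer_thickness(core)
  keep <- !is.na(phi)
  sum(phi[keep] * dz[keep]) / sum(dz[keep])
}

#' Satellite-scaled phosphorus release concentration
#'
#' First-order scaling of sediment P to a remotely sensed SPM change:
#' \eqn{P_{scaled} = \bar P_{sediment} \times 10^{-3} \times \Delta SPM}, the
#' P carried by the resuspended sediment per unit water volume.
#'
#' @param p_bar_sediment Mean bed-sediment P concentration (mg g^-1, >= 0),
#'   averaged across sampled depths, stations and dates.
#' @param delta_spm SPM increase (g m^-3, >= 0).
#' @return Released P concentration in g m^-3; linear in both arguments.
#' @examples
#' scaled_p(1.0, 30)   # 0.03 g m-3
#' @export
scaled_p <- function(p_bar_sediment, delta_spm) {
  if (any(p_bar_sediment < 0, na.rm = TRUE) || any(delta_spm < 0, na.rm = TRUE))
    stop("scaled_p requires non-negative arguments", call. = FALSE)
  p_bar_sediment * 1e-3 * delta_spm
}

#' Basin-wide phosphorus load from a scene pair
#'
#' Applies the satellite scaling per resuspended pixel and integrates to a
#' basin total: for each masked pixel,
#' `scaled_p(p_bar, delta_spm) * depth * pixel_area` grams, summed and
#' converted to kg. Pixels outside the mask, with negative SPM change, or
#' with missing bathymetry are excluded and counted.
#'
#' @param pair A [scene_pair()] of SPM grids (g m^-3).
#' @param bathymetry An [spm_grid()] of water depths (m), co-registered with
#'   the scenes.
#' @param p_bar_TP,p_bar_BioP Mean bed-sediment total / bioavailable P
#'   concentrations (mg g^-1).
#' @param threshold_pct Resuspension classification threshold (percent); see
#'   [resuspension_mask()].
#' @param mask Optional logical matrix overriding the threshold
#'   classification.
#' @return An object of class `"basin_load"`: totals `TP_scaled_total_kg`
#'   and `BioP_scaled_total_kg`, `pixel_count`, `n_excluded`,
#'   `pixel_area_m2`, the echoed `p_bar` means, and per-pixel release grids
#'   `tp_release_g_m3` and `tp_release_g_m2` (and BioP counterparts).
#' @export
basin_load <- function(pair, bathymetry, p_bar_TP, p_bar_BioP,
                       threshold_pct = 13.9, mask = NULL) {
  stopifnot(inherits(pair, "scene_pair"), inherits(bathymetry, "spm_grid"))
  .check_same_geometry(pair$before, bathymetry, "scene and bathymetry grids")
  if (any(c(p_bar_TP, p_bar_BioP) < 0))
    stop("p_bar values must be >= 0", call. = FALSE)
  if (is.null(mask)) mask <- resuspension_mask(pair, threshold_pct)
  if (!identical(dim(mask), dim(bathymetry$values)))
    stop("mask shape does not match the grids", call. = FALSE)

  dspm <- delta_spm(pair)$values
  depth <- bathymetry$values
  usable <- mask & !is.na(dspm) & dspm > 0 & !is.na(depth)
  n_excluded <- sum(mask & !usable)
  area <- pixel_area(bathymetry)

  d_use <- ifelse(usable, dspm, NA_real_)
  tp_conc <- scaled_p(p_bar_TP, pmax(d_use, 0))        # g m-3
  biop_conc <- scaled_p(p_bar_BioP, pmax(d_use, 0))
  tp_areal <- tp_conc * depth                           # g m-2
  biop_areal <- biop_conc * depth

  mk_grid <- function(v) { g <- bathymetry; g$values <- v; g }
  structure(
    list(TP_scaled_total_kg = sum(tp_areal * area, na.rm = TRUE) / 1000,
         BioP_scaled_total_kg = sum(biop_areal * area, na.rm = TRUE) / 1000,
         pixel_count = sum(usable), n_excluded = n_excluded,
         pixel_area_m2 = area,
         mean_sediment_TP_mg_g = p_bar_TP, mean_sediment_BioP_mg_g = p_bar_BioP,
         threshold_pct = threshold_pct,
         tp_release_g_m3 = mk_grid(tp_conc), tp_release_g_m2 = mk_grid(tp_areal),
         biop_release_g_m3 = mk_grid(biop_conc),
         biop_release_g_m2 = mk_grid(biop_areal)),
    class = "basin_load")
}

#' @export
print.basin_load <- function(x, ...) {
  cat("Basin-wide resuspension P load\n")
  cat(sprintf("  TP mobilised:   %.4g kg\n", x$TP_scaled_total_kg))
  cat(sprintf("  BioP released:  %.4g kg\n", x$BioP_scaled_total_kg))
  cat(sprintf("  %d resuspended pixels (%.3g m2 each), %d excluded, threshold %.3g%%\n",
              x$pixel_count, x$pixel_area_m2, x$n_excluded, x$threshold_pct))
  cat(sprintf("  mean sediment TP %.3g, BioP %.3g mg g-1\n",
              x$mean_sediment_TP_mg_g, x$mean_sediment_BioP_mg_g))
  invisible(x)
}

#' Load as a percentage of a management target
#'
#' @param load_kg Estimated load (kg).
#' @param target_kg Target load (kg, > 0).
#' @return `100 * load_kg / target_kg`, percent.
#' @examples
#' percent_of_target(40314, 86e4)   # ~4.69
#' @export
percent_of_target <- function(load_kg, target_kg) {
  if (any(target_kg <= 0)) stop("target_kg must be > 0", call. = FALSE)
  100 * load_kg / target_kg
}

#' Fold comparison of event release against diffusive flux
#'
#' Bounds on how many times larger an episodic per-event release is than a
#' sustained diffusive flux, from the two ranges: the lower bound divides the
#' smallest release by the largest flux, the upper the largest release by the
#' smallest flux. Reported rounded to whole folds; unrounded values are kept
#' in the `"exact"` attribute.
#'
#' @param event_release_range Length-2 range of per-event release
#'   (g m^-2 event^-1, > 0).
#' @param diffusive_flux_range Length-2 range of diffusive flux
#'   (g m^-2 day^-1, > 0).
#' @return Named numeric `c(fold_min, fold_max)`, integers, with attribute
#'   `exact`.
#' @examples
#' diffusive_flux_comparison(c(2e-2, 11e-2), c(0.43e-3, 0.91e-3))  # 22, 256
#' @export
diffusive_flux_comparison <- function(event_release_range, diffusive_flux_range) {
  r <- sort(as.numeric(event_release_range))
  f <- sort(as.numeric(diffusive_flux_range))
  if (length(r) != 2L || length(f) != 2L || any(c(r, f) <= 0))
    stop("both ranges must be two positive bounds", call. = FALSE)
  exact <- c(fold_min = r[1L] / f[2L], fold_max = r[2L] / f[1L])
  structure(round(exact), exact = exact)
}
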