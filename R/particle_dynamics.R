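#' Steady-state beryllium-7 deposition flux
#'
#' At steady state the depositional flux of tracer-bearing particles balances
#' decay of the sediment inventory: \eqn{J_{sed} = \lambda I_{sed}}.
#'
#' @param I_sed Sediment inventory (dpm cm^-2, >= 0).
#' @param lambda Decay constant (day^-1, > 0).
#' @return Flux in dpm cm^-2 day^-1.
#' @examples
#' steady_state_flux(15.5, decay_constant(53.3))
#' @export
steady_state_flux <- function(I_sed, lambda) {
  if (any(I_sed < 0, na.rm = TRUE)) stop("I_sed must be >= 0", call. = FALSE)
  if (any(lambda <= 0)) stop("lambda must be > 0", call. = FALSE)
  lambda * I_sed
}

#' Water-column particle residence time
#'
#' Time suspended particles spend in the water column before settling,
#' from the standing stock of particle-bound tracer over its deposition flux:
#' \deqn{T_{res} = A_w D / (J_{sed} \times 10^4)}
#' with \eqn{A_w} in dpm m^-3, depth \eqn{D} in m and \eqn{J_{sed}} in
#' dpm cm^-2 day^-1 (the 10^4 converts cm^-2 to m^-2).
#'
#' @param A_w Volumetric SPM-bound activity (dpm m^-3, >= 0). Multiply
#'   dpm L^-1 by 1000 to convert.
#' @param D Water depth (m, >= 0).
#' @param J_sed Deposition flux (dpm cm^-2 day^-1, > 0).
#' @return Residence time in days.
#' @examples
#' particle_residence_time(210, 5, 0.13)   # ~0.81 d
#' @export
particle_residence_time <- function(A_w, D, J_sed) {
  if (any(J_sed <= 0)) stop("J_sed must be > 0", call. = FALSE)
  if (any(A_w < 0) || any(D < 0))
    stop("A_w and D must be >= 0", call. = FALSE)
  (A_w * D) / (J_sed * 1e4)
}

#' Particle settling rate
#'
#' @param D Water depth (m).
#' @param T_res Particle residence time (days, > 0).
#' @return Settling rate in m day^-1; satisfies
#'   `settling_rate(D, T_res) * T_res == D`.
#' @examples
#' settling_rate(5, 0.8077)
#' @export
settling_rate <- function(D, T_res) {
  if (any(T_res <= 0)) stop("T_res must be > 0", call. = FALSE)
  D / T_res
}

#' Depositional flux from an inventory pair
#'
#' Time-averaged beryllium-7 depositional flux between two sampling dates,
#' correcting the first inventory for radioactive decay:
#' \deqn{J_{Be} = \lambda [I_2 - I_1 e^{-\lambda t}] / (1 - e^{-\lambda t}).}
#' A negative value means the inventory declined faster than decay alone —
#' net removal of tracer-bearing sediment (erosion); such intervals are
#' returned as-is with attribute `net_erosion = TRUE`, never clamped.
#'
#' @param I1,I2 Inventories at the first and second date (dpm cm^-2, >= 0).
#' @param t Days between the dates (> 0).
#' @param lambda Decay constant (day^-1, > 0).
#' @return Flux in dpm cm^-2 day^-1 with logical attribute `net_erosion`.
#' @examples
#' depositional_flux(5, 6, 30, 0.013)   # 0.10525
#' @export
depositional_flux <- function(I1, I2, t, lambda) {
  if (any(t <= 0)) stop("t must be > 0 days", call. = FALSE)
  if (any(I1 < 0) || any(I2 < 0)) stop("inventories must be >= 0", call. = FALSE)
  if (any(lambda <= 0)) stop("lambda must be > 0", call. = FALSE)
  decay <- exp(-lambda * t)
  J <- lambda * (I2 - I1 * decay) / (1 - decay)
  structure(J, net_erosion = J < 0)
}

#' Sediment mass accumulation rate
#'
#' Converts a beryllium-7 depositional flux to a sediment mass flux using the
#' mass-specific activity of suspended particles:
#' \eqn{AR = (J_{Be} / A_{spm}) \times 365} in g cm^-2 yr^-1. A negative
#' flux propagates to a negative rate (flagged), carrying the net-erosion
#' interpretation.
#'
#' @param J_Be Depositional flux (dpm cm^-2 day^-1).
#' @param A_spm Mass-specific SPM activity (dpm g^-1, > 0).
#' @param days_per_year Conversion constant (default 365).
#' @return Accumulation rate in g cm^-2 yr^-1 with attribute `net_erosion`.
#' @examples
#' accumulation_rate(0.10525, 20)   # ~1.92 g cm-2 yr-1
#' @export
accumulation_rate <- function(J_Be, A_spm, days_per_year = 365) {
  if (any(A_spm <= 0)) stop("A_spm must be > 0", call. = FALSE)
  ar <- as.numeric(J_Be) / A_spm * days_per_year
  structure(ar, net_erosion = ar < 0)
}

#' Particle dynamics metrics for one station
#'
#' Convenience wrapper combining the flux, residence-time and settling-rate
#' calculations for a fitted core and a co-located water sample.
#'
#' @param fit A [be7_fit()].
#' @param water A [water_sample()] with `be7_dpm_m3` present.
#' @return A one-row data frame: `station_id`, `J_sed`, `T_res_days`,
#'   `settling_m_day`.
#' @export
particle_dynamics <- function(fit, water) {
  stopifnot(inherits(fit, "be7_fit"), inherits(water, "water_sample"))
  if (is.na(water$be7_dpm_m3))
    stop("water sample lacks volumetric Be-7 activity", call. = FALSE)
  J <- steady_state_flux(fit$inventory, fit$lambda)
  Tres <- particle_residence_time(water$be7_dpm_m3, water$depth_m, J)
  data.frame(station_id = water$station_id, J_sed = J, T_res_days = Tres,
             settling_m_day = if (Tres > 0) settling_rate(water$depth_m, Tres)
                              else NA_real_)
}
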