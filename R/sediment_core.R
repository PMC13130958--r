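#' Sediment core with layered beryllium-7 and phosphorus data
#'
#' Constructs a validated sediment core: an ordered, contiguous stack of
#' layers below the sediment-water interface, each carrying a depth-integrated
#' beryllium-7 activity, up to five sequential-extraction phosphorus
#' fractions, porosity and/or dry bulk density. Depths are centimetres below
#' the interface; layers are half-open intervals `[top_cm, bottom_cm)` stored
#' surface-down with the first top at 0.
#'
#' Missing measurements are `NA`, never silently zero: zero is a legitimate
#' measured value for activities and fractions.
#'
#' @param station_id Station label.
#' @param date Sampling date (`Date` or ISO-8601 string).
#' @param water_depth Water column depth at the station (m, > 0). May be `NA`
#'   when only the sediment profile is used.
#' @param layers A data frame with columns `top_cm`, `bottom_cm` and any of
#'   `be7_dpm_cm2` (layer-integrated activity, dpm cm^-2), the five P
#'   fractions `p_loose_mg_g`, `p_redox_mg_g`, `p_alfe_mg_g`, `p_ca_mg_g`,
#'   `p_org_mg_g` (mg P per g dry sediment), `porosity` (fraction in [0, 1))
#'   and `rho_b_g_cm3` (dry bulk density, g cm^-3).
#' @param constants A [be7_constants()] object; used to cross-check porosity
#'   against dry bulk density (`rho_b = rho_d * (1 - porosity)` to 1e-6
#'   relative) where both are present.
#' @return An object of class `"sediment_core"`: the layer data frame with
#'   attributes `station_id`, `date` and `water_depth`.
#' @examples
#' core <- sediment_core("WLE1", "2023-04-15", 7,
#'   data.frame(top_cm = 0:4, bottom_cm = 1:5,
#'              be7_dpm_cm2 = c(8, 4, 2, 1, 0.5)))
#' layer_midpoints(core)
#' @export
sediment_core <- function(station_id, date, water_depth = NA_real_, layers,
                          constants = be7_constants()) {
  stopifnot(is.data.frame(layers), nrow(layers) >= 1L)
  if (!all(c("top_cm", "bottom_cm") %in% names(layers)))
    stop("layers must have 'top_cm' and 'bottom_cm' columns", call. = FALSE)

  optional <- c("be7_dpm_cm2", "p_loose_mg_g", "p_redox_mg_g", "p_alfe_mg_g",
                "p_ca_mg_g", "p_org_mg_g", "porosity", "rho_b_g_cm3")
  for (col in optional) {
    if (!col %in% names(layers)) layers[[col]] <- NA_real_
    layers[[col]] <- as.numeric(layers[[col]])
  }
  layers <- layers[c("top_cm", "bottom_cm", optional)]
  layers <- layers[order(layers$top_cm), , drop = FALSE]
  rownames(layers) <- NULL

  top <- layers$top_cm; bot <- layers$bottom_cm
  if (any(!is.finite(top)) || any(!is.finite(bot)))
    stop("layer boundaries must be finite", call. = FALSE)
  if (any(top < 0) || any(bot <= top))
    stop("layers require 0 <= top_cm < bottom_cm", call. = FALSE)
  if (abs(top[1L]) > 1e-12)
    stop("first layer must start at the sediment-water interface (top_cm = 0)",
         call. = FALSE)
  if (nrow(layers) > 1L &&
      any(abs(top[-1L] - bot[-nrow(layers)]) > 1e-9))
    stop("layers must be contiguous: each top_cm must equal the previous bottom_cm",
         call. = FALSE)

  nonneg <- c("be7_dpm_cm2", "p_loose_mg_g", "p_redox_mg_g", "p_alfe_mg_g",
              "p_ca_mg_g", "p_org_mg_g")
  for (col in nonneg)
    if (any(layers[[col]] < 0, na.rm = TRUE))
      stop(sprintf("'%s' must be non-negative where present", col),
           call. = FALSE)
  phi <- layers$porosity
  if (any(phi < 0 | phi >= 1, na.rm = TRUE))
    stop("porosity must lie in [0, 1)", call. = FALSE)
  rb <- layers$rho_b_g_cm3
  if (any(rb <= 0, na.rm = TRUE))
    stop("dry bulk density must be positive where present", call. = FALSE)

  both <- which(!is.na(phi) & !is.na(rb))
  if (length(both)) {
    expect <- constants$particle_density * (1 - phi[both])
    bad <- abs(rb[both] - expect) > 1e-6 * pmax(abs(expect), 1e-300)
    if (any(bad))
      stop("porosity and dry bulk density are inconsistent with rho_b = rho_d * (1 - porosity) in layer(s) ",
           paste(both[bad], collapse = ", "), call. = FALSE)
  }

  if (!is.na(water_depth) && water_depth <= 0)
    stop("water_depth must be > 0", call. = FALSE)

  structure(layers,
            station_id = as.character(station_id),
            date = as.Date(date),
            water_depth = as.numeric(water_depth),
            class = c("sediment_core", "data.frame"))
}

#' @export
print.sediment_core <- function(x, ...) {
  cat(sprintf("Sediment core: station %s, %s (water depth %s m)\n",
              attr(x, "station_id"), format(attr(x, "date")),
              format(attr(x, "water_depth"))))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Layer midpoint depths of a core
#'
#' @param core A [sediment_core()].
#' @return Numeric vector of layer midpoint depths (cm).
#' @export
layer_midpoints <- function(core) {
  stopifnot(inherits(core, "sediment_core"))
  (core$top_cm + core$bottom_cm) / 2
}

#' Layer thicknesses of a core
#'
#' @param core A [sediment_core()].
#' @return Numeric vector of layer thicknesses (cm).
#' @export
layer_thickness <- function(core) {
  stopifnot(inherits(core, "sediment_core"))
  core$bottom_cm - core$top_cm
}

.p_fraction_cols <- c("p_loose_mg_g", "p_redox_mg_g", "p_alfe_mg_g",
                      "p_ca_mg_g", "p_org_mg_g")
.p_labile_cols <- c("p_loose_mg_g", "p_redox_mg_g", "p_alfe_mg_g")

.p_sum <- function(x, cols, what) {
  if (inherits(x, "sediment_core") || is.data.frame(x)) {
    df <- as.data.frame(x)
  } else if (is.list(x)) {
    df <- as.data.frame(x[intersect(names(x), .p_fraction_cols)])
  } else stop("x must be a sediment_core, data frame or named list",
              call. = FALSE)
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols))
    stop(sprintf("missing %s fraction column(s): %s", what,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  for (col in cols) {
    if (any(is.na(df[[col]])))
      stop(sprintf("missing value in fraction '%s' (row %s); fractions must be measured, not NA",
                   col, paste(which(is.na(df[[col]])), collapse = ", ")),
           call. = FALSE)
  }
  rowSums(df[, cols, drop = FALSE])
}

#' Total phosphorus of sediment layers
#'
#' Total P is the sum of the five sequential-extraction fractions: loosely
#' bound, redox-sensitive, Al/Fe oxide-bound, Ca-bound and residual organic P.
#' All five must be present; a missing fraction is an error (it cannot be
#' assumed zero).
#'
#' @param x A [sediment_core()], a data frame of layers, or a named list with
#'   the five fraction fields.
#' @return Total P per layer, mg P per g dry sediment.
#' @examples
#' total_p(list(p_loose_mg_g = 0.10, p_redox_mg_g = 0.20, p_alfe_mg_g = 0.30,
#'              p_ca_mg_g = 0.25, p_org_mg_g = 0.15))  # 1.0
#' @seealso [bioavailable_p()]
#' @export
total_p <- function(x) .p_sum(x, .p_fraction_cols, "total-P")

#' Bioavailable phosphorus of sediment layers
#'
#' Bioavailable P (BioP) is the labile part of total P: loosely bound +
#' redox-sensitive + Al/Fe oxide-bound fractions. The Ca-bound and residual
#' organic fractions do not contribute.
#'
#' @inheritParams total_p
#' @return BioP per layer, mg P per g dry sediment; always `<=` [total_p()]
#'   when all five fractions are present.
#' @examples
#' bioavailable_p(list(p_loose_mg_g = 0.10, p_redox_mg_g = 0.20,
#'                     p_alfe_mg_g = 0.30))  # 0.6
#' @export
bioavailable_p <- function(x) .p_sum(x, .p_labile_cols, "labile")

#' Porosity from dry bulk density
#'
#' Inverts the packing relation \eqn{\rho_b = \rho_d (1 - \phi)}:
#' \eqn{\phi = 1 - \rho_b / \rho_d}.
#'
#' @param rho_b Dry bulk density (g cm^-3), with `0 < rho_b <= rho_d`.
#' @param rho_d Particle density (g cm^-3), default 2.45.
#' @return Porosity, a fraction in [0, 1).
#' @examples
#' porosity_from_bulk_density(0.3675)        # 0.85
#' bulk_density_from_porosity(0.85)          # 0.3675
#' @export
porosity_from_bulk_density <- function(rho_b, rho_d = 2.45) {
  if (!is.numeric(rho_b) || !is.numeric(rho_d) || any(rho_d <= 0))
    stop("densities must be positive numbers", call. = FALSE)
  if (any(rho_b <= 0) || any(rho_b > rho_d))
    stop("rho_b must satisfy 0 < rho_b <= rho_d", call. = FALSE)
  1 - rho_b / rho_d
}

#' @rdname porosity_from_bulk_density
#' @param phi Porosity fraction in [0, 1).
#' @export
bulk_density_from_porosity <- function(phi, rho_d = 2.45) {
  if (!is.numeric(phi) || any(phi < 0 | phi >= 1))
    stop("phi must lie in [0, 1)", call. = FALSE)
  if (!is.numeric(rho_d) || any(rho_d <= 0))
    stop("rho_d must be positive", call. = FALSE)
  rho_d * (1 - phi)
}

#' Spatial coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean of a set
#' of station concentrations; the across-station variability summary used for
#' sediment P fractions.
#'
#' @param values Numeric vector of >= 2 concentrations with positive mean.
#' @return The coefficient of variation as a dimensionless fraction.
#' @examples
#' spatial_cv(c(1, 2, 3))   # 0.5
#' @export
spatial_cv <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("spatial_cv needs at least two values", call. = FALSE)
  if (anyNA(values)) stop("spatial_cv: values contain NA", call. = FALSE)
  m <- mean(values)
  if (m <= 0) stop("spatial_cv requires a positive mean", call. = FALSE)
  stats::sd(values) / m
}

#' Water-column sample
#'
#' A single station/date water-column observation: SPM, total and soluble
#' reactive phosphorus, and the beryllium-7 activity of suspended particles
#' (volumetric and mass-specific).
#'
#' @param station_id Station label.
#' @param date Sampling date.
#' @param depth_m Water column depth (m, > 0).
#' @param spm_g_m3 Suspended particulate matter (g m^-3).
#' @param tp_g_m3,srp_g_m3 Total and soluble reactive P (g m^-3).
#' @param be7_dpm_m3 Volumetric SPM-bound activity \eqn{A_w} (dpm m^-3);
#'   1 dpm L^-1 = 1000 dpm m^-3.
#' @param be7_dpm_g Mass-specific SPM activity \eqn{A_{spm}} (dpm g^-1).
#' @return An object of class `"water_sample"` (named list).
#' @examples
#' water_sample("WLE13", "2023-05-23", 5, spm_g_m3 = 12, tp_g_m3 = 0.05)
#' @export
water_sample <- function(station_id, date, depth_m,
                         spm_g_m3 = NA_real_, tp_g_m3 = NA_real_,
                         srp_g_m3 = NA_real_, be7_dpm_m3 = NA_real_,
                         be7_dpm_g = NA_real_) {
  vals <- c(spm_g_m3 = spm_g_m3, tp_g_m3 = tp_g_m3, srp_g_m3 = srp_g_m3,
            be7_dpm_m3 = be7_dpm_m3, be7_dpm_g = be7_dpm_g)
  if (any(vals < 0, na.rm = TRUE))
    stop("concentrations and activities must be non-negative where present",
         call. = FALSE)
  if (!is.finite(depth_m) || depth_m <= 0)
    stop("depth_m must be > 0", call. = FALSE)
  structure(list(station_id = as.character(station_id), date = as.Date(date),
                 depth_m = depth_m, spm_g_m3 = spm_g_m3, tp_g_m3 = tp_g_m3,
                 srp_g_m3 = srp_g_m3, be7_dpm_m3 = be7_dpm_m3,
                 be7_dpm_g = be7_dpm_g),
            class = "water_sample")
}

#' @export
print.water_sample <- function(x, ...) {
  cat(sprintf("Water sample: station %s, %s, depth %g m\n",
              x$station_id, format(x$date), x$depth_m))
  cat(sprintf("  SPM %s g m-3 | TP %s g m-3 | SRP %s g m-3 | A_w %s dpm m-3 | A_spm %s dpm g-1\n",
              format(x$spm_g_m3), format(x$tp_g_m3), format(x$srp_g_m3),
              format(x$be7_dpm_m3), format(x$be7_dpm_g)))
  invisible(x)
}
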