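# Seed scoping: generators are pure functions of (seed, parameters) and must
# not perturb the caller's RNG stream.
.with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Simulate a beryllium-7 sediment core
#'
#' Forward model of the steady-state decay-biodiffusion profile: layer
#' activities \eqn{A_T \exp(-k z_{mid}) \cdot \varepsilon} at layer midpoints,
#' with \eqn{k = \sqrt{\lambda / (D_b/365)}} and multiplicative lognormal
#' noise \eqn{\varepsilon = e^{N(0, \sigma)}} emulating the error structure
#' of activity counting. Bit-identical for identical seeds.
#'
#' @param A_T Interface activity (dpm cm^-2, > 0).
#' @param D_b Mixing coefficient (cm^2 yr^-1, > 0).
#' @param lambda Decay constant (day^-1, > 0).
#' @param n_layers Number of layers (>= 2).
#' @param layer_thickness Layer thickness (cm, > 0); default 1 cm slabs.
#' @param noise_sigma Lognormal sigma of the multiplicative noise (0 = exact).
#' @param seed RNG seed (required).
#' @param station_id,date,water_depth Core metadata; defaults mimic a shallow
#'   lacustrine station.
#' @param constants A [be7_constants()] object (validation only).
#' @return A [sediment_core()] with `be7_dpm_cm2` filled.
#' @examples
#' core <- simulate_be7_core(11.3137, 9.8797, decay_constant(53.3),
#'                           n_layers = 5, noise_sigma = 0, seed = 1)
#' core$be7_dpm_cm2   # 8, 4, 2, 1, 0.5
#' @export
simulate_be7_core <- function(A_T, D_b, lambda, n_layers = 5,
                              layer_thickness = 1, noise_sigma = 0, seed,
                              station_id = "SYN", date = "2023-05-01",
                              water_depth = 7.5,
                              constants = be7_constants()) {
  if (A_T <= 0 || D_b <= 0 || lambda <= 0 || layer_thickness <= 0 ||
      noise_sigma < 0)
    stop("A_T, D_b, lambda and layer_thickness must be positive; noise_sigma >= 0",
         call. = FALSE)
  if (n_layers < 2) stop("n_layers must be >= 2", call. = FALSE)
  k <- sqrt(lambda / (D_b / constants$days_per_year))
  top <- (seq_len(n_layers) - 1) * layer_thickness
  z_mid <- top + layer_thickness / 2
  eps <- .with_seed(seed, exp(stats::rnorm(n_layers, 0, noise_sigma)))
  act <- A_T * exp(-k * z_mid) * eps
  sediment_core(station_id, date, water_depth,
                data.frame(top_cm = top, bottom_cm = top + layer_thickness,
                           be7_dpm_cm2 = act),
                constants = constants)
}

#' Simulate near-depth-invariant phosphorus fraction profiles
#'
#' Generates per-layer sequential-extraction fractions around a base
#' composition with small, independent multiplicative perturbations
#' \eqn{(1 + \eta)}, \eqn{\eta \sim N(0, sd)}, truncated at zero — emulating
#' the low compositional variability with depth observed in actively mixed
#' surface sediments (relative SD typically below ~3.5%).
#'
#' @param base_fractions Named numeric vector of the five base fractions
#'   (mg g^-1, >= 0): `p_loose_mg_g`, `p_redox_mg_g`, `p_alfe_mg_g`,
#'   `p_ca_mg_g`, `p_org_mg_g`.
#' @param depth_rel_sd Relative standard deviation with depth (default
#'   0.035).
#' @param n_layers Number of layers.
#' @param seed RNG seed (required).
#' @return Data frame of `n_layers` rows with the five fraction columns.
#' @export
simulate_p_profiles <- function(base_fractions, depth_rel_sd = 0.035,
                                n_layers, seed) {
  cols <- .p_fraction_cols
  if (is.null(names(base_fractions))) names(base_fractions) <- cols
  if (!all(cols %in% names(base_fractions)))
    stop("base_fractions must name all five fractions", call. = FALSE)
  base <- as.numeric(base_fractions[cols])
  if (any(base < 0)) stop("base fractions must be >= 0", call. = FALSE)
  if (depth_rel_sd < 0) stop("depth_rel_sd must be >= 0", call. = FALSE)
  eta <- .with_seed(seed,
                    matrix(stats::rnorm(n_layers * length(cols), 0, depth_rel_sd),
                           nrow = n_layers))
  out <- pmax(matrix(base, n_layers, length(cols), byrow = TRUE) * (1 + eta), 0)
  stats::setNames(as.data.frame(out), cols)
}

#' Simulate an inventory time series under constant deposition
#'
#' Forward model inverted by [depositional_flux()]: starting from inventory
#' `I1`, decay plus a constant flux `J_true` for `t` days gives
#' \deqn{I_2 = I_1 e^{-\lambda t} + J (1 - e^{-\lambda t}) / \lambda.}
#'
#' @param I1 Initial inventory (dpm cm^-2, >= 0).
#' @param J_true Constant depositional flux (dpm cm^-2 day^-1, >= 0).
#' @param t Elapsed days (> 0).
#' @param lambda Decay constant (day^-1, > 0).
#' @return The later inventory `I2` (dpm cm^-2).
#' @examples
#' simulate_inventory_series(5, 0.10525, 30, 0.013)   # ~6.0
#' @export
simulate_inventory_series <- function(I1, J_true, t, lambda) {
  if (any(t <= 0)) stop("t must be > 0", call. = FALSE)
  if (any(I1 < 0) || any(J_true < 0) || any(lambda <= 0))
    stop("I1, J_true must be >= 0 and lambda > 0", call. = FALSE)
  decay <- exp(-lambda * t)
  I1 * decay + J_true * (1 - decay) / lambda
}

#' Simulate a resuspension event scene pair with known truth
#'
#' Builds a pre/post SPM grid pair where the post-event scene adds a Gaussian
#' resuspension plume to a uniform background, optionally with additive
#' normal pixel noise on both scenes, plus a co-registered bathymetry grid.
#' The ground truth (erosion depth, resuspended mass and P release per pixel;
#' basin totals) is computed from the same closed forms the analysis inverts,
#' on the noise-free fields and under the same classification threshold, so a
#' noise-free pipeline run must reproduce it. In situ water-sample pairs
#' consistent with the grids are drawn at the plume centre and a background
#' pixel.
#'
#' @param grid_shape `c(nrows, ncols)`.
#' @param pixel_size Pixel edge (m); default 300 m.
#' @param depth_m Bathymetry: a scalar or matrix (m); default 7.5 m, a
#'   shallow-basin mean depth.
#' @param background_spm Pre-event SPM (g m^-3).
#' @param plume List with `center` (row, col; default grid centre), `width`
#'   (Gaussian sigma in pixels; default 15% of the smaller grid dimension,
#'   so the event is basin-scale at any resolution) and `amplitude` (peak
#'   SPM increase, g m^-3, >= 0).
#' @param porosity Sediment porosity used for the truth erosion depths.
#' @param p_bar_TP,p_bar_BioP Mean sediment P concentrations (mg g^-1).
#' @param noise_sd Additive normal noise SD per scene pixel (g m^-3).
#' @param threshold_pct Classification threshold the truth totals use.
#' @param seed RNG seed (required).
#' @param constants A [be7_constants()] object.
#' @return A list: `pair` ([scene_pair()]), `bathymetry` ([spm_grid()]),
#'   `truth` (class `"synthetic_event_truth"`: noise-free `delta_spm`,
#'   `mask`, grids `erosion_depth_cm`, `m_resuspended_g_m2`,
#'   `tp_release_g_m2`, `biop_release_g_m2`, totals
#'   `TP_total_kg`/`BioP_total_kg`, the generating parameters and `seed`),
#'   and `water` (list of `before`/`after` [water_sample()] pairs).
#' @export
simulate_event <- function(grid_shape = c(50, 50), pixel_size = 300,
                           depth_m = 7.5, background_spm = 10,
                           plume = list(center = NULL, width = NULL,
                                        amplitude = 30),
                           porosity = 0.85, p_bar_TP = 1.0, p_bar_BioP = 0.4,
                           noise_sd = 0, threshold_pct = 13.9, seed,
                           constants = be7_constants()) {
  nr <- as.integer(grid_shape[1L]); nc <- as.integer(grid_shape[2L])
  if (nr < 1 || nc < 1) stop("grid_shape must be positive", call. = FALSE)
  if (background_spm <= 0) stop("background_spm must be > 0", call. = FALSE)
  if (is.null(plume$center)) plume$center <- c((nr + 1) / 2, (nc + 1) / 2)
  if (is.null(plume$width)) plume$width <- 0.15 * min(nr, nc)
  if (plume$amplitude < 0) stop("plume amplitude must be >= 0", call. = FALSE)
  if (porosity < 0 || porosity >= 1) stop("porosity must lie in [0, 1)", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)

  depth <- if (is.matrix(depth_m)) depth_m else matrix(depth_m, nr, nc)
  if (!identical(dim(depth), c(nr, nc)))
    stop("bathymetry shape does not match grid_shape", call. = FALSE)
  if (any(depth <= 0, na.rm = TRUE))
    stop("bathymetry depths must be > 0", call. = FALSE)

  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  plume_true <- plume$amplitude *
    exp(-((rr - plume$center[1L])^2 + (cc - plume$center[2L])^2) /
          (2 * plume$width^2))

  before_true <- matrix(background_spm, nr, nc)
  after_true <- before_true + plume_true

  noise <- .with_seed(seed, list(
    b = matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc),
    a = matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc)))

  g <- function(v) spm_grid(v, cellsize = pixel_size)
  pair <- scene_pair(g(pmax(before_true + noise$b, 0)),
                     g(pmax(after_true + noise$a, 0)),
                     date_before = "2023-05-18", date_after = "2023-05-26")
  bathy <- g(depth)

  # truth on the noise-free fields, same classification rule as the pipeline
  mask <- 100 * plume_true / before_true > threshold_pct
  dspm_m <- ifelse(mask, plume_true, NA_real_)
  ed <- as.numeric(erosion_depth(ifelse(mask, plume_true, 0), depth, porosity,
                                 constants$particle_density))
  ed <- matrix(ed, nr, nc)
  m_res <- ifelse(mask, plume_true * depth, 0)
  tp_areal <- ifelse(mask, scaled_p(p_bar_TP, plume_true) * depth, 0)
  biop_areal <- ifelse(mask, scaled_p(p_bar_BioP, plume_true) * depth, 0)
  area <- pixel_size^2

  truth <- structure(
    list(delta_spm = g(dspm_m), mask = mask,
         erosion_depth_cm = g(ed), m_resuspended_g_m2 = g(m_res),
         tp_release_g_m2 = g(tp_areal), biop_release_g_m2 = g(biop_areal),
         TP_total_kg = sum(tp_areal) * area / 1000,
         BioP_total_kg = sum(biop_areal) * area / 1000,
         porosity = porosity, p_bar_TP = p_bar_TP, p_bar_BioP = p_bar_BioP,
         threshold_pct = threshold_pct, pixel_area_m2 = area, seed = seed),
    class = "synthetic_event_truth")

  station_pix <- list(PLUME = round(plume$center), BACKGROUND = c(1L, 1L))
  water <- lapply(names(station_pix), function(sid) {
    px <- station_pix[[sid]]
    d <- depth[px[1L], px[2L]]
    spm_b <- before_true[px[1L], px[2L]]
    dsp <- plume_true[px[1L], px[2L]]
    tp_b <- 0.05; srp_b <- 0.01
    list(before = water_sample(sid, pair$date_before, d, spm_g_m3 = spm_b,
                               tp_g_m3 = tp_b, srp_g_m3 = srp_b),
         after = water_sample(sid, pair$date_after, d, spm_g_m3 = spm_b + dsp,
                              tp_g_m3 = tp_b + scaled_p(p_bar_TP, dsp),
                              srp_g_m3 = srp_b + scaled_p(p_bar_BioP, dsp)))
  })
  names(water) <- names(station_pix)

  list(pair = pair, bathymetry = bathy, truth = truth, water = water)
}
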