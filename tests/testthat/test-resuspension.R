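test_that("erosion depth matches hand arithmetic and clamps deposition", {
  expect_equal(as.numeric(erosion_depth(30, 7, 0.85)), 0.05714,
               tolerance = 1e-3)
  expect_equal(as.numeric(erosion_depth(0, 7, 0.85)), 0)
  ed <- erosion_depth(-5, 7, 0.85)
  expect_equal(as.numeric(ed), 0)
  expect_true(attr(ed, "no_erosion"))
  expect_error(erosion_depth(30, 7, 1), "phi")
  expect_error(erosion_depth(30, 0, 0.85), "D must")
})

test_that("erosion depth is monotone in its drivers", {
  dspm <- seq(1, 100, length.out = 25)
  expect_true(all(diff(as.numeric(erosion_depth(dspm, 7, 0.85))) > 0))
  depths <- seq(1, 12, length.out = 25)
  expect_true(all(diff(as.numeric(erosion_depth(30, depths, 0.85))) > 0))
  # decreasing in dry bulk density rho_d * (1 - phi)
  phis <- seq(0.1, 0.95, length.out = 25)   # increasing phi -> lower rho_b
  expect_true(all(diff(as.numeric(erosion_depth(30, 7, phis))) > 0))
  rhods <- seq(1.5, 3, length.out = 25)
  expect_true(all(diff(as.numeric(erosion_depth(30, 7, 0.85, rhods))) < 0))
})

test_that("resuspended mass and the consistency chain with erosion depth", {
  expect_equal(as.numeric(mass_resuspended(30, 7)), 210)
  expect_equal(as.numeric(mass_resuspended(0, 7)), 0)
  expect_true(attr(mass_resuspended(-3, 7), "no_erosion"))
  # M / ED = rho_d (1 - phi) in g cm-3 after the 1e4 cm2/m2 conversion
  set.seed(13)
  for (i in 1:25) {
    dspm <- runif(1, 1, 80); D <- runif(1, 2, 12); phi <- runif(1, 0.5, 0.95)
    m <- as.numeric(mass_resuspended(dspm, D))
    ed <- as.numeric(erosion_depth(dspm, D, phi))
    expect_equal(m / (ed * 1e4), 2.45 * (1 - phi), tolerance = 1e-12)
  }
})

test_that("thickness-weighted P matches hand case and brute-force oracle", {
  expect_equal(depth_weighted_p(c(1.0, 0.8, 0.6), c(1, 1, 1), 1.5), 0.93333,
               tolerance = 1e-4)
  expect_equal(depth_weighted_p(rep(0.7, 5), rep(1, 5), 3.2), 0.7)
  expect_error(depth_weighted_p(c(1, 1, 1, 1, 1), rep(1, 5), 6),
               "exceeds sampled profile")
  expect_error(depth_weighted_p(c(1, 1), c(1, 1), 0), "ED must be")

  # brute-force 0.01 cm sub-layer discretization oracle
  brute <- function(p, dz, ED) {
    sub <- 0.01
    edges <- seq(sub / 2, ED - sub / 2 + 1e-12, by = sub)
    idx <- findInterval(edges, cumsum(dz), left.open = TRUE) + 1L
    mean(p[idx])
  }
  set.seed(17)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    p <- runif(n, 0.2, 2)
    dz <- rep(1, n)
    ED <- round(runif(1, 0.01, n), 2)   # multiple of 0.01 so the oracle tiles exactly
    expect_equal(depth_weighted_p(p, dz, ED), brute(p, dz, ED),
                 tolerance = 1e-9)
    expect_gte(depth_weighted_p(p, dz, ED) + 1e-12, min(p))
    expect_lte(depth_weighted_p(p, dz, ED) - 1e-12, max(p))
  }
})

test_that("sediment P release combines weighted P and resuspended mass", {
  core <- exp_core(with_p = TRUE)
  rel <- sediment_p_release(core, 1.5, 210)
  expect_equal(rel$TP_sediment, 1.0 * 210 * 1e-3, tolerance = 1e-9)
  expect_equal(rel$BioP_sediment, 0.6 * 210 * 1e-3, tolerance = 1e-9)
  expect_gte(rel$TP_sediment, rel$BioP_sediment)
  expect_equal(sediment_p_release(core, 1.5, 0),
               list(TP_sediment = 0, BioP_sediment = 0))
  # graded profile reproduces the documented hand case
  layers <- data.frame(top_cm = 0:2, bottom_cm = 1:3,
                       p_loose_mg_g = c(1.0, 0.8, 0.6) / 3,
                       p_redox_mg_g = c(1.0, 0.8, 0.6) / 3,
                       p_alfe_mg_g = c(1.0, 0.8, 0.6) / 3,
                       p_ca_mg_g = 0, p_org_mg_g = 0)
  graded <- sediment_core("S", "2023-05-01", 7, layers)
  rel2 <- sediment_p_release(graded, 1.5, 210)
  expect_equal(rel2$TP_sediment, 0.1960, tolerance = 1e-3)
  expect_equal(rel2$TP_sediment, rel2$BioP_sediment)  # all P labile here
})

test_that("water-column deltas integrate over depth and ratio correctly", {
  b <- water_sample("WLE13", "2023-05-18", 7, spm_g_m3 = 10, tp_g_m3 = 0.05,
                    srp_g_m3 = 0.010)
  a <- water_sample("WLE13", "2023-05-26", 7, spm_g_m3 = 34, tp_g_m3 = 0.08,
                    srp_g_m3 = 0.016)
  wc <- water_column_delta(b, a)
  expect_equal(wc$delta_tp_g_m2, 0.21, tolerance = 1e-9)
  expect_equal(wc$delta_spm_g_m3, 24)
  expect_equal(wc$tp_spm_ratio_mg_g, 1.25, tolerance = 1e-9)
  expect_true(wc$ratios_defined)
  same <- water_column_delta(b, water_sample("WLE13", "2023-05-26", 7,
                                             spm_g_m3 = 10, tp_g_m3 = 0.05,
                                             srp_g_m3 = 0.010))
  expect_equal(same$delta_spm_g_m3, 0)
  expect_equal(same$delta_tp_g_m2, 0)
  expect_false(same$ratios_defined)
  expect_true(is.na(same$tp_spm_ratio_mg_g))
  other <- water_sample("WLE14", "2023-05-26", 7, spm_g_m3 = 20)
  expect_error(water_column_delta(b, other), "different stations")
  expect_error(water_column_delta(a, b), "postdate")
})

test_that("satellite scaling is linear and matches hand arithmetic", {
  expect_equal(scaled_p(1.0, 30), 0.03)
  expect_equal(scaled_p(1.0, 0), 0)
  expect_equal(scaled_p(2.0, 30), 2 * scaled_p(1.0, 30))
  expect_equal(scaled_p(1.0, 60), 2 * scaled_p(1.0, 30))
  expect_error(scaled_p(-1, 30), "non-negative")
})

test_that("basin load integrates masked pixels and is additive", {
  # single masked pixel: dSPM 10 g m-3, depth 7 m, 300 m pixels, TP 1 mg/g
  before <- matrix(c(100, 100), 1); after <- matrix(c(110, 100), 1)
  pair <- tiny_pair(before, after)
  bathy <- spm_grid(matrix(7, 1, 2), 300)
  mask <- matrix(c(TRUE, FALSE), 1)
  bl <- basin_load(pair, bathy, 1.0, 0.4, mask = mask)
  expect_equal(bl$TP_scaled_total_kg, 6.3, tolerance = 1e-9)
  expect_equal(bl$BioP_scaled_total_kg, 6.3 * 0.4, tolerance = 1e-9)
  expect_equal(bl$pixel_count, 1L)
  expect_equal(bl$pixel_area_m2, 9e4)

  # empty mask
  bl0 <- basin_load(pair, bathy, 1.0, 0.4, mask = matrix(FALSE, 1, 2))
  expect_equal(bl0$TP_scaled_total_kg, 0)

  # two identical pixels double one
  pair2 <- tiny_pair(matrix(100, 1, 2), matrix(130, 1, 2))
  bl2 <- basin_load(pair2, bathy, 1.0, 0.4)
  bl1 <- basin_load(pair2, bathy, 1.0, 0.4,
                    mask = matrix(c(TRUE, FALSE), 1))
  expect_equal(bl2$TP_scaled_total_kg, 2 * bl1$TP_scaled_total_kg)

  # additivity over disjoint masks
  m1 <- matrix(c(TRUE, FALSE), 1); m2 <- matrix(c(FALSE, TRUE), 1)
  expect_equal(basin_load(pair2, bathy, 1, 0.4, mask = m1)$TP_scaled_total_kg +
                 basin_load(pair2, bathy, 1, 0.4, mask = m2)$TP_scaled_total_kg,
               bl2$TP_scaled_total_kg, tolerance = 1e-12)

  # geometry mismatch
  expect_error(basin_load(pair2, spm_grid(matrix(7, 2, 2), 300), 1, 0.4),
               "shape")
  # missing bathymetry excluded and counted
  bathy_na <- spm_grid(matrix(c(7, NA), 1), 300)
  bln <- basin_load(pair2, bathy_na, 1, 0.4)
  expect_equal(bln$n_excluded, 1L)
  expect_equal(bln$TP_scaled_total_kg, bl1$TP_scaled_total_kg)
})

test_that("percent of target and diffusive-flux folds reproduce reporting", {
  expect_equal(percent_of_target(40314, 86e4), 4.69, tolerance = 1e-3)
  expect_equal(percent_of_target(12665, 18.6e4), 6.81, tolerance = 1e-3)
  expect_equal(percent_of_target(5, 5), 100)
  expect_error(percent_of_target(10, 0), "target")

  folds <- diffusive_flux_comparison(c(2e-2, 11e-2), c(0.43e-3, 0.91e-3))
  expect_equal(as.numeric(folds), c(22, 256))
  sym <- diffusive_flux_comparison(c(2, 8), c(2, 8))
  expect_equal(attr(sym, "exact")[["fold_min"]],
               1 / attr(sym, "exact")[["fold_max"]])
  pt <- diffusive_flux_comparison(c(6, 6), c(3, 3))
  expect_equal(as.numeric(pt), c(2, 2))
  expect_error(diffusive_flux_comparison(c(0, 1), c(1, 2)), "positive")
})

test_that("event_site_load runs the full site-level chain", {
  core <- exp_core(with_p = TRUE, porosity = 0.85)
  b <- water_sample("WLE1", "2023-05-18", 7, spm_g_m3 = 10, tp_g_m3 = 0.05,
                    srp_g_m3 = 0.01)
  a <- water_sample("WLE1", "2023-05-26", 7, spm_g_m3 = 40, tp_g_m3 = 0.08,
                    srp_g_m3 = 0.02)
  row <- event_site_load(core, b, a)
  expect_equal(row$delta_spm_g_m3, 30)
  expect_equal(row$erosion_depth_cm, 0.05714, tolerance = 1e-3)
  expect_equal(row$m_resuspended_g_m2, 210)
  expect_equal(row$tp_sediment_g_m2, 0.210, tolerance = 1e-9) # uniform 1 mg/g
  expect_gte(row$tp_sediment_g_m2, row$biop_sediment_g_m2)
})

test_that("core mean porosity is thickness weighted and falls back to rho_b", {
  layers <- data.frame(top_cm = c(0, 1), bottom_cm = c(1, 3),
                       porosity = c(0.9, 0.6))
  core <- sediment_core("S", "2023-05-01", 7, layers)
  expect_equal(core_mean_porosity(core), (0.9 * 1 + 0.6 * 2) / 3)
  layers2 <- data.frame(top_cm = c(0, 1), bottom_cm = c(1, 2),
                        rho_b_g_cm3 = c(0.3675, 0.3675))
  expect_equal(core_mean_porosity(sediment_core("S", "2023-05-01", 7, layers2)),
               0.85)
  bare <- sediment_core("S", "2023-05-01", 7,
                        data.frame(top_cm = 0, bottom_cm = 1))
  expect_error(core_mean_porosity(bare), "neither porosity")
})
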