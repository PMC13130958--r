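# Shared fixtures, built in code.

# Exponential five-layer core: A_T = 11.3137 dpm cm-2, k = ln(2) cm-1 gives
# activities (8, 4, 2, 1, 0.5) at midpoints 0.5..4.5 cm.
exp_core <- function(with_p = FALSE, porosity = NA_real_) {
  layers <- data.frame(top_cm = 0:4, bottom_cm = 1:5,
                       be7_dpm_cm2 = c(8, 4, 2, 1, 0.5))
  if (with_p) {
    layers$p_loose_mg_g <- rep(0.10, 5)
    layers$p_redox_mg_g <- rep(0.20, 5)
    layers$p_alfe_mg_g  <- rep(0.30, 5)
    layers$p_ca_mg_g    <- rep(0.25, 5)
    layers$p_org_mg_g   <- rep(0.15, 5)
  }
  if (!is.na(porosity)) layers$porosity <- porosity
  sediment_core("WLE1", "2023-04-15", 7, layers)
}

one_layer_fracs <- function(loose = 0.10, redox = 0.20, alfe = 0.30,
                            ca = 0.25, org = 0.15) {
  list(p_loose_mg_g = loose, p_redox_mg_g = redox, p_alfe_mg_g = alfe,
       p_ca_mg_g = ca, p_org_mg_g = org)
}

# Two-scene pair on a tiny grid from explicit before/after matrices.
tiny_pair <- function(before, after, cellsize = 300) {
  scene_pair(spm_grid(before, cellsize), spm_grid(after, cellsize),
             "2023-05-18", "2023-05-26")
}
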