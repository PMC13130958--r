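lam533 <- decay_constant(53.3)

test_that("decay constant and mean lifetime follow ln(2) arithmetic", {
  expect_equal(decay_constant(53.3), 0.013005, tolerance = 1e-4)
  expect_equal(mean_lifetime(53.3), 53.3 / log(2))
  expect_gt(mean_lifetime(53), 76); expect_lt(mean_lifetime(53.3), 77.5)
  expect_equal(decay_constant(2 * 53.3), decay_constant(53.3) / 2)
  expect_error(decay_constant(0), "positive")
})

test_that("inventory sums measured layers and counts exclusions", {
  expect_equal(as.numeric(be7_inventory(exp_core())), 15.5)
  one <- sediment_core("S", "2023-01-01", 5,
                       data.frame(top_cm = 0, bottom_cm = 1, be7_dpm_cm2 = 3))
  expect_equal(as.numeric(be7_inventory(one)), 3)
  gap <- sediment_core("S", "2023-01-01", 5,
                       data.frame(top_cm = 0:2, bottom_cm = 1:3,
                                  be7_dpm_cm2 = c(2, NA, 1)))
  inv <- be7_inventory(gap)
  expect_equal(as.numeric(inv), 3)
  expect_equal(attr(inv, "n_excluded"), 1L)
  zeros <- sediment_core("S", "2023-01-01", 5,
                         data.frame(top_cm = 0:1, bottom_cm = 1:2,
                                    be7_dpm_cm2 = c(0, 0)))
  expect_equal(as.numeric(be7_inventory(zeros)), 0)
  none <- sediment_core("S", "2023-01-01", 5,
                        data.frame(top_cm = 0, bottom_cm = 1))
  expect_error(be7_inventory(none), "no beryllium-7")
})

test_that("mixing-profile fit recovers noise-free parameters exactly", {
  fit <- be7_fit(exp_core())
  expect_equal(fit$k, log(2), tolerance = 1e-6)
  expect_equal(fit$A_T, 11.3137, tolerance = 1e-4)
  expect_equal(fit$D_b, be7_constants()$lambda / log(2)^2 * 365,
               tolerance = 1e-6)
  expect_equal(fit$D_b, 9.88, tolerance = 1e-3)
  expect_equal(fit$n_layers_used, 5L)
  expect_lt(fit$rss_log, 1e-20)
})

test_that("flat and inverted profiles are flagged, never negative D_b", {
  flat <- sediment_core("S", "2023-01-01", 5,
                        data.frame(top_cm = 0:3, bottom_cm = 1:4,
                                   be7_dpm_cm2 = rep(2, 4)))
  f <- be7_fit(flat)
  expect_true("non_attenuating_profile" %in% f$flags)
  expect_identical(f$k, 0)
  expect_identical(f$D_b, Inf)
  inc <- sediment_core("S", "2023-01-01", 5,
                       data.frame(top_cm = 0:3, bottom_cm = 1:4,
                                  be7_dpm_cm2 = c(1, 2, 4, 8)))
  expect_true("non_attenuating_profile" %in% be7_fit(inc)$flags)
})

test_that("fit excludes non-positive layers and requires two positive ones", {
  holey <- sediment_core("S", "2023-01-01", 5,
                         data.frame(top_cm = 0:3, bottom_cm = 1:4,
                                    be7_dpm_cm2 = c(8, 0, 2, NA)))
  f <- be7_fit(holey)
  expect_equal(f$n_layers_used, 2L)
  expect_equal(f$n_excluded, 2L)
  expect_true("layers_excluded" %in% f$flags)
  thin <- sediment_core("S", "2023-01-01", 5,
                        data.frame(top_cm = 0:1, bottom_cm = 1:2,
                                   be7_dpm_cm2 = c(8, 0)))
  expect_error(be7_fit(thin), "at least two")
})

test_that("D_b recovery under 10% lognormal noise: median error < 15% over 200 seeds", {
  lam <- lam533
  errs <- vapply(1:200, function(s) {
    core <- simulate_be7_core(A_T = 12, D_b = 50, lambda = lam, n_layers = 5,
                              noise_sigma = 0.1, seed = s)
    abs(be7_fit(core)$D_b - 50) / 50
  }, 0)
  expect_lt(median(errs), 0.15)
})

test_that("be7_fit methods are mutually consistent", {
  fit <- be7_fit(exp_core())
  expect_named(coef(fit), c("A_T", "k"))
  expect_equal(predict(fit, 0), fit$A_T)
  expect_equal(fitted(fit), exp(fit$log_activity), tolerance = 1e-9)
  expect_equal(sum(residuals(fit, "response")^2), 0, tolerance = 1e-18)
  sims <- simulate(fit, nsim = 3, seed = 9)
  expect_equal(dim(sims), c(5L, 3L))
  expect_identical(simulate(fit, nsim = 3, seed = 9), sims)
  expect_output(print(fit), "mixing profile fit")
  expect_output(print(summary(fit)), "fitted_dpm_cm2")
  tab <- be7_results_table(fit)
  expect_equal(tab$I_sed, 15.5)
  expect_equal(tab$J_sed, lam533 * 15.5)
})

test_that("mixing depth follows sqrt(D_b tau) and is monotone in both", {
  expect_equal(mixing_depth(0, 77), 0)
  expect_equal(mixing_depth(70.51, 77), 3.86, tolerance = 1e-3)
  expect_equal(mixing_depth(200, 77), 6.50, tolerance = 1e-3)
  expect_error(mixing_depth(-1, 77), "D_b")
  expect_error(mixing_depth(10, 0), "tau")
  db <- seq(1, 200, length.out = 20)
  expect_true(all(diff(mixing_depth(db, 77)) > 0))
  taus <- seq(10, 150, length.out = 20)
  expect_true(all(diff(mixing_depth(70, taus)) > 0))
})

test_that("steady-state flux is linear in inventory", {
  expect_equal(steady_state_flux(15.5, 0.013005), 0.20158, tolerance = 1e-4)
  expect_equal(steady_state_flux(0, lam533), 0)
  expect_equal(steady_state_flux(2 * 15.5, lam533),
               2 * steady_state_flux(15.5, lam533))
  expect_error(steady_state_flux(-1, lam533), "I_sed")
})

test_that("residence time, settling rate and their identities", {
  Tres <- particle_residence_time(210, 5, 0.13)
  expect_equal(Tres, 0.808, tolerance = 1e-3)
  expect_equal(particle_residence_time(0, 5, 0.13), 0)
  expect_error(particle_residence_time(210, 5, 0), "J_sed")
  # unit invariance: dpm L-1 * 1000 = dpm m-3
  expect_equal(particle_residence_time(0.21 * 1000, 5, 0.13), Tres)
  expect_equal(settling_rate(5, Tres), 6.19, tolerance = 1e-3)
  expect_error(settling_rate(5, 0), "T_res")
  # settling_rate x T_res = D, and the closed form J*1e4/A_w
  set.seed(3)
  for (i in 1:25) {
    A_w <- runif(1, 10, 500); D <- runif(1, 2, 12); J <- runif(1, 0.01, 0.5)
    Tr <- particle_residence_time(A_w, D, J)
    expect_equal(settling_rate(D, Tr) * Tr, D, tolerance = 1e-12)
    expect_equal(settling_rate(D, Tr), J * 1e4 / A_w, tolerance = 1e-12)
  }
})

test_that("depositional flux inverts its forward model and flags erosion", {
  expect_equal(as.numeric(depositional_flux(5, 6, 30, 0.013)), 0.10525,
               tolerance = 1e-4)
  # pure-decay null
  expect_equal(as.numeric(depositional_flux(5, 5 * exp(-0.013 * 30), 30, 0.013)),
               0, tolerance = 1e-12)
  # algebraic inversion oracle across random parameters
  set.seed(5)
  for (i in 1:25) {
    I1 <- runif(1, 0, 20); J <- runif(1, 0, 1); t <- runif(1, 5, 90)
    I2 <- simulate_inventory_series(I1, J, t, lam533)
    expect_equal(as.numeric(depositional_flux(I1, I2, t, lam533)), J,
                 tolerance = 1e-10)
  }
  ero <- depositional_flux(10, 2, 30, lam533)
  expect_lt(as.numeric(ero), 0)
  expect_true(attr(ero, "net_erosion"))
  expect_error(depositional_flux(5, 6, 0, 0.013), "t must be")
})

test_that("accumulation rate converts flux via SPM specific activity", {
  expect_equal(as.numeric(accumulation_rate(0.10525, 20)), 1.921,
               tolerance = 1e-3)
  expect_equal(as.numeric(accumulation_rate(0, 20)), 0)
  neg <- accumulation_rate(-0.05, 20)
  expect_lt(as.numeric(neg), 0)
  expect_true(attr(neg, "net_erosion"))
  expect_error(accumulation_rate(0.1, 0), "A_spm")
})

test_that("particle_dynamics composes flux, residence and settling", {
  fit <- be7_fit(exp_core())
  w <- water_sample("WLE1", "2023-05-23", 5, be7_dpm_m3 = 210)
  pd <- particle_dynamics(fit, w)
  expect_equal(pd$J_sed, lam533 * 15.5)
  expect_equal(pd$settling_m_day * pd$T_res_days, 5, tolerance = 1e-12)
  w0 <- water_sample("WLE1", "2023-05-23", 5)
  expect_error(particle_dynamics(fit, w0), "volumetric")
})
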