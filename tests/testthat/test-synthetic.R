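test_that("truth surfaces interpolate their calibration anchors", {
  tr <- default_truth_surfaces()
  expect_equal(tr$etr_max(6), 24.6)
  expect_equal(tr$etr_max(860), 62.7)
  expect_equal(tr$alpha(74, day = 5), 0.173)
  expect_equal(tr$npp(0), -0.35)
  expect_equal(tr$npp(13.7), 0)
  expect_equal(tr$respiration(355), -0.55)
  # finite at all design levels
  lv <- photo_constants$treatment_par
  for (f in c("etr_max", "chla", "npp", "respiration")) {
    expect_true(all(is.finite(tr[[f]](lv))))
  }
  # chlorophyll contrast: low-light levels 2-3x the highest
  expect_gt(tr$chla(6) / tr$chla(860), 2)
  expect_lt(tr$chla(6) / tr$chla(860), 3)
})

test_that("noiseless RLC simulation round-trips through the fit", {
  tr <- simulate_rlc(ps = 40, alpha = 0.16, beta = 0, yield_noise_sd = 0,
                     fm_noise_sdlog = 0, seed = 9)
  fit <- fit_platt(build_etr_curve(tr), qc = FALSE)
  expect_equal(coef(fit)[["ps"]], 40, tolerance = 1e-6)
  expect_equal(coef(fit)[["alpha"]], 0.16, tolerance = 1e-6)
})

test_that("RLC simulation is seed-deterministic and respects the ceiling", {
  a <- simulate_rlc(ps = 40, alpha = 0.16, seed = 33)
  b <- simulate_rlc(ps = 40, alpha = 0.16, seed = 33)
  expect_identical(a$f, b$f)
  c <- simulate_rlc(ps = 40, alpha = 0.16, seed = 34)
  expect_false(identical(a$f, c$f))
  # pushing the yield above the physiological ceiling errors out
  expect_error(simulate_rlc(ps = 40, alpha = 0.6, seed = 1),
               class = "photoacclim_config_error")
})

test_that("alpha recovery from noisy simulated RLCs stays below 10% RMSE", {
  errs <- vapply(1:200, function(i) {
    tr <- simulate_rlc(ps = 45, alpha = 0.15, yield_noise_sd = 0.05,
                       seed = 1000 + i)
    fit <- fit_platt(build_etr_curve(tr), qc = FALSE)
    (coef(fit)[["alpha"]] - 0.15) / 0.15
  }, numeric(1))
  expect_lt(sqrt(mean(errs^2)), 0.10)
})

test_that("simulated spectra express the package effect", {
  # zero pigments: baseline only, af_photo = 0
  sp0 <- simulate_spectrum(0, 0, 0, noise_sd = 0, depth_sdlog = 0,
                           baseline_sdlog = 0, seed = 1)
  la0 <- leaf_absorptance(sp0$wavelength_nm, sp0$absorbance)
  expect_equal(la0$af_photo, 0, tolerance = 1e-9)
  # doubling pigments much less than doubles af_photo
  one <- simulate_spectrum(1, 0.35, 0.33, noise_sd = 0, depth_sdlog = 0,
                           baseline_sdlog = 0, seed = 1)
  two <- simulate_spectrum(2, 0.70, 0.66, noise_sd = 0, depth_sdlog = 0,
                           baseline_sdlog = 0, seed = 1)
  af1 <- leaf_absorptance(one$wavelength_nm, one$absorbance)$af_photo
  af2 <- leaf_absorptance(two$wavelength_nm, two$absorbance)$af_photo
  expect_lt(af2 / af1, 1.2)
  expect_gt(af2 / af1, 1)
})

test_that("noiseless incubations round-trip to the true rates", {
  inc <- simulate_incubation(npp = 0.8, respiration = -0.3,
                             noise_sd = 0, seed = 2)
  rr <- rates(inc$light, inc$dark, volume_l = inc$volume_l,
              ps_surface_cm2 = inc$ps_surface_cm2,
              total_surface_cm2 = inc$total_surface_cm2)
  expect_equal(rr$npp, 0.8, tolerance = 1e-9)
  expect_equal(rr$r, -0.3, tolerance = 1e-9)
  expect_equal(rr$gpp, 0.8 - (-0.3) * 15 / 12, tolerance = 1e-9)
})

test_that("NPP estimates from noisy incubations are unbiased", {
  est <- vapply(1:100, function(i) {
    inc <- simulate_incubation(npp = 0.8, respiration = -0.3,
                               noise_sd = 0.8, seed = 5000 + i)
    rates(inc$light, inc$dark, inc$volume_l, inc$ps_surface_cm2,
          inc$total_surface_cm2)$npp
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.8) / 0.8, 0.02)
})

test_that("the full experiment matches the design arithmetic", {
  ex <- simulate_experiment(sim_config(seed = 8))
  expect_equal(nrow(unique(ex$rlc_steps[c("shoot_id", "day")])), 126)
  expect_equal(length(unique(ex$rlc_steps$shoot_id)), 63)
  expect_equal(nrow(ex$pigments), 63)
  expect_equal(length(unique(ex$spectra$shoot_id)), 63)
  expect_equal(length(unique(ex$incubations$shoot_id)), 63)
  # 3 containers nested in each of 7 treatments
  expect_equal(length(unique(ex$rlc_steps$container_id)), 21)
})

test_that("experiments are reproducible and seeds differentiate", {
  a <- simulate_experiment(sim_config(seed = 77))
  b <- simulate_experiment(sim_config(seed = 77))
  expect_identical(a$rlc_steps, b$rlc_steps)
  expect_identical(a$pigments, b$pigments)
  expect_identical(a$spectra, b$spectra)
  expect_identical(a$incubations, b$incubations)
  c <- simulate_experiment(sim_config(seed = 78))
  expect_false(identical(a$rlc_steps$f, c$rlc_steps$f))
})

test_that("dropout removes whole traces", {
  ex <- simulate_experiment(sim_config(seed = 8, dropout = 0.3))
  expect_lt(nrow(unique(ex$rlc_steps[c("shoot_id", "day")])), 126)
})

test_that("the noiseless experiment is recovered exactly downstream", {
  ex <- simulate_experiment(noiseless_config(seed = 4))
  # platt fits equal per-shoot truth
  d <- ex$rlc_steps[ex$rlc_steps$shoot_id == ex$rlc_steps$shoot_id[1] &
                      ex$rlc_steps$day == 5, ]
  tr <- rlc_trace(d$actinic_par, d$f, d$fm_prime)
  fit <- fit_platt(build_etr_curve(tr), qc = FALSE)
  truth_row <- ex$truth$shoots[ex$truth$shoots$shoot_id == d$shoot_id[1] &
                                 ex$truth$shoots$day == 5, ]
  expect_equal(fit$etr_max, truth_row$etr_max, tolerance = 1e-6)
  expect_equal(coef(fit)[["alpha"]], truth_row$alpha, tolerance = 1e-6)

  # pigment contents equal truth through the trichromatic equations
  pg <- ex$pigments[1, ]
  out <- pigment_concentrations(pg$a470, pg$a645, pg$a662,
                                pg$extract_volume_ml, pg$fresh_weight_g)
  expect_equal(out$chla_mg_gfw, ex$truth$pigment_truth$chla[1],
               tolerance = 1e-9)
  expect_equal(out$car_mg_gfw, ex$truth$pigment_truth$carotenoids[1],
               tolerance = 1e-9)

  # metabolic rates equal truth
  inc <- ex$incubations[ex$incubations$shoot_id == pg$shoot_id, ]
  light <- inc[inc$phase == "light", ]; dark <- inc[inc$phase == "dark", ]
  rr <- rates(list(time_h = light$time_h, o2_umol_l = light$o2_umol_l),
              list(time_h = dark$time_h, o2_umol_l = dark$o2_umol_l),
              inc$volume_l[1], inc$ps_surface_cm2[1],
              inc$total_surface_cm2[1])
  mt <- ex$truth$metabolism_truth
  expect_equal(rr$npp, mt$npp[mt$shoot_id == pg$shoot_id], tolerance = 1e-9)
  expect_equal(rr$r, mt$respiration[mt$shoot_id == pg$shoot_id],
               tolerance = 1e-9)
})
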