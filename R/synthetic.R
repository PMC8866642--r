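# deterministic sub-seed derivation: keeps every stage seed below 2^31
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed %% 1000003L) * 2099 + index * 7919) %%
               2147483629)
}

#' Configuration for the synthetic photoacclimation experiment
#'
#' Defaults reproduce the study design: 7 growth-irradiance treatments
#' (6-860 umol photons m-2 s-1), 3 containers per treatment, 3 shoots per
#' container, RLCs on days 5 and 25 over the 10-step actinic protocol, and
#' physiological sampling (pigments, spectra, incubations) at day 25.
#' Noise magnitudes are relative (lognormal sdlog) for fluorescence and
#' pigments and additive for metabolic rates; container and shoot random
#' effects are drawn once per experiment and shared across data streams.
#'
#' @param treatment_par growth PAR levels.
#' @param containers_per_treatment,shoots_per_container design sizes.
#' @param days RLC measurement days.
#' @param rlc_steps actinic PAR staircase.
#' @param af_pam absorption factor assumed by the fluorometer (0.44).
#' @param yield_noise_sd relative Gaussian noise on the effective quantum
#'   yield (default 0.05, i.e. ~5% ETR noise).
#' @param fm_baseline,fm_noise_sdlog baseline light-adapted maximal
#'   fluorescence and its lognormal variability.
#' @param container_sdlog,shoot_sdlog lognormal random-effect scales applied
#'   to photosynthetic capacity (and, at half strength, efficiency).
#' @param met_container_sd,met_shoot_sd additive random-effect scales
#'   (umol O2 cm-2 h-1) for metabolic rates.
#' @param pigment_sdlog lognormal shoot-level pigment variability.
#' @param o2_noise_sd additive O2 reading noise (umol L-1).
#' @param absorbance_noise_sd noise on extract absorbances.
#' @param spectrum_noise_sd noise on leaf spectral absorbance.
#' @param baseline_a750_d flat non-photosynthetic optical depth (sets the
#'   750 nm absorptance, about 0.37, so total and photosynthetic absorption
#'   factors land near the observed 0.55 and 0.18).
#' @param package_depth,package_rate package-effect parameters: maximum
#'   pigment-band optical depth and the rate at which pigment content
#'   saturates it (self-shading).
#' @param af_leaf_sdlog leaf-to-leaf lognormal variability of the band depth
#'   and baseline (optical geometry differences between leaf fragments).
#' @param volume_l,ps_surface_cm2,total_surface_cm2,surface_sdlog incubation
#'   bottle volume and one-sided leaf surfaces with their variability.
#' @param dropout uniform random probability that a shoot's RLC is lost.
#' @param seed integer seed controlling the whole experiment.
#' @return A `sim_config` list.
#' @export
sim_config <- function(treatment_par = photo_constants$treatment_par,
                       containers_per_treatment = 3,
                       shoots_per_container = 3,
                       days = c(5, 25),
                       rlc_steps = photo_constants$rlc_steps,
                       af_pam = photo_constants$af_default,
                       yield_noise_sd = 0.05,
                       fm_baseline = 800, fm_noise_sdlog = 0.05,
                       container_sdlog = 0.05, shoot_sdlog = 0.07,
                       met_container_sd = 0.05, met_shoot_sd = 0.07,
                       pigment_sdlog = 0.10,
                       o2_noise_sd = 0.8,
                       absorbance_noise_sd = 0.005,
                       spectrum_noise_sd = 0.01,
                       baseline_a750_d = 0.2007,
                       package_depth = 0.42, package_rate = 6,
                       af_leaf_sdlog = 0.08,
                       volume_l = 0.3, ps_surface_cm2 = 12,
                       total_surface_cm2 = 15, surface_sdlog = 0.08,
                       dropout = 0,
                       seed = 1L) {
  cfg <- as.list(environment())
  sds <- c(cfg$yield_noise_sd, cfg$fm_noise_sdlog, cfg$container_sdlog,
           cfg$shoot_sdlog, cfg$met_container_sd, cfg$met_shoot_sd,
           cfg$pigment_sdlog, cfg$o2_noise_sd, cfg$absorbance_noise_sd,
           cfg$spectrum_noise_sd, cfg$surface_sdlog, cfg$af_leaf_sdlog)
  if (any(sds < 0)) {
    stop_photo("noise and random-effect sds must be >= 0",
               class = "photoacclim_config_error")
  }
  structure(cfg, class = "sim_config")
}

#' Ground-truth irradiance-response surfaces
#'
#' Piecewise-smooth (shape-preserving monotone cubic) surfaces interpolating
#' the study's reported anchors: photosynthetic capacity (ETRmax) rising
#' linearly from 24.6 at PAR 6 to 62.7 at PAR 860; efficiency (alpha) peaked
#' at 0.173 at the 74 level on day 5 and levelled at high light by day 25;
#' chlorophyll a 2-3 times higher under low light than at 860; net primary
#' production anchored at -0.35 at PAR 0 (the mean dark respiration) and
#' crossing zero at the compensation irradiance 13.7; respiration -0.55 and
#' -0.53 in the 355 and 860 treatments and -0.28 in the others (their
#' balanced mean magnitude, 0.35, is the NPP anchor at zero irradiance).
#'
#' @return Named list of functions of PAR: `etr_max(par)`,
#'   `alpha(par, day)`, `ek(par, day)`, `chla(par)`, `chlb(par)`,
#'   `carotenoids(par)`, `npp(par)`, `respiration(par)`, plus
#'   `compensation_par` (13.7).
#' @export
default_truth_surfaces <- function() {
  lv <- photo_constants$treatment_par
  mono <- function(x, y) stats::splinefun(x, y, method = "monoH.FC")
  etr_max_f <- function(par) 24.6 + (62.7 - 24.6) * (par - 6) / (860 - 6)
  alpha5 <- mono(lv, c(0.120, 0.155, 0.173, 0.160, 0.130, 0.120, 0.113))
  alpha25 <- mono(lv, c(0.120, 0.155, 0.173, 0.160, 0.150, 0.147, 0.145))
  alpha_f <- function(par, day = 5) {
    ifelse(day >= 25, alpha25(par), alpha5(par))
  }
  chla_f <- mono(lv, c(2.0, 1.9, 1.8, 1.7, 1.10, 0.90, 0.75))
  chlb_f <- function(par) 0.35 * chla_f(par)
  car_f <- mono(lv, c(0.65, 0.63, 0.62, 0.60, 0.52, 0.50, 0.48))
  npp_f <- mono(c(0, 13.7, 36, 74, 133, 355, 503, 860),
                c(-0.35, 0, 0.55, 1.0, 1.03, 1.05, 1.0, 0.95))
  r_f <- mono(c(0, 6, 36, 74, 133, 355, 503, 860),
              c(-0.28, -0.28, -0.28, -0.28, -0.28, -0.55, -0.28, -0.53))
  list(
    etr_max = etr_max_f,
    alpha = alpha_f,
    ek = function(par, day = 5) etr_max_f(par) / alpha_f(par, day),
    chla = chla_f, chlb = chlb_f, carotenoids = car_f,
    npp = npp_f, respiration = r_f,
    compensation_par = 13.7
  )
}

#' Simulate one rapid light curve trace
#'
#' Inverts the ETR equation: the true yield at each actinic step is
#' \eqn{Y(II) = P(E) / (E \cdot AF \cdot 0.5)} from the Platt model, then
#' fluorescence is constructed as `Fm' = baseline * lognormal noise` and
#' `F = Fm' (1 - YII (1 + Gaussian noise))`. In the noiseless limit,
#' [build_etr_curve()] recovers the true ETR exactly.
#'
#' @param ps,alpha,beta true Platt parameters.
#' @param af absorption factor assumed in the ETR equation.
#' @param steps actinic PAR staircase.
#' @param yield_noise_sd relative yield noise.
#' @param fm_baseline,fm_noise_sdlog Fm' baseline and lognormal noise.
#' @param seed integer seed.
#' @param ... metadata passed to [rlc_trace()] (shoot_id, day, ...).
#' @return An [rlc_trace()].
#' @export
simulate_rlc <- function(ps, alpha, beta = 0,
                         af = photo_constants$af_default,
                         steps = photo_constants$rlc_steps,
                         yield_noise_sd = 0.05,
                         fm_baseline = 800, fm_noise_sdlog = 0.05,
                         seed = 1L, ...) {
  yii_true <- platt_model(steps, ps, alpha, beta) /
    (steps * af * photo_constants$psii_fraction)
  if (any(yii_true > 0.83)) {
    stop_photo("generator config implies YII > 0.83 (physiological ceiling)",
               class = "photoacclim_config_error")
  }
  set.seed(seed)
  n <- length(steps)
  fm_prime <- fm_baseline * exp(stats::rnorm(n, 0, fm_noise_sdlog))
  yii_obs <- pmin(pmax(yii_true * (1 + stats::rnorm(n, 0, yield_noise_sd)),
                       0), 1)
  f <- fm_prime * (1 - yii_obs)
  rlc_trace(actinic_par = steps, f = f, fm_prime = fm_prime, ...)
}

# fixed pigment absorption band shapes (arbitrary but documented): Gaussian
# mixtures on the wavelength axis, per pigment, in ug-1 mL units
pigment_band <- function(wl, chla, chlb, car) {
  g <- function(mu, sd) exp(-0.5 * ((wl - mu) / sd)^2)
  chla * (g(435, 24) + 0.9 * g(675, 20)) +
    chlb * (g(470, 20) + 0.7 * g(650, 16)) +
    car * 1.1 * g(490, 28)
}

#' Simulate a leaf spectral absorbance scan with a package effect
#'
#' Builds the pigment-band optical depth with explicit self-shading:
#' \eqn{D_p(\lambda) = D_{max} S(\lambda)\,(1 - e^{-s P(\lambda)})}, where
#' `P` is the pigment-weighted Gaussian band mixture, `S` its normalized
#' shape and `Dmax`/`s` the package-effect parameters, plus a flat
#' non-photosynthetic baseline depth. Because the band depth saturates in
#' pigment content (pigment packaging in stacked chloroplasts) and the
#' absorptance transform `1 - 10^(-D)` compresses further, a three-fold
#' increase in chlorophyll changes the photosynthetic absorption factor only
#' marginally -- the package effect reported for low-light acclimated leaves.
#'
#' @param chla,chlb,car pigment contents (mg g-1 FW scale; only ratios and
#'   the package rate matter).
#' @param package_depth maximum band optical depth `Dmax`.
#' @param package_rate saturation rate `s` (per pigment unit).
#' @param baseline_a750_d flat baseline optical depth.
#' @param wavelength wavelength grid, nm.
#' @param noise_sd additive absorbance noise.
#' @param depth_sdlog,baseline_sdlog per-leaf lognormal variability of band
#'   depth and baseline.
#' @param seed integer seed.
#' @return Data frame with `wavelength_nm` and `absorbance`.
#' @export
simulate_spectrum <- function(chla, chlb, car,
                              package_depth = 0.42, package_rate = 6,
                              baseline_a750_d = 0.2007,
                              wavelength = 400:750,
                              noise_sd = 0.01,
                              depth_sdlog = 0.08, baseline_sdlog = 0.08,
                              seed = 1L) {
  if (package_rate <= 0 || package_depth <= 0) {
    stop_photo("package parameters must be > 0",
               class = "photoacclim_config_error")
  }
  set.seed(seed)
  p <- pigment_band(wavelength, chla, chlb, car)
  shape <- pigment_band(wavelength, 1, 0.35, 0.33)
  shape <- shape / max(shape)
  dmax <- package_depth * exp(stats::rnorm(1, 0, depth_sdlog))
  base <- baseline_a750_d * exp(stats::rnorm(1, 0, baseline_sdlog))
  d <- dmax * shape * (1 - exp(-package_rate * p)) + base
  d <- pmax(d + stats::rnorm(length(wavelength), 0, noise_sd), 0)
  data.frame(wavelength_nm = wavelength, absorbance = d)
}

#' Simulate a paired light/dark oxygen incubation
#'
#' Inverts the rate equations: the light-phase slope is
#' `npp * ps_surface / volume` and the dark-phase slope
#' `respiration * total_surface / volume`; four readings 20 minutes apart
#' per phase with additive Gaussian noise. The noiseless series round-trips
#' through [rates()] to the true rates exactly.
#'
#' @param npp,respiration true rates (umol O2 cm-2 h-1; respiration signed,
#'   normally negative).
#' @param ps_surface_cm2,total_surface_cm2 one-sided leaf surfaces.
#' @param volume_l bottle volume.
#' @param o2_start starting O2 concentration (umol L-1).
#' @param noise_sd additive O2 noise (umol L-1).
#' @param seed integer seed.
#' @return List with `light` and `dark` data frames (`time_h`,
#'   `o2_umol_l`) plus the surfaces and volume.
#' @export
simulate_incubation <- function(npp, respiration,
                                ps_surface_cm2 = 12, total_surface_cm2 = 15,
                                volume_l = 0.3, o2_start = 250,
                                noise_sd = 0.8, seed = 1L) {
  if (volume_l <= 0 || ps_surface_cm2 <= 0 ||
      total_surface_cm2 < ps_surface_cm2) {
    stop_photo("invalid volume or surfaces", class = "photoacclim_config_error")
  }
  set.seed(seed)
  t <- c(0, 1, 2, 3) / 3
  slope_light <- npp * ps_surface_cm2 / volume_l
  slope_dark <- respiration * total_surface_cm2 / volume_l
  dark <- data.frame(
    time_h = t,
    o2_umol_l = o2_start + slope_dark * t + stats::rnorm(4, 0, noise_sd)
  )
  light_start <- o2_start + slope_dark * max(t)
  light <- data.frame(
    time_h = t,
    o2_umol_l = light_start + slope_light * t + stats::rnorm(4, 0, noise_sd)
  )
  list(light = light, dark = dark,
       ps_surface_cm2 = ps_surface_cm2,
       total_surface_cm2 = total_surface_cm2, volume_l = volume_l)
}

#' Simulate a complete photoacclimation experiment
#'
#' Generates all four data streams of the study design with shared container
#' and shoot random effects and a known truth bundle: RLC fluorescence
#' staircases for every shoot on both measurement days, pigment-extract
#' absorbances (back-calculated so the trichromatic equations recover the
#' true contents), leaf absorbance spectra with the package effect, and
#' paired light/dark O2 incubations. Identical config and seed reproduce the
#' output exactly.
#'
#' @param config a [sim_config()].
#' @param truth truth surfaces, by default [default_truth_surfaces()].
#' @return List of class `photo_experiment` with data frames `rlc_steps`,
#'   `pigments`, `spectra`, `incubations` and a `truth` list (config,
#'   surfaces, per-shoot true parameters).
#' @export
simulate_experiment <- function(config = sim_config(),
                                truth = default_truth_surfaces()) {
  stopifnot(inherits(config, "sim_config"))
  seed <- config$seed
  set.seed(derive_seed(seed, 0))

  design <- expand.grid(
    shoot = seq_len(config$shoots_per_container),
    container = seq_len(config$containers_per_treatment),
    treatment_par = config$treatment_par,
    KEEP.OUT.ATTRS = FALSE
  )
  design$container_id <- sprintf("T%03d_C%d", design$treatment_par,
                                 design$container)
  design$shoot_id <- sprintf("%s_S%d", design$container_id, design$shoot)
  n_shoot <- nrow(design)

  containers <- unique(design$container_id)
  z_c <- stats::setNames(stats::rnorm(length(containers)), containers)
  z_s <- stats::setNames(stats::rnorm(n_shoot), design$shoot_id)
  design$z <- z_c[design$container_id] + z_s[design$shoot_id]

  # fluorescence-scale effects: multiplicative on capacity, half on efficiency
  eff_cap <- exp(config$shoot_sdlog * z_s[design$shoot_id] +
                   config$container_sdlog * z_c[design$container_id])
  eff_alpha <- sqrt(eff_cap)
  # metabolism-scale effects: additive, same underlying draws
  eff_met <- config$met_shoot_sd * z_s[design$shoot_id] +
    config$met_container_sd * z_c[design$container_id]

  truth_shoots <- list()
  rlc_rows <- list()
  drop_rng_seed <- derive_seed(seed, 1)
  set.seed(drop_rng_seed)
  dropped <- stats::runif(n_shoot * length(config$days)) < config$dropout

  idx <- 0
  for (i in seq_len(n_shoot)) {
    for (day in config$days) {
      idx <- idx + 1
      if (dropped[idx]) next
      a <- truth$alpha(design$treatment_par[i], day) * eff_alpha[i]
      em <- truth$etr_max(design$treatment_par[i]) * eff_cap[i]
      tr <- simulate_rlc(
        ps = em, alpha = a, beta = 0, af = config$af_pam,
        steps = config$rlc_steps,
        yield_noise_sd = config$yield_noise_sd,
        fm_baseline = config$fm_baseline,
        fm_noise_sdlog = config$fm_noise_sdlog,
        seed = derive_seed(seed, 100 + idx),
        shoot_id = design$shoot_id[i], container_id = design$container_id[i],
        treatment_par = design$treatment_par[i], day = day
      )
      rlc_rows[[idx]] <- data.frame(
        shoot_id = design$shoot_id[i], container_id = design$container_id[i],
        treatment_par = design$treatment_par[i], day = day,
        step_index = seq_along(tr$actinic_par),
        actinic_par = tr$actinic_par, f = tr$f, fm_prime = tr$fm_prime
      )
      truth_shoots[[length(truth_shoots) + 1]] <- data.frame(
        shoot_id = design$shoot_id[i], day = day,
        ps = em, alpha = a, beta = 0,
        etr_max = em, ek = em / a
      )
    }
  }
  rlc_steps <- do.call(rbind, rlc_rows)

  # pigments (day 25): lognormal shoot-level variation on all three contents
  set.seed(derive_seed(seed, 2))
  pg_mult <- exp(stats::rnorm(n_shoot, 0, config$pigment_sdlog))
  chla_t <- truth$chla(design$treatment_par) * pg_mult
  chlb_t <- truth$chlb(design$treatment_par) * pg_mult
  car_t <- truth$carotenoids(design$treatment_par) * pg_mult
  fw <- 0.1 * exp(stats::rnorm(n_shoot, 0, 0.1))
  vol_ml <- 10
  # invert the trichromatic equations: contents -> extract concentrations
  conc_scale <- fw * 1000 / vol_ml            # mg g-1 FW -> ug mL-1
  # 2x2 linear solve of the chlorophyll equations for (A662, A645)
  k <- pigment_coefficients[1, ]
  det <- k$chla_a662 * k$chlb_a645 - k$chla_a645 * k$chlb_a662
  ca <- chla_t * conc_scale; cb <- chlb_t * conc_scale
  cc <- car_t * conc_scale
  a662 <- (ca * k$chlb_a645 - cb * k$chla_a645) / det
  a645 <- (cb * k$chla_a662 - ca * k$chlb_a662) / det
  a470 <- (cc * k$car_denom - k$car_chla * ca - k$car_chlb * cb) / k$car_a470
  noise <- matrix(stats::rnorm(3 * n_shoot, 0, config$absorbance_noise_sd),
                  ncol = 3)
  pigments <- data.frame(
    shoot_id = design$shoot_id, container_id = design$container_id,
    treatment_par = design$treatment_par,
    a470 = pmax(a470 + noise[, 1], 0),
    a645 = pmax(a645 + noise[, 2], 0),
    a662 = pmax(a662 + noise[, 3], 0),
    extract_volume_ml = vol_ml, fresh_weight_g = fw
  )

  # spectra (day 25): package-effect leaf scans from true pigment contents
  spectra <- do.call(rbind, lapply(seq_len(n_shoot), function(i) {
    sp <- simulate_spectrum(
      chla = chla_t[i], chlb = chlb_t[i], car = car_t[i],
      package_depth = config$package_depth,
      package_rate = config$package_rate,
      baseline_a750_d = config$baseline_a750_d,
      noise_sd = config$spectrum_noise_sd,
      depth_sdlog = config$af_leaf_sdlog,
      baseline_sdlog = config$af_leaf_sdlog,
      seed = derive_seed(seed, 300 + i)
    )
    cbind(shoot_id = design$shoot_id[i], sp)
  }))

  # incubations (day 25)
  set.seed(derive_seed(seed, 3))
  ps_surf <- config$ps_surface_cm2 * exp(stats::rnorm(n_shoot, 0,
                                                      config$surface_sdlog))
  tot_surf <- ps_surf * (config$total_surface_cm2 / config$ps_surface_cm2) *
    exp(abs(stats::rnorm(n_shoot, 0, 0.03)))
  npp_t <- truth$npp(design$treatment_par) + eff_met
  r_t <- truth$respiration(design$treatment_par) - 0.3 * eff_met
  inc_rows <- lapply(seq_len(n_shoot), function(i) {
    inc <- simulate_incubation(
      npp = npp_t[i], respiration = r_t[i],
      ps_surface_cm2 = ps_surf[i], total_surface_cm2 = tot_surf[i],
      volume_l = config$volume_l, noise_sd = config$o2_noise_sd,
      seed = derive_seed(seed, 500 + i)
    )
    rbind(
      data.frame(shoot_id = design$shoot_id[i],
                 container_id = design$container_id[i],
                 treatment_par = design$treatment_par[i],
                 phase = "dark", inc$dark,
                 volume_l = config$volume_l,
                 ps_surface_cm2 = ps_surf[i], total_surface_cm2 = tot_surf[i]),
      data.frame(shoot_id = design$shoot_id[i],
                 container_id = design$container_id[i],
                 treatment_par = design$treatment_par[i],
                 phase = "light", inc$light,
                 volume_l = config$volume_l,
                 ps_surface_cm2 = ps_surf[i], total_surface_cm2 = tot_surf[i])
    )
  })
  incubations <- do.call(rbind, inc_rows)

  structure(list(
    rlc_steps = rlc_steps,
    pigments = pigments,
    spectra = spectra,
    incubations = incubations,
    truth = list(
      config = config,
      surfaces = truth,
      shoots = do.call(rbind, truth_shoots),
      pigment_truth = data.frame(
        shoot_id = design$shoot_id, treatment_par = design$treatment_par,
        chla = chla_t, chlb = chlb_t, carotenoids = car_t
      ),
      metabolism_truth = data.frame(
        shoot_id = design$shoot_id, treatment_par = design$treatment_par,
        npp = npp_t, respiration = r_t,
        gpp = npp_t - r_t * tot_surf / ps_surf
      ),
      compensation_par = truth$compensation_par
    )
  ), class = "photo_experiment")
}

#' @export
print.photo_experiment <- function(x, ...) {
  cat("Synthetic photoacclimation experiment\n")
  cat("  RLC traces:",
      nrow(unique(x$rlc_steps[c("shoot_id", "day")])), "\n")
  cat("  pigment samples:", nrow(x$pigments),
      "| spectra:", length(unique(x$spectra$shoot_id)),
      "| incubation pairs:", length(unique(x$incubations$shoot_id)), "\n")
  invisible(x)
}
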