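# shared fixtures, built in code at test time

# noiseless RLC trace from known Platt parameters
noiseless_trace <- function(ps = 60, alpha = 0.15, beta = 0,
                            af = photo_constants$af_default,
                            steps = photo_constants$rlc_steps) {
  yii <- platt_model(steps, ps, alpha, beta) / (steps * af * 0.5)
  fm <- rep(800, length(steps))
  rlc_trace(steps, f = fm * (1 - yii), fm_prime = fm,
            shoot_id = "S1", container_id = "C1",
            treatment_par = 133, day = 5)
}

# all noise and random-effect scales set to zero
noiseless_config <- function(seed = 1L, ...) {
  sim_config(yield_noise_sd = 0, fm_noise_sdlog = 0,
             container_sdlog = 0, shoot_sdlog = 0,
             met_container_sd = 0, met_shoot_sd = 0,
             pigment_sdlog = 0, o2_noise_sd = 0,
             absorbance_noise_sd = 0, spectrum_noise_sd = 0,
             af_leaf_sdlog = 0, surface_sdlog = 0,
             dropout = 0, seed = seed, ...)
}

# brute-force SSE oracle: best point on a coarse log-spaced parameter grid
platt_grid_sse <- function(e, y, n_ps = 20, n_alpha = 20, n_beta = 10) {
  slope_max <- max(y[e > 0] / e[e > 0])
  ps_grid <- exp(seq(log(0.1 * max(y)), log(10 * max(y)), length.out = n_ps))
  alpha_grid <- exp(seq(log(0.01 * slope_max), log(10 * slope_max),
                        length.out = n_alpha))
  beta_grid <- c(0, exp(seq(log(1e-4 * slope_max), log(slope_max),
                            length.out = n_beta - 1)))
  best <- Inf
  for (ps in ps_grid) for (a in alpha_grid) for (b in beta_grid) {
    sse <- sum((y - platt_model(e, ps, a, b))^2)
    if (sse < best) best <- sse
  }
  best
}
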