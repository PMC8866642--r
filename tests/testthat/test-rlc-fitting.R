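test_that("ETR curves are built per valid step with QC accounting", {
  tr <- noiseless_trace(ps = 60, alpha = 0.15)
  cv <- build_etr_curve(tr, af = 0.44)
  expect_s3_class(cv, "etr_curve")
  expect_equal(cv$etr, platt_model(cv$par, 60, 0.15, 0), tolerance = 1e-12)

  # constant yield: etr = yii * E * af * 0.5
  fm <- rep(800, 10)
  tr2 <- rlc_trace(photo_constants$rlc_steps, f = fm * 0.5, fm_prime = fm)
  cv2 <- build_etr_curve(tr2, af = 0.44)
  expect_equal(cv2$etr, 0.5 * cv2$par * 0.44 * 0.5)
  expect_equal(cv2$etr[cv2$par == 98] * 100 / 98, 11.0, tolerance = 1e-12)

  # all-zero yield
  tr3 <- rlc_trace(photo_constants$rlc_steps, f = fm, fm_prime = fm)
  expect_true(all(build_etr_curve(tr3)$etr == 0))

  # too few valid steps
  tr4 <- rlc_trace(c(38, 68, 98), f = c(400, 420, 450),
                   fm_prime = c(800, 800, 800))
  expect_error(build_etr_curve(tr4),
               class = "photoacclim_insufficient_data")

  # invalid Fm' steps dropped and counted
  fm_bad <- fm; fm_bad[c(2, 5)] <- NA
  tr5 <- rlc_trace(photo_constants$rlc_steps, f = fm * 0.5,
                   fm_prime = fm_bad)
  cv5 <- build_etr_curve(tr5)
  expect_equal(cv5$n_dropped, 2)
  expect_length(cv5$par, 8)
})

test_that("Platt model obeys its limits and closed form", {
  expect_equal(platt_model(0, 80, 0.2, 0.01), 0)
  # beta = 0 saturation limit
  expect_equal(platt_model(1e9, 60, 0.15, 0), 60, tolerance = 1e-9)
  # independent evaluation of the expression
  e <- 400; ps <- 80; a <- 0.2; b <- 0.01
  expect_equal(platt_model(e, ps, a, b),
               ps * (1 - exp(-a * e / ps)) * exp(-b * e / ps),
               tolerance = 1e-12)
  # initial slope equals alpha
  h <- 1e-6
  expect_equal(platt_model(h, ps, a, b) / h, a, tolerance = 1e-4)
  expect_error(platt_model(100, -1, 0.2), class = "photoacclim_parameter_error")
})

test_that("derived ETRmax and Ek match a brute-force maximization oracle", {
  cases <- list(c(60, 0.15, 0), c(80, 0.2, 0.01), c(30, 0.35, 0.05),
                c(100, 0.08, 0.002))
  for (cs in cases) {
    d <- platt_derived(cs[1], cs[2], cs[3])
    grid <- seq(0, 50000, by = 0.5)
    oracle_max <- max(platt_model(grid, cs[1], cs[2], cs[3]))
    expect_equal(d$etr_max, oracle_max, tolerance = 1e-3)
    expect_equal(d$ek, d$etr_max / cs[2], tolerance = 1e-12)
  }
  # beta = 0 closed form
  d0 <- platt_derived(60, 0.15, 0)
  expect_equal(d0$etr_max, 60)
  expect_equal(d0$ek, 400)
  # continuity at beta -> 0
  d_eps <- platt_derived(60, 0.15, 1e-10)
  expect_equal(d_eps$etr_max, 60, tolerance = 1e-6)
})

test_that("noiseless curves are recovered to 1e-6 relative", {
  cases <- list(c(60, 0.15, 0), c(80, 0.2, 0.01), c(45, 0.25, 0))
  for (cs in cases) {
    e <- photo_constants$rlc_steps
    y <- platt_model(e, cs[1], cs[2], cs[3])
    fit <- fit_platt(list(par = e, etr = y), qc = FALSE)
    expect_true(fit$converged)
    expect_equal(unname(coef(fit)), cs, tolerance = 1e-6)
    d <- platt_derived(cs[1], cs[2], cs[3])
    expect_equal(fit$etr_max, d$etr_max, tolerance = 1e-6)
    expect_equal(fit$ek, d$ek, tolerance = 1e-6)
  }
})

test_that("fitted SSE never exceeds the coarse grid-search oracle", {
  e <- photo_constants$rlc_steps
  set.seed(11)
  curves <- c(
    lapply(list(c(60, 0.15, 0), c(80, 0.2, 0.01)), function(cs) {
      platt_model(e, cs[1], cs[2], cs[3])
    }),
    lapply(1:3, function(i) {
      y <- platt_model(e, 50 + 10 * i, 0.1 + 0.05 * i, 0.002 * i)
      y * (1 + rnorm(length(e), 0, 0.05))
    })
  )
  for (y in curves) {
    fit <- fit_platt(list(par = e, etr = y), qc = FALSE)
    expect_lte(fit$sse, platt_grid_sse(e, y) + 1e-9)
  }
})

test_that("ek invariants hold on fits", {
  e <- photo_constants$rlc_steps
  set.seed(5)
  y <- platt_model(e, 55, 0.18, 0.004) * (1 + rnorm(10, 0, 0.04))
  fit <- fit_platt(list(par = e, etr = y), qc = FALSE)
  th <- coef(fit)
  expect_equal(fit$ek * th[["alpha"]], fit$etr_max, tolerance = 1e-9)
})

test_that("rescaling ETR rescales Ps, alpha, ETRmax and leaves Ek unchanged", {
  e <- photo_constants$rlc_steps
  y <- platt_model(e, 60, 0.15, 0.003)
  fit1 <- fit_platt(list(par = e, etr = y), qc = FALSE)
  for (c_mult in c(0.409, 2)) {
    fit2 <- fit_platt(list(par = e, etr = c_mult * y), qc = FALSE)
    expect_equal(coef(fit2)[["ps"]], c_mult * coef(fit1)[["ps"]],
                 tolerance = 1e-6)
    expect_equal(coef(fit2)[["alpha"]], c_mult * coef(fit1)[["alpha"]],
                 tolerance = 1e-6)
    expect_equal(fit2$etr_max, c_mult * fit1$etr_max, tolerance = 1e-6)
    expect_equal(fit2$ek, fit1$ek, tolerance = 1e-6)
  }
})

test_that("parameter recovery stays within tolerance at 5% noise", {
  e <- photo_constants$rlc_steps
  n_rep <- 200
  etr_max_true <- seq(24.6, 62.7, length.out = n_rep)  # reported day-5 range
  rel_err <- matrix(NA_real_, n_rep, 3)
  set.seed(20240917)
  for (i in seq_len(n_rep)) {
    ps <- etr_max_true[i]; a <- ps / 200   # ek fixed at 200
    y <- platt_model(e, ps, a, 0)
    y <- y + rnorm(length(e), 0, 0.05 * ps)
    fit <- fit_platt(list(par = e, etr = pmax(y, 0)), qc = FALSE)
    rel_err[i, ] <- c((fit$etr_max - ps) / ps, (coef(fit)[["alpha"]] - a) / a,
                      (fit$ek - 200) / 200)
  }
  expect_lt(sqrt(mean(rel_err[, 1]^2)), 0.10)          # ETRmax RMSE < 10%
  expect_lt(median(abs(rel_err[, 2])), 0.10)           # alpha
  expect_lt(median(abs(rel_err[, 3])), 0.15)           # ek
})

test_that("saturation QC rejects curves that never plateau", {
  e <- photo_constants$rlc_steps
  # strictly linear response: no plateau
  fit_lin <- fit_platt(list(par = e, etr = 0.1 * e))
  expect_true(fit_lin$rejected)

  # well-saturated curve accepted: ek = 166 far below 1246
  y <- platt_model(e, 50, 0.3, 0)
  fit_ok <- fit_platt(list(par = e, etr = y))
  expect_false(fit_ok$rejected)
  expect_equal(fit_ok$ek, 50 / 0.3, tolerance = 1e-6)

  # threshold sub-rule: fitted ek above the highest actinic step
  fit_hi <- fit_platt(list(par = e, etr = y), qc = FALSE)
  fit_hi$ek <- 1300
  out <- qc_saturation(fit_hi, max_actinic = 1246)
  expect_true(out$rejected)
  expect_match(out$reject_reason, "ek_above_max_actinic")
})

test_that("platt_fit methods are coherent", {
  tr <- noiseless_trace()
  fit <- fit_platt(build_etr_curve(tr))
  expect_equal(predict(fit, newdata = fit$curve$par), fitted(fit))
  expect_equal(residuals(fit), fit$curve$etr - fitted(fit))
  expect_output(print(fit), "ETRmax")
  expect_output(print(summary(fit)), "residuals")
})
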