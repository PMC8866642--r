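lv <- photo_constants$treatment_par

test_that("straight-line data lie in the penalty null space", {
  d <- data.frame(treatment_par = rep(lv, 3))
  d$y <- 2 + 0.01 * d$treatment_par
  for (lambda in c(0, 1, 1e6)) {
    fit <- fit_hgam(d, response = "y", random = NULL, sp = lambda)
    expect_lt(max(abs(residuals(fit$gam))), 1e-8)
  }
})

test_that("infinite smoothing converges to the OLS line", {
  set.seed(71)
  d <- data.frame(treatment_par = rep(lv, 3))
  d$y <- 1 + 0.005 * d$treatment_par + rnorm(nrow(d), 0, 0.3)
  fit <- fit_hgam(d, response = "y", random = NULL, sp = 1e12)
  ols <- lm(y ~ treatment_par, data = d)
  pred <- predict(fit, new_par = lv)$fit
  expect_equal(pred, unname(predict(ols, data.frame(treatment_par = lv))),
               tolerance = 1e-6)
})

test_that("unpenalized fit interpolates noiseless level means", {
  truth <- function(p) 0.1 + 0.1 * exp(-p / 200) + 1e-4 * p
  d <- data.frame(treatment_par = rep(lv, 3))
  d$y <- truth(d$treatment_par)
  fit <- fit_hgam(d, response = "y", random = NULL, sp = 0)
  # direct linear-solve oracle: with 7 basis functions and 7 level means,
  # the unpenalized fit must reproduce the means exactly
  expect_equal(predict(fit, lv)$fit, truth(lv), tolerance = 1e-6)
})

test_that("basis dimension is reduced with a warning when levels are few", {
  d <- data.frame(treatment_par = rep(c(6, 74, 503), each = 4))
  d$y <- log(d$treatment_par) + rnorm(12, 0, 0.01)
  expect_warning(fit <- fit_hgam(d, response = "y", random = NULL, k = 7),
                 "reduced")
  expect_s3_class(fit, "hgam_fit")
})

test_that("random container intercepts shrink toward simulated offsets", {
  set.seed(99)
  offs <- c(A = 0.6, B = 0, C = -0.6)
  d <- expand.grid(treatment_par = lv, container_id = names(offs),
                   rep = 1:3, KEEP.OUT.ATTRS = FALSE)
  d$y <- 0.01 * d$treatment_par + offs[d$container_id] +
    rnorm(nrow(d), 0, 0.2)
  fit <- fit_hgam(d, response = "y", random = "container_id")
  # extract the fitted random intercepts by differencing predictions
  co <- coef(fit$gam)
  re <- co[grep("container_id", names(co))]
  expect_equal(order(re), order(offs))
  # shrinkage: BLUP magnitude below the raw offsets but clearly nonzero
  expect_lt(max(abs(re)), 0.6 + 0.1)
  expect_gt(max(abs(re)), 0.3)
})

test_that("summary reports t for parametric and F for smooth terms", {
  set.seed(12)
  d <- expand.grid(treatment_par = lv, day = c(5, 25), rep = 1:3,
                   KEEP.OUT.ATTRS = FALSE)
  d$y <- 0.01 * d$treatment_par + 0.5 * (d$day == 25) + rnorm(nrow(d), 0, 0.2)
  fit <- fit_hgam(d, response = "y", group = "day", random = NULL)
  s <- summary(fit)
  expect_true(any(s$terms$stat_type == "t"))
  expect_true(any(s$terms$stat_type == "F"))
  expect_true(all(s$terms$p_value >= 0 & s$terms$p_value <= 1))
  expect_true(is.finite(s$r_sq_adj) && is.finite(s$dev_expl))
})

test_that("population predictions carry calibrated pointwise intervals", {
  set.seed(13)
  d <- data.frame(treatment_par = rep(lv, 4))
  d$y <- 0.5 + 0.002 * d$treatment_par + rnorm(nrow(d), 0, 0.1)
  fit <- fit_hgam(d, response = "y", random = NULL)
  pr <- predict(fit, lv, level = 0.95)
  # z = 1.96 for 95%: half-width / se
  expect_equal((pr$upper - pr$fit) / pr$se, rep(qnorm(0.975), 7),
               tolerance = 1e-9)
  # interval width shrinks as noise shrinks
  widths <- sapply(c(0.2, 0.05, 0.01), function(s) {
    set.seed(14)
    d$y <- 0.5 + 0.002 * d$treatment_par + rnorm(nrow(d), 0, s)
    f <- fit_hgam(d, response = "y", random = NULL)
    mean(predict(f, lv)$upper - predict(f, lv)$lower)
  })
  expect_true(all(diff(widths) < 0))
  # extrapolation flagged
  expect_warning(out <- predict(fit, c(3, 900)), "design PAR range")
  expect_true(all(out$extrapolated))
})

test_that("non-overlap regions are located on the PAR grid", {
  grid <- seq(0, 860, by = 10)
  band <- function(f, hw) data.frame(par = grid, fit = f, se = hw / 1.96,
                                     lower = f - hw, upper = f + hw)
  # identical fits: no separation
  a <- band(rep(1, length(grid)), 1)
  expect_equal(nrow(ci_overlap_regions(a, a)), 0)
  # constant separation of 10 with half-width 1: whole grid
  b <- band(rep(11, length(grid)), 1)
  out <- ci_overlap_regions(a, b)
  expect_equal(out$start, 0)
  expect_equal(out$end, 860)
  # divergence onset detected within one grid step of construction
  onset <- 355
  f2 <- ifelse(grid >= onset, 1 + 0.05 * (grid - onset), 1)
  c2 <- band(f2, 1)
  out2 <- ci_overlap_regions(a, c2)
  true_onset <- grid[min(which(f2 - 1 > 2))]
  expect_lte(abs(out2$start[1] - true_onset), 10)
})

test_that("threshold t-test reports statistics and assumption flags", {
  x <- c(1, 2, 3, 4, 5)
  out <- threshold_ttest(x, x)
  expect_equal(out$t, 0)
  expect_equal(out$p_value, 1)
  expect_true(out$method == "welch")
  expect_true(is.finite(out$shapiro_p_low) && is.finite(out$fligner_p))
  expect_error(threshold_ttest(c(1, 2), c(1, 2, 3)),
               class = "photoacclim_insufficient_data")
  expect_error(threshold_ttest(rep(1, 5), rep(2, 5)),
               class = "photoacclim_input_error")
})

test_that("MQR root matches the closed form on linear fitted NPP", {
  # line -0.35 + 0.0255 PAR through the anchored model: null-space exactness
  d <- data.frame(treatment_par = c(lv, lv), container_id = "x")
  d$npp <- -0.35 + 0.0255 * d$treatment_par
  fit <- npp_irradiance_model(d[c("treatment_par", "npp")],
                              mean_r_magnitude = 0.35, random = NULL)
  est <- estimate_mqr(fit)
  expect_false(est$no_root)
  expect_equal(est$mqr, 0.35 / 0.0255, tolerance = 0.02 / 13)
  expect_equal(est$anchor_respiration, 0.35)
})

test_that("everywhere-positive fitted NPP yields a flagged no-root result", {
  d <- data.frame(treatment_par = rep(lv, 2))
  d$npp <- 0.5 + 0.001 * d$treatment_par
  fit <- fit_hgam(d, response = "npp", random = NULL)
  est <- estimate_mqr(fit)
  expect_true(est$no_root)
  expect_true(is.na(est$mqr))
})

test_that("daily dose conversion is the exact closed form and linear", {
  expect_equal(convert_par_to_daily(0), 0)
  expect_equal(convert_par_to_daily(100, 10), 100 * 3600 * 10 * 1e-6)
  # linear in both arguments
  expect_equal(convert_par_to_daily(2 * 37, 14),
               2 * convert_par_to_daily(37, 14))
  expect_equal(convert_par_to_daily(37, 7), convert_par_to_daily(37, 14) / 2)
  expect_error(convert_par_to_daily(-1), class = "photoacclim_input_error")
  expect_error(convert_par_to_daily(10, 25),
               class = "photoacclim_input_error")
})
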