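#' Construct a rapid light curve trace
#'
#' Bundles one shoot-by-date fluorescence staircase: per actinic step the
#' steady-state fluorescence `F` and saturating-pulse maximum `Fm'`, plus the
#' design metadata (shoot, container, growth-irradiance treatment, day).
#'
#' @param actinic_par actinic PAR per step (umol photons m-2 s-1), strictly
#'   increasing; defaults are checked against nothing -- any staircase with at
#'   least 5 steps is accepted for fitting.
#' @param f,fm_prime fluorescence readings per step.
#' @param shoot_id,container_id identifiers.
#' @param treatment_par growth irradiance of the treatment the shoot was
#'   acclimated to.
#' @param day measurement day (the study design used days 5 and 25).
#' @param fo_prime,fm_dark,fo_dark optional readings (NA when not recorded).
#' @return An object of class `rlc_trace`.
#' @export
rlc_trace <- function(actinic_par, f, fm_prime,
                      shoot_id = NA_character_, container_id = NA_character_,
                      treatment_par = NA_real_, day = NA_real_,
                      fo_prime = NA_real_, fm_dark = NA_real_,
                      fo_dark = NA_real_) {
  n <- length(actinic_par)
  if (length(f) != n || length(fm_prime) != n) {
    stop_photo("actinic_par, f and fm_prime must have equal length",
               class = "photoacclim_input_error")
  }
  if (is.unsorted(actinic_par, strictly = TRUE)) {
    stop_photo("actinic_par must be strictly increasing",
               class = "photoacclim_input_error")
  }
  structure(list(
    actinic_par = as.numeric(actinic_par),
    f = as.numeric(f), fm_prime = as.numeric(fm_prime),
    fo_prime = rep_len(as.numeric(fo_prime), n),
    fm_dark = fm_dark, fo_dark = fo_dark,
    shoot_id = shoot_id, container_id = container_id,
    treatment_par = treatment_par, day = day
  ), class = "rlc_trace")
}

#' @export
print.rlc_trace <- function(x, ...) {
  cat("Rapid light curve trace:", length(x$actinic_par), "steps\n")
  cat("  shoot", x$shoot_id, "| container", x$container_id,
      "| treatment", x$treatment_par, "umol m-2 s-1 | day", x$day, "\n")
  invisible(x)
}

#' Build an ETR-vs-irradiance curve from an RLC trace
#'
#' Applies [quantum_yield()] and [etr()] per step. Steps with missing or
#' non-positive `Fm'` are dropped and counted; steps whose yield is negative
#' (noise) are clamped to zero ETR and flagged so the curve satisfies
#' `etr >= 0` while remaining auditable.
#'
#' @param trace an [rlc_trace()].
#' @param af absorption factor in (0, 1\].
#' @param af_kind label for the AF used: `"default_044"`, `"af_total"` or
#'   `"af_photo"`.
#' @param min_steps minimum number of valid steps required (default 5).
#' @return An object of class `etr_curve`: list with `par`, `etr`, `yii`,
#'   `af_used`, `af_kind`, `n_dropped`, `n_clamped` and the trace metadata.
#' @export
build_etr_curve <- function(trace, af = photo_constants$af_default,
                            af_kind = c("default_044", "af_total", "af_photo"),
                            min_steps = 5) {
  stopifnot(inherits(trace, "rlc_trace"))
  af_kind <- match.arg(af_kind)
  if (!is.numeric(af) || length(af) != 1 || af <= 0 || af > 1) {
    stop_photo("af must lie in (0, 1]", class = "photoacclim_config_error")
  }
  valid <- is.finite(trace$f) & is.finite(trace$fm_prime) & trace$fm_prime > 0
  n_dropped <- sum(!valid)
  if (sum(valid) < min_steps) {
    stop_photo("insufficient data: ", sum(valid), " valid steps (need >= ",
               min_steps, ")", class = "photoacclim_insufficient_data")
  }
  par <- trace$actinic_par[valid]
  yii <- as.numeric(quantum_yield(trace$f[valid], trace$fm_prime[valid]))
  clamped <- yii < 0
  yii[clamped] <- 0
  structure(list(
    par = par,
    etr = yii * par * af * photo_constants$psii_fraction,
    yii = yii,
    af_used = af, af_kind = af_kind,
    n_dropped = n_dropped, n_clamped = sum(clamped),
    shoot_id = trace$shoot_id, container_id = trace$container_id,
    treatment_par = trace$treatment_par, day = trace$day
  ), class = "etr_curve")
}

#' Platt photosynthesis-irradiance model with photoinhibition
#'
#' The double-exponential saturation curve
#' \deqn{P(E) = P_s (1 - e^{-\alpha E / P_s}) e^{-\beta E / P_s}}
#' where `Ps` is the scale parameter, `alpha` the initial slope (quantum
#' efficiency proxy) and `beta` the photoinhibition parameter. `P(0) = 0` and
#' `dP/dE` at 0 equals `alpha`.
#'
#' @param e irradiance (umol photons m-2 s-1).
#' @param ps,alpha,beta model parameters; `ps > 0`, `alpha > 0`, `beta >= 0`.
#' @return Modelled ETR at `e`.
#' @export
platt_model <- function(e, ps, alpha, beta = 0) {
  if (any(ps <= 0) || any(alpha <= 0) || any(beta < 0)) {
    stop_photo("require ps > 0, alpha > 0, beta >= 0",
               class = "photoacclim_parameter_error")
  }
  ps * (1 - exp(-alpha * e / ps)) * exp(-beta * e / ps)
}

#' Derived photosynthetic parameters ETRmax and Ek
#'
#' Closed forms for the plateau (`etr_max`) and the onset of light
#' saturation (`ek = etr_max / alpha`):
#' \deqn{ETR_{max} = P_s \frac{\alpha}{\alpha+\beta}
#'       \left(\frac{\beta}{\alpha+\beta}\right)^{\beta/\alpha}}
#' for `beta > 0`, continuously extended to `ETRmax = Ps` at `beta = 0`.
#'
#' @inheritParams platt_model
#' @return Named list with `etr_max` and `ek`.
#' @export
platt_derived <- function(ps, alpha, beta = 0) {
  if (any(ps <= 0) || any(alpha <= 0) || any(beta < 0)) {
    stop_photo("require ps > 0, alpha > 0, beta >= 0",
               class = "photoacclim_parameter_error")
  }
  etr_max <- ifelse(
    beta == 0, ps,
    ps * (alpha / (alpha + beta)) *
      (beta / (alpha + beta))^(beta / alpha)
  )
  list(etr_max = as.numeric(etr_max), ek = as.numeric(etr_max / alpha))
}

# sum of squared residuals of the Platt model on a curve
platt_sse <- function(theta, e, y) {
  p <- platt_model(e, theta[1], theta[2], theta[3])
  sum((y - p)^2)
}

#' Fit the Platt model to an ETR curve
#'
#' Bounded least squares in the parameters `(Ps, alpha, beta)` using the Port
#' algorithm of [stats::nls()] (with a bounded quasi-Newton
#' [stats::optim()] fallback), multi-started from a slope/plateau heuristic:
#' `alpha0` is the origin-constrained OLS slope of the three lowest-irradiance
#' points, `Ps0` the maximum observed ETR, and `beta0` in `{0, 0.01 alpha0}`.
#' Bounds: `Ps` in (0, 10 max ETR\], `alpha` in (0, 10 max secant slope\],
#' `beta` in \[0, upper(alpha)\]. Fits landing on the lower `beta` bound
#' report `beta = 0` (no photoinhibition).
#'
#' @param curve an [build_etr_curve()] result, or any list with numeric
#'   `par` and `etr` components.
#' @param weights `"none"` (unweighted SSE, default) or `"relative"`
#'   (residuals scaled by fitted value magnitudes).
#' @param qc apply the saturation QC rule ([qc_saturation()]) to the result?
#' @param max_actinic highest actinic step of the protocol, used by QC.
#' @return An object of class `platt_fit` with components `coefficients`
#'   (`ps`, `alpha`, `beta`), `etr_max`, `ek`, `sse`, `converged`, `rejected`,
#'   `reject_reason`, `fitted`, `residuals` and the input `curve`.
#' @examples
#' e <- photo_constants$rlc_steps
#' y <- platt_model(e, ps = 60, alpha = 0.15)
#' fit <- fit_platt(list(par = e, etr = y))
#' coef(fit)
#' @export
fit_platt <- function(curve, weights = c("none", "relative"), qc = TRUE,
                      max_actinic = max(curve$par)) {
  weights <- match.arg(weights)
  e <- as.numeric(curve$par)
  y <- as.numeric(curve$etr)
  keep <- is.finite(e) & is.finite(y)
  e <- e[keep]; y <- y[keep]
  if (length(e) < 5) {
    stop_photo("insufficient data: need >= 5 finite points",
               class = "photoacclim_insufficient_data")
  }
  if (max(y) <= 0) {
    return(new_platt_fit(curve, c(ps = NA, alpha = NA, beta = NA),
                         sse = NA_real_, converged = FALSE,
                         rejected = TRUE, reason = "all ETR non-positive"))
  }

  ord <- order(e)
  e3 <- head(e[ord], 3); y3 <- head(y[ord], 3)
  alpha0 <- max(sum(e3 * y3) / sum(e3^2), 1e-6)
  ps0 <- max(y)
  slope_max <- max(y[e > 0] / e[e > 0])
  upper <- c(ps = 10 * max(y), alpha = 10 * slope_max, beta = 10 * slope_max)
  lower <- c(ps = 1e-8, alpha = 1e-8, beta = 0)
  starts <- list(c(ps0, alpha0, 0), c(ps0, alpha0, 0.01 * alpha0))

  w <- if (weights == "relative") 1 / pmax(abs(y), 1e-8)^2 else
    rep(1, length(y))
  obj <- function(theta) {
    p <- platt_model(e, max(theta[1], lower[1]), max(theta[2], lower[2]),
                     max(theta[3], 0))
    sum(w * (y - p)^2)
  }

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(suppressWarnings({
      df <- data.frame(e = e, y = y)
      m <- stats::nls(
        y ~ platt_model(e, ps, alpha, beta), data = df,
        start = list(ps = st[1], alpha = st[2], beta = st[3]),
        algorithm = "port", lower = lower, upper = upper,
        weights = w,
        control = stats::nls.control(maxiter = 200, warnOnly = TRUE)
      )
      th <- stats::coef(m)
      list(theta = th, sse = obj(th), converged = m$convInfo$isConv)
    }), error = function(err) NULL)
    if (is.null(fit)) {
      o <- stats::optim(st, obj, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(maxit = 500))
      fit <- list(theta = o$par, sse = o$value, converged = o$convergence == 0)
    } else {
      # polish: port occasionally stops early near zero-residual solutions
      o <- stats::optim(fit$theta, obj, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(maxit = 500))
      if (o$value < fit$sse) {
        fit <- list(theta = o$par, sse = o$value,
                    converged = fit$converged || o$convergence == 0)
      }
    }
    if (is.null(best) || fit$sse < best$sse) best <- fit
  }

  theta <- pmin(pmax(best$theta, lower), upper)
  names(theta) <- c("ps", "alpha", "beta")
  if (theta["beta"] <= 1e-10) theta["beta"] <- 0
  res <- new_platt_fit(curve, theta, sse = platt_sse(theta, e, y),
                       converged = isTRUE(best$converged),
                       rejected = FALSE, reason = NA_character_)
  if (qc && res$converged) res <- qc_saturation(res, max_actinic = max_actinic)
  res
}

new_platt_fit <- function(curve, theta, sse, converged, rejected, reason) {
  der <- if (anyNA(theta)) list(etr_max = NA_real_, ek = NA_real_) else
    platt_derived(theta[["ps"]], theta[["alpha"]], theta[["beta"]])
  fitted <- if (anyNA(theta)) rep(NA_real_, length(curve$par)) else
    platt_model(curve$par, theta[["ps"]], theta[["alpha"]], theta[["beta"]])
  structure(list(
    coefficients = theta,
    etr_max = der$etr_max, ek = der$ek,
    sse = sse, converged = converged,
    rejected = rejected, reject_reason = reason,
    fitted = fitted, residuals = curve$etr - fitted,
    curve = curve
  ), class = "platt_fit")
}

#' Saturation quality-control rule for fitted light curves
#'
#' Curves with no saturation of electron transport even at the highest
#' actinic light reflect technical problems and are rejected. Two sub-rules,
#' logged separately in `reject_reason`:
#' (i) fitted `Ek` exceeds the highest actinic irradiance of the protocol;
#' (ii) the secant slope of the last two steps exceeds 50\% of the fitted
#' initial slope `alpha` (the curve is still rising steeply at the top).
#'
#' @param fit a `platt_fit`.
#' @param max_actinic highest actinic irradiance reached by the protocol.
#' @param tail_slope_frac tail-slope threshold as a fraction of alpha.
#' @return The fit with `rejected`/`reject_reason` updated. Rejection is
#'   data, not an error.
#' @export
qc_saturation <- function(fit, max_actinic = max(fit$curve$par),
                          tail_slope_frac = 0.5) {
  stopifnot(inherits(fit, "platt_fit"))
  if (!fit$converged) return(fit)
  reasons <- character(0)
  if (is.finite(fit$ek) && fit$ek > max_actinic) {
    reasons <- c(reasons, "ek_above_max_actinic")
  }
  e <- fit$curve$par; y <- fit$curve$etr
  n <- length(e)
  if (n >= 2) {
    tail_slope <- (y[n] - y[n - 1]) / (e[n] - e[n - 1])
    if (is.finite(tail_slope) &&
        tail_slope > tail_slope_frac * fit$coefficients[["alpha"]]) {
      reasons <- c(reasons, "tail_slope_above_half_alpha")
    }
  }
  if (length(reasons)) {
    fit$rejected <- TRUE
    fit$reject_reason <- paste(reasons, collapse = ";")
  }
  fit
}

# S3 methods ------------------------------------------------------------------

#' @export
print.platt_fit <- function(x, digits = 4, ...) {
  cat("Platt photosynthesis-irradiance fit\n")
  cat(sprintf("  Ps = %.*g, alpha = %.*g, beta = %.*g\n",
              digits, x$coefficients[["ps"]], digits,
              x$coefficients[["alpha"]], digits, x$coefficients[["beta"]]))
  cat(sprintf("  ETRmax = %.*g umol electrons m-2 s-1, Ek = %.*g umol photons m-2 s-1\n",
              digits, x$etr_max, digits, x$ek))
  cat(sprintf("  SSE = %.*g, converged: %s", digits, x$sse, x$converged))
  if (isTRUE(x$rejected)) cat(", REJECTED (", x$reject_reason, ")", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
coef.platt_fit <- function(object, ...) object$coefficients

#' @export
fitted.platt_fit <- function(object, ...) object$fitted

#' @export
residuals.platt_fit <- function(object, ...) object$residuals

#' @export
predict.platt_fit <- function(object, newdata = NULL, ...) {
  e <- if (is.null(newdata)) object$curve$par else
    if (is.list(newdata)) newdata$par else as.numeric(newdata)
  th <- object$coefficients
  platt_model(e, th[["ps"]], th[["alpha"]], th[["beta"]])
}

#' @export
summary.platt_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.platt_fit")
}

#' @export
print.summary.platt_fit <- function(x, ...) {
  print(x$fit)
  r <- x$fit$residuals
  cat(sprintf("  residuals: min %.4g, median %.4g, max %.4g (n = %d)\n",
              min(r), stats::median(r), max(r), length(r)))
  invisible(x)
}

#' @export
plot.platt_fit <- function(x, ...) {
  e <- x$curve$par
  grid <- seq(0, max(e), length.out = 200)
  plot(e, x$curve$etr, xlab = "PAR (umol photons m-2 s-1)",
       ylab = "ETR (umol electrons m-2 s-1)", pch = 19, ...)
  graphics::lines(grid, predict(x, grid), col = "steelblue", lwd = 2)
  graphics::abline(v = x$ek, lty = 3)
  invisible(x)
}
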