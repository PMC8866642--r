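#' Hierarchical irradiance-response model (HGAM)
#'
#' Fits a penalized-spline irradiance-response model of the kind used for
#' photoacclimation gradients: a cubic regression spline in growth PAR with
#' at most `k = 7` basis functions (one per design irradiance level, PAR
#' treated as continuous), optionally one smooth per group (measurement date
#' or absorptance-estimation method) together with the group main effect,
#' plus Gaussian random intercepts for containers and shoots. Fitting is by
#' penalized likelihood via [mgcv::gam()]; the smoothing parameter is chosen
#' by GCV by default (REML available).
#'
#' The straight line lies in the penalty null space, so linear responses are
#' reproduced exactly at any smoothing parameter, and as the smoothing
#' parameter grows the fit converges to the ordinary least-squares line.
#'
#' @param data data frame with the predictor and response columns plus any
#'   grouping/random-effect columns.
#' @param response name of the response column.
#' @param par name of the irradiance column (default `"treatment_par"`).
#' @param group optional name of a grouping factor column (e.g. `"day"` or
#'   `"af_kind"`) yielding group-specific smooths and a group main effect.
#' @param random character vector of random-intercept columns, any of the
#'   data's columns (default `c("container_id", "shoot_id")` when present).
#' @param k maximum basis dimension for the PAR smooth; reduced
#'   automatically (with a warning) when the data have fewer distinct PAR
#'   values than `k`.
#' @param method smoothing-parameter criterion: `"GCV.Cp"` (default) or
#'   `"REML"`.
#' @param sp optional fixed smoothing parameter(s) for the PAR smooth(s);
#'   random-effect terms are always estimated.
#' @param log_par model the smooth on `log(PAR + 1)`? The design levels are
#'   near-geometric; default `FALSE`.
#' @param weights optional observation weights.
#' @return Object of class `hgam_fit` wrapping the `mgcv::gam` fit with the
#'   model metadata.
#' @examples
#' d <- data.frame(treatment_par = rep(photo_constants$treatment_par, 3))
#' d$y <- 0.1 + 0.002 * d$treatment_par + rnorm(nrow(d), 0, 0.01)
#' fit <- fit_hgam(d, response = "y", random = NULL)
#' predict(fit, new_par = c(10, 100, 500))
#' @export
fit_hgam <- function(data, response, par = "treatment_par", group = NULL,
                     random = intersect(c("container_id", "shoot_id"),
                                        names(data)),
                     k = 7, method = c("GCV.Cp", "REML"), sp = NULL,
                     log_par = FALSE, weights = NULL) {
  method <- match.arg(method)
  for (col in c(response, par, group, random)) {
    if (!col %in% names(data)) {
      stop_photo("column not found: ", col, class = "photoacclim_input_error")
    }
  }
  d <- data.frame(
    .y = data[[response]],
    .par = if (log_par) log(data[[par]] + 1) else data[[par]]
  )
  d <- cbind(d, data[setdiff(names(data), names(d))])
  if (!is.null(group)) d[[group]] <- factor(data[[group]])
  for (r in random) d[[r]] <- factor(data[[r]])
  keep <- is.finite(d$.y) & is.finite(d$.par)
  d <- d[keep, , drop = FALSE]
  if (!is.null(weights)) weights <- weights[keep]

  n_levels <- length(unique(d$.par))
  if (n_levels < 2) {
    stop_photo("need >= 2 distinct PAR levels",
               class = "photoacclim_input_error")
  }
  if (!is.null(group)) {
    per_group <- tapply(d$.par, d[[group]], function(x) length(unique(x)))
    if (any(per_group < 2)) {
      stop_photo("a group has fewer than 2 PAR levels",
                 class = "photoacclim_input_error")
    }
    n_levels <- min(per_group)
  }
  if (k > n_levels) {
    warning("basis dimension k = ", k, " reduced to ", n_levels,
            " (number of distinct PAR levels)")
    k <- n_levels
  }

  smooth_term <- if (is.null(group)) {
    sprintf("s(.par, k = %d, bs = \"cr\")", k)
  } else {
    sprintf("%s + s(.par, by = %s, k = %d, bs = \"cr\")", group, group, k)
  }
  re_terms <- vapply(random, function(r) sprintf("s(%s, bs = \"re\")", r), "")
  fml <- stats::as.formula(
    paste(".y ~", paste(c(smooth_term, re_terms), collapse = " + "))
  )

  sp_full <- NULL
  if (!is.null(sp)) {
    n_par_smooths <- if (is.null(group)) 1 else nlevels(d[[group]])
    sp_full <- c(rep_len(sp, n_par_smooths), rep(-1, length(random)))
  }
  gm <- mgcv::gam(fml, data = d, method = method, sp = sp_full,
                  weights = weights)
  structure(list(
    gam = gm, data = d, response = response, par = par, group = group,
    random = random, k = k, method = method, log_par = log_par,
    par_range = range(d$.par)
  ), class = "hgam_fit")
}

#' @export
print.hgam_fit <- function(x, ...) {
  cat("Hierarchical irradiance-response model (penalized spline, k =",
      x$k, ")\n")
  cat("  response:", x$response,
      if (!is.null(x$group)) paste("| group-specific smooths by", x$group),
      "\n")
  if (length(x$random)) {
    cat("  random intercepts:", paste(x$random, collapse = ", "), "\n")
  }
  s <- summary(x$gam)
  cat(sprintf("  R2 (adj.) = %.3f, deviance explained = %.1f%%, n = %d\n",
              s$r.sq, 100 * s$dev.expl, stats::nobs(x$gam)))
  invisible(x)
}

#' Model summary mirroring an HGAM results table
#'
#' Per-term statistics: parametric terms (e.g. the group main effect) report
#' t statistics, smooth terms report approximate F statistics, each with its
#' p-value; plus adjusted R-squared, deviance explained and n.
#'
#' @param object an `hgam_fit`.
#' @param ... unused.
#' @return Object of class `summary.hgam_fit` with a `terms` data frame
#'   (`term`, `stat_type`, `statistic`, `p_value`) and scalars `r_sq_adj`,
#'   `dev_expl`, `n`.
#' @export
summary.hgam_fit <- function(object, ...) {
  s <- summary(object$gam)
  pt <- s$p.table
  param <- if (nrow(pt) > 1) {
    data.frame(
      term = rownames(pt)[-1],     # drop intercept
      stat_type = "t",
      statistic = pt[-1, "t value"],
      p_value = pt[-1, "Pr(>|t|)"],
      row.names = NULL
    )
  } else {
    data.frame(term = character(0), stat_type = character(0),
               statistic = numeric(0), p_value = numeric(0))
  }
  st <- s$s.table
  smooths <- data.frame(
    term = rownames(st),
    stat_type = "F",
    statistic = st[, "F"],
    p_value = st[, "p-value"],
    row.names = NULL
  )
  structure(list(
    terms = rbind(param, smooths),
    r_sq_adj = s$r.sq, dev_expl = s$dev.expl, n = stats::nobs(object$gam)
  ), class = "summary.hgam_fit")
}

#' @export
print.summary.hgam_fit <- function(x, ...) {
  print(x$terms, row.names = FALSE)
  cat(sprintf("R2 (adj.) = %.3f, deviance explained = %.1f%%, n = %d\n",
              x$r_sq_adj, 100 * x$dev_expl, x$n))
  invisible(x)
}

# newdata for population-level prediction: random effects at reference level,
# then excluded from the linear predictor
hgam_newdata <- function(fit, new_par, group_level = NULL) {
  nd <- data.frame(.par = if (fit$log_par) log(new_par + 1) else new_par)
  if (!is.null(fit$group)) {
    lev <- if (is.null(group_level)) levels(fit$data[[fit$group]])[1] else
      as.character(group_level)
    nd[[fit$group]] <- factor(lev, levels = levels(fit$data[[fit$group]]))
  }
  for (r in fit$random) {
    nd[[r]] <- factor(levels(fit$data[[r]])[1],
                      levels = levels(fit$data[[r]]))
  }
  nd
}

#' Population-level predictions with pointwise confidence intervals
#'
#' Predicts the fitted irradiance response at new PAR values with Gaussian
#' pointwise intervals `fit +/- z se`, random effects set to zero (excluded
#' from the linear predictor). Predictions outside the design PAR range are
#' returned but flagged as extrapolation.
#'
#' @param object an `hgam_fit`.
#' @param new_par PAR values to predict at.
#' @param level confidence level, default 0.95.
#' @param group_level group level to predict for (first level by default).
#' @param ... unused.
#' @return Data frame with `par`, `fit`, `se`, `lower`, `upper`,
#'   `extrapolated`.
#' @export
predict.hgam_fit <- function(object, new_par, level = 0.95,
                             group_level = NULL, ...) {
  nd <- hgam_newdata(object, new_par, group_level)
  excl <- vapply(object$random, function(r) sprintf("s(%s)", r), "")
  pr <- mgcv::predict.gam(object$gam, newdata = nd, se.fit = TRUE,
                          exclude = if (length(excl)) excl else NULL,
                          newdata.guaranteed = TRUE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  extrap <- nd$.par < object$par_range[1] | nd$.par > object$par_range[2]
  if (any(extrap)) warning("prediction outside the design PAR range flagged")
  data.frame(
    par = new_par,
    fit = as.numeric(pr$fit), se = as.numeric(pr$se.fit),
    lower = as.numeric(pr$fit) - z * as.numeric(pr$se.fit),
    upper = as.numeric(pr$fit) + z * as.numeric(pr$se.fit),
    extrapolated = extrap
  )
}

#' @export
plot.hgam_fit <- function(x, n_grid = 100, level = 0.95, ...) {
  grid <- seq(x$par_range[1], x$par_range[2], length.out = n_grid)
  groups <- if (is.null(x$group)) list(NULL) else
    as.list(levels(x$data[[x$group]]))
  preds <- lapply(groups, function(g) predict(x, grid, level, g))
  ylim <- range(unlist(lapply(preds, function(p) c(p$lower, p$upper))))
  plot(NA, xlim = range(grid), ylim = ylim,
       xlab = "PAR (umol photons m-2 s-1)", ylab = x$response, ...)
  for (i in seq_along(preds)) {
    p <- preds[[i]]
    graphics::polygon(c(p$par, rev(p$par)), c(p$lower, rev(p$upper)),
                      col = grDevices::adjustcolor(i + 1, 0.2), border = NA)
    graphics::lines(p$par, p$fit, col = i + 1, lwd = 2)
  }
  invisible(x)
}

#' Irradiance regions where two fits' confidence intervals do not overlap
#'
#' Evaluates both models' pointwise intervals on a PAR grid and returns the
#' contiguous intervals where one band lies entirely above the other --
#' the graphical criterion used to locate where two response curves (e.g.
#' day 5 vs day 25) diverge.
#'
#' @param fit_a,fit_b `hgam_fit` objects (or data frames with `par`,
#'   `lower`, `upper` already on a shared grid).
#' @param par_grid PAR values to scan.
#' @param level confidence level.
#' @param group_level_a,group_level_b group levels for each prediction when
#'   a single grouped fit is compared against itself.
#' @return Data frame with `start`, `end` (PAR) per non-overlap run; zero
#'   rows when the bands always overlap.
#' @export
ci_overlap_regions <- function(fit_a, fit_b, par_grid = NULL, level = 0.95,
                               group_level_a = NULL, group_level_b = NULL) {
  get_band <- function(f, g) {
    if (is.data.frame(f)) return(f)
    grid <- if (is.null(par_grid))
      seq(f$par_range[1], f$par_range[2], length.out = 200) else par_grid
    predict(f, grid, level = level, group_level = g)
  }
  a <- get_band(fit_a, group_level_a)
  b <- get_band(fit_b, group_level_b)
  if (nrow(a) != nrow(b) || any(a$par != b$par)) {
    stop_photo("fits must be evaluated on the same PAR grid",
               class = "photoacclim_input_error")
  }
  sep <- a$upper < b$lower | b$upper < a$lower
  if (!any(sep)) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  r <- rle(sep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  idx <- which(r$values)
  data.frame(start = a$par[starts[idx]], end = a$par[ends[idx]])
}

#' Two-sample threshold test with assumption diagnostics
#'
#' Welch two-sample t-test (pooled-variance optional) used to confirm a
#' threshold suggested by the fitted response curves, e.g. comparing a
#' parameter between the 133 and 355 umol photons m-2 s-1 treatments.
#' Shapiro-Wilk normality p-values per group and the Fligner-Killeen
#' homogeneity p-value are attached as assumption flags; they do not switch
#' the test automatically.
#'
#' @param values_low,values_high samples from the two treatments (>= 3 each).
#' @param var_equal pooled-variance t-test instead of Welch?
#' @return List with `t`, `df`, `p_value`, `shapiro_p_low`, `shapiro_p_high`,
#'   `fligner_p`, `method`.
#' @export
threshold_ttest <- function(values_low, values_high, var_equal = FALSE) {
  values_low <- values_low[is.finite(values_low)]
  values_high <- values_high[is.finite(values_high)]
  if (length(values_low) < 3 || length(values_high) < 3) {
    stop_photo("need >= 3 finite values per group",
               class = "photoacclim_insufficient_data")
  }
  if (stats::var(values_low) == 0 && stats::var(values_high) == 0) {
    stop_photo("both groups have zero variance",
               class = "photoacclim_input_error")
  }
  tt <- stats::t.test(values_low, values_high, var.equal = var_equal)
  grp <- factor(rep(c("low", "high"),
                    c(length(values_low), length(values_high))))
  list(
    t = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value,
    shapiro_p_low = tryCatch(stats::shapiro.test(values_low)$p.value,
                             error = function(e) NA_real_),
    shapiro_p_high = tryCatch(stats::shapiro.test(values_high)$p.value,
                              error = function(e) NA_real_),
    fligner_p = stats::fligner.test(c(values_low, values_high), grp)$p.value,
    method = if (var_equal) "pooled" else "welch"
  )
}

#' Net primary production irradiance model with respiration anchor
#'
#' Fits the NPP-vs-growth-irradiance HGAM with the PAR = 0 anchor included
#' as data: NPP at zero irradiance equals minus the mean respiration
#' magnitude, the measured dark metabolic cost. The anchored model is the
#' input to [estimate_mqr()].
#'
#' @param npp_table data frame with at least `treatment_par` and `npp`
#'   columns, plus optional `container_id` / `shoot_id` random-effect
#'   columns.
#' @param mean_r_magnitude magnitude of the mean respiration rate
#'   (umol O2 cm-2 h-1, > 0).
#' @param anchor_weight total weight of the anchor constraint (default 1).
#' @param ... passed to [fit_hgam()].
#' @return An `hgam_fit` whose data include the anchor rows; the anchor
#'   magnitude is stored as `anchor_respiration`.
#' @details The anchor is a population-level datum, so when the model has a
#'   container random intercept the anchor is replicated once per container
#'   level (total weight `anchor_weight`): a pull shared by every level
#'   cannot be absorbed into the shrunken intercepts and therefore acts on
#'   the smooth itself, which is what a compensation-point constraint must
#'   do. A single pseudo-level would instead be soaked up by its own random
#'   intercept and leave the population curve unconstrained.
#' @export
npp_irradiance_model <- function(npp_table, mean_r_magnitude,
                                 anchor_weight = 1, ...) {
  if (mean_r_magnitude <= 0) {
    stop_photo("mean_r_magnitude must be > 0",
               class = "photoacclim_input_error")
  }
  reps <- if ("container_id" %in% names(npp_table)) {
    unique(as.character(npp_table$container_id))
  } else NA_character_
  anchor <- npp_table[rep(1, length(reps)), , drop = FALSE]
  anchor[] <- NA
  anchor$treatment_par <- 0
  anchor$npp <- -mean_r_magnitude
  if ("container_id" %in% names(npp_table)) anchor$container_id <- reps
  if ("shoot_id" %in% names(npp_table)) anchor$shoot_id <- reps
  d <- rbind(npp_table, anchor)
  w <- c(rep(1, nrow(npp_table)), rep(anchor_weight / length(reps),
                                      length(reps)))
  fit <- fit_hgam(d, response = "npp", weights = w, ...)
  fit$anchor_respiration <- mean_r_magnitude
  fit
}

#' Minimum quantum requirement (compensation irradiance)
#'
#' The irradiance at which fitted net primary production is zero, i.e. gross
#' photosynthesis exactly balances respiration. Found as the smallest root
#' of the population-level fitted NPP curve on \[0, PAR at maximum fitted
#' NPP\], by bisection to an absolute tolerance of 0.01 umol photons m-2 s-1.
#' If the fitted curve never changes sign the result is flagged
#' (`no_root = TRUE`), not an error.
#'
#' @param npp_fit an anchored NPP `hgam_fit` (see [npp_irradiance_model()]),
#'   or any `hgam_fit` whose fitted response crosses zero.
#' @param tol absolute bisection tolerance in umol photons m-2 s-1.
#' @param n_grid grid resolution used to bracket the root.
#' @return Object of class `mqr_estimate`: `mqr` (umol photons m-2 s-1 or
#'   `NA`), `no_root`, `anchor_respiration`, `bracket`, `tol`.
#' @export
estimate_mqr <- function(npp_fit, tol = 0.01, n_grid = 400) {
  stopifnot(inherits(npp_fit, "hgam_fit"))
  lo <- max(0, npp_fit$par_range[1])
  hi <- npp_fit$par_range[2]
  grid <- seq(lo, hi, length.out = n_grid)
  f <- function(p) suppressWarnings(predict(npp_fit, p))$fit
  fx <- f(grid)
  hi_search <- grid[which.max(fx)]
  idx <- which(grid <= hi_search)
  cross <- which(fx[idx][-1] * fx[idx][-length(idx)] <= 0 &
                   fx[idx][-length(idx)] < 0)
  if (fx[1] >= 0 || length(cross) == 0) {
    return(structure(list(mqr = NA_real_, no_root = TRUE,
                          anchor_respiration = npp_fit$anchor_respiration,
                          bracket = c(lo, hi_search), tol = tol),
                     class = "mqr_estimate"))
  }
  i <- cross[1]
  root <- stats::uniroot(f, lower = grid[i], upper = grid[i + 1],
                         tol = tol)$root
  structure(list(mqr = root, no_root = FALSE,
                 anchor_respiration = npp_fit$anchor_respiration,
                 bracket = c(grid[i], grid[i + 1]), tol = tol),
            class = "mqr_estimate")
}

#' @export
print.mqr_estimate <- function(x, ...) {
  if (x$no_root) {
    cat("No compensation point: fitted NPP does not cross zero\n")
  } else {
    cat(sprintf("Minimum quantum requirement: %.2f umol photons m-2 s-1\n",
                x$mqr))
    if (!is.null(x$anchor_respiration)) {
      cat(sprintf("  (anchored at NPP = -%.3f umol O2 cm-2 h-1 at PAR 0)\n",
                  x$anchor_respiration))
    }
  }
  invisible(x)
}

#' Convert an instantaneous irradiance to a daily light dose
#'
#' \eqn{dose = PAR \times 3600 \times photoperiod \times 10^{-6}} in mol
#' photons m-2 d-1, for a constant irradiance held over the experimental
#' photoperiod (14 h light by default).
#'
#' @param par irradiance in umol photons m-2 s-1 (>= 0).
#' @param photoperiod_h light hours per day, in (0, 24\].
#' @return Daily dose in mol photons m-2 d-1.
#' @examples
#' convert_par_to_daily(13.7)   # 0.69 mol m-2 d-1
#' convert_par_to_daily(200)    # 10.08 mol m-2 d-1
#' @export
convert_par_to_daily <- function(par,
                                 photoperiod_h = photo_constants$photoperiod_h) {
  check_number(par, "par", lower = 0)
  if (any(photoperiod_h <= 0 | photoperiod_h > 24)) {
    stop_photo("photoperiod_h must lie in (0, 24]",
               class = "photoacclim_input_error")
  }
  par * 3600 * photoperiod_h * 1e-6
}
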