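#' Oxygen-evolution slope of an incubation series
#'
#' Ordinary least-squares slope (with intercept) of dissolved O2
#' concentration against time. The protocol records four readings 20 min
#' apart per phase, but any series with at least two distinct times is
#' accepted. The intercept absorbs the arbitrary starting concentration, so
#' rates are invariant to a constant offset in the readings.
#'
#' @param time_h times in hours, not all equal.
#' @param o2_umol_l dissolved O2 in umol L-1.
#' @return List with `slope` (umol O2 L-1 h-1), `se`, `r_squared`, `n`.
#' @export
o2_slope <- function(time_h, o2_umol_l) {
  if (length(time_h) < 2 || length(o2_umol_l) != length(time_h)) {
    stop_photo("need >= 2 paired (time, O2) readings",
               class = "photoacclim_insufficient_data")
  }
  if (stats::var(time_h) == 0) {
    stop_photo("zero variance in time", class = "photoacclim_input_error")
  }
  fit <- stats::lm(o2_umol_l ~ time_h)
  sm <- suppressWarnings(summary(fit))   # zero-residual series are legitimate
  list(slope = unname(stats::coef(fit)[2]),
       se = if (nrow(sm$coefficients) > 1 && ncol(sm$coefficients) > 1)
         sm$coefficients[2, 2] else NA_real_,
       r_squared = sm$r.squared,
       n = length(time_h))
}

#' Metabolic rates from paired light/dark incubations
#'
#' Converts the light- and dark-phase O2 slopes of one shoot's sealed-bottle
#' incubation into surface-standardized rates:
#' \deqn{NPP = \alpha_{light} \cdot vol / S_{photo}}
#' \deqn{GPP = (\alpha_{light} - \alpha_{dark}) \cdot vol / S_{photo}}
#' \deqn{R = \alpha_{dark} \cdot vol / S_{total}}
#' NPP and GPP are standardized to the photosynthetic (green) leaf surface,
#' respiration to the total leaf surface; all surfaces are one-sided areas.
#' Slopes keep their measured sign, so respiration is normally negative.
#'
#' @param light,dark lists with `time_h` and `o2_umol_l` for each phase, or
#'   precomputed slope lists as returned by [o2_slope()].
#' @param volume_l bottle volume in L (protocol 0.3).
#' @param ps_surface_cm2 photosynthetic leaf surface, cm2, one side.
#' @param total_surface_cm2 total leaf surface, cm2, one side.
#' @return Object of class `metabolic_rates`: `npp`, `gpp`, `r`
#'   (umol O2 cm-2 h-1), `slope_light`, `slope_dark`, `se_light`, `se_dark`.
#' @examples
#' rates(light = list(slope = 2, se = 0), dark = list(slope = -1, se = 0),
#'       volume_l = 0.3, ps_surface_cm2 = 12, total_surface_cm2 = 15)
#' @export
rates <- function(light, dark, volume_l = 0.3,
                  ps_surface_cm2, total_surface_cm2) {
  if (volume_l <= 0) {
    stop_photo("volume_l must be > 0", class = "photoacclim_input_error")
  }
  if (ps_surface_cm2 <= 0 || total_surface_cm2 <= 0 ||
      ps_surface_cm2 > total_surface_cm2) {
    stop_photo("require 0 < ps_surface_cm2 <= total_surface_cm2",
               class = "photoacclim_input_error")
  }
  sl <- if (!is.null(light$slope)) light else
    o2_slope(light$time_h, light$o2_umol_l)
  sd_ <- if (!is.null(dark$slope)) dark else
    o2_slope(dark$time_h, dark$o2_umol_l)
  structure(list(
    npp = sl$slope * volume_l / ps_surface_cm2,
    gpp = (sl$slope - sd_$slope) * volume_l / ps_surface_cm2,
    r = sd_$slope * volume_l / total_surface_cm2,
    slope_light = sl$slope, slope_dark = sd_$slope,
    se_light = sl$se, se_dark = sd_$se,
    volume_l = volume_l,
    ps_surface_cm2 = ps_surface_cm2,
    total_surface_cm2 = total_surface_cm2
  ), class = "metabolic_rates")
}

#' @export
print.metabolic_rates <- function(x, ...) {
  cat(sprintf("NPP = %.4g, GPP = %.4g, R = %.4g umol O2 cm-2 h-1\n",
              x$npp, x$gpp, x$r))
  invisible(x)
}

#' Mean respiration rate across shoots
#'
#' Arithmetic mean of the signed respiration rates with its standard error.
#' The magnitude of this mean is the PAR = 0 anchor of the net primary
#' production irradiance model used for the minimum quantum requirement.
#'
#' @param r signed respiration rates (umol O2 cm-2 h-1), or a list of
#'   `metabolic_rates` objects.
#' @return List with `mean`, `se` (`NA` flagged for n = 1), `n` and
#'   `magnitude` (= `abs(mean)`).
#' @export
mean_respiration <- function(r) {
  if (is.list(r) && !is.data.frame(r)) {
    r <- vapply(r, function(x) x$r, numeric(1))
  }
  r <- r[is.finite(r)]
  if (length(r) == 0) {
    stop_photo("no finite respiration rates", class = "photoacclim_input_error")
  }
  m <- mean(r)
  se <- if (length(r) > 1) stats::sd(r) / sqrt(length(r)) else NA_real_
  list(mean = m, se = se, n = length(r), magnitude = abs(m))
}
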