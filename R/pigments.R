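#' Spectrophotometric pigment coefficient sets
#'
#' Lichtenthaler-type trichromatic equations for chlorophyll a, chlorophyll b
#' and total carotenoids from extract absorbances at 470, 645 and 662 nm
#' (1-cm path, blank-corrected). The default set is for 100% acetone, the
#' extraction solvent of the protocol; the table keeps the solvent explicit
#' so another set can be swapped in.
#'
#' Concentrations in ug mL-1 of extract:
#' \itemize{
#'   \item chla = 11.24 A662 - 2.04 A645
#'   \item chlb = 20.13 A645 - 4.19 A662
#'   \item carotenoids = (1000 A470 - 1.90 chla - 63.14 chlb) / 214
#' }
#' @format Data frame with one row per solvent.
#' @export
pigment_coefficients <- data.frame(
  solvent = "acetone_100",
  chla_a662 = 11.24, chla_a645 = -2.04,
  chlb_a645 = 20.13, chlb_a662 = -4.19,
  car_a470 = 1000, car_chla = -1.90, car_chlb = -63.14, car_denom = 214,
  stringsAsFactors = FALSE
)

#' Pigment contents from extract absorbances
#'
#' Converts blank-corrected extract absorbances at 470, 645 and 662 nm into
#' chlorophyll a, chlorophyll b and total carotenoid contents, standardized
#' to leaf fresh weight: concentration (ug mL-1) x extract volume (mL) /
#' fresh weight (g) / 1000 = mg pigment g-1 FW.
#'
#' A negative intermediate concentration (possible with distorted spectra)
#' fails QC: the affected pigment is reported as `NA` and `qc_flag` is set,
#' never silently truncated.
#'
#' @param a470,a645,a662 absorbances (dimensionless, >= 0, 1-cm path).
#' @param extract_volume_ml extract volume in mL (protocol default 10).
#' @param fresh_weight_g leaf fresh weight in g (> 0).
#' @param solvent coefficient set name in [pigment_coefficients].
#' @return Data frame with columns `chla_mg_gfw`, `chlb_mg_gfw`,
#'   `car_mg_gfw`, `qc_flag`.
#' @examples
#' pigment_concentrations(a470 = 0.8, a645 = 0.2, a662 = 0.5,
#'                        extract_volume_ml = 10, fresh_weight_g = 0.1)
#' @export
pigment_concentrations <- function(a470, a645, a662,
                                   extract_volume_ml = 10,
                                   fresh_weight_g,
                                   solvent = "acetone_100") {
  check_number(a470, "a470", lower = 0)
  check_number(a645, "a645", lower = 0)
  check_number(a662, "a662", lower = 0)
  if (any(fresh_weight_g <= 0)) {
    stop_photo("fresh_weight_g must be > 0", class = "photoacclim_input_error")
  }
  if (any(extract_volume_ml <= 0)) {
    stop_photo("extract_volume_ml must be > 0",
               class = "photoacclim_input_error")
  }
  k <- pigment_coefficients[pigment_coefficients$solvent == solvent, ]
  if (nrow(k) != 1) {
    stop_photo("unknown solvent coefficient set: ", solvent,
               class = "photoacclim_config_error")
  }
  chla <- k$chla_a662 * a662 + k$chla_a645 * a645            # ug mL-1
  chlb <- k$chlb_a645 * a645 + k$chlb_a662 * a662
  car <- (k$car_a470 * a470 + k$car_chla * chla + k$car_chlb * chlb) /
    k$car_denom
  scale <- extract_volume_ml / fresh_weight_g / 1000          # -> mg g-1 FW
  qc <- chla < 0 | chlb < 0 | car < 0
  out <- data.frame(
    chla_mg_gfw = ifelse(chla < 0, NA_real_, chla * scale),
    chlb_mg_gfw = ifelse(chlb < 0, NA_real_, chlb * scale),
    car_mg_gfw  = ifelse(car < 0, NA_real_, car * scale),
    qc_flag = qc
  )
  out
}
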