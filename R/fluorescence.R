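#' Effective quantum yield of PSII (YII)
#'
#' Computes the Genty effective quantum yield of photosystem II from
#' steady-state fluorescence `F` and light-adapted maximal fluorescence
#' `Fm'`: \eqn{Y(II) = (Fm' - F) / Fm'}.
#'
#' Negative yields can arise from measurement noise when `F` slightly exceeds
#' `Fm'`. They are never silently clipped: the raw value is returned and the
#' `"flagged"` attribute marks the affected elements so downstream QC can
#' decide what to drop.
#'
#' @param f steady-state fluorescence under actinic light (instrument units,
#'   non-negative).
#' @param fm_prime maximal fluorescence under actinic light during a
#'   saturating pulse (instrument units, strictly positive).
#' @return Numeric vector of yields, with a logical `"flagged"` attribute
#'   marking elements outside \[0, 1\].
#' @examples
#' quantum_yield(300, 700)   # 0.5714...
#' @export
quantum_yield <- function(f, fm_prime) {
  check_number(f, "f", lower = 0, allow_na = TRUE)
  if (!is.numeric(fm_prime) || any(!is.na(fm_prime) & fm_prime <= 0)) {
    stop_photo("fm_prime must be > 0 (invalid fluorescence read)",
               class = "photoacclim_read_error")
  }
  yii <- (fm_prime - f) / fm_prime
  flagged <- !is.na(yii) & (yii < 0 | yii > 1)
  attr(yii, "flagged") <- flagged
  yii
}

#' Electron transport rate through PSII
#'
#' \eqn{ETR = Y(II) \times PAR \times AF \times 0.5} in umol electrons
#' m-2 s-1, where AF is the fraction of incident light absorbed by the leaf
#' and 0.5 assumes even photon partitioning between PSII and PSI.
#'
#' @param yii effective quantum yield in \[0, 1\].
#' @param par actinic irradiance (umol photons m-2 s-1, non-negative).
#' @param af absorption factor in (0, 1\]; defaults to the eelgrass
#'   literature mean 0.44.
#' @param psii_fraction photon fraction reaching PSII; 0.5 by convention.
#' @return ETR in umol electrons m-2 s-1.
#' @examples
#' etr(0.6, 100)           # 13.2 with the default AF of 0.44
#' @export
etr <- function(yii, par, af = photo_constants$af_default,
                psii_fraction = photo_constants$psii_fraction) {
  check_number(yii, "yii", lower = 0, upper = 1, allow_na = TRUE)
  check_number(par, "par", lower = 0, allow_na = TRUE)
  if (!is.numeric(af) || any(af <= 0 | af > 1)) {
    stop_photo("af must lie in (0, 1]", class = "photoacclim_config_error")
  }
  as.numeric(yii) * par * af * psii_fraction
}

#' Non-photochemical quenching (Stern-Volmer NPQ)
#'
#' \eqn{NPQ = (Fm - Fm') / Fm'} from the dark-adapted maximal fluorescence
#' `Fm` and the light-adapted `Fm'`. Negative values (noise: `Fm' > Fm`) are
#' flagged, not clipped.
#'
#' @param fm_dark dark-adapted maximal fluorescence (> 0).
#' @param fm_prime light-adapted maximal fluorescence (> 0).
#' @return NPQ with a logical `"flagged"` attribute marking negatives.
#' @export
npq <- function(fm_dark, fm_prime) {
  if (!is.numeric(fm_prime) || any(!is.na(fm_prime) & fm_prime <= 0)) {
    stop_photo("fm_prime must be > 0 (invalid fluorescence read)",
               class = "photoacclim_read_error")
  }
  check_number(fm_dark, "fm_dark", lower = 0, allow_na = TRUE)
  out <- (fm_dark - fm_prime) / fm_prime
  flagged <- !is.na(out) & out < 0
  if (any(flagged)) {
    warning("negative NPQ flagged (Fm' > Fm, likely measurement noise)")
  }
  attr(out, "flagged") <- flagged
  out
}

#' Estimate Fo' when not measured (Oxborough-Baker)
#'
#' \eqn{Fo' = Fo / (Fv/Fm + Fo/Fm')}. Used by [qp()] when the instrument did
#' not record minimal fluorescence under actinic light.
#'
#' @param fo_dark,fm_dark dark-adapted minimal and maximal fluorescence.
#' @param fm_prime light-adapted maximal fluorescence.
#' @return Estimated Fo'.
#' @export
estimate_fo_prime <- function(fo_dark, fm_dark, fm_prime) {
  check_number(fo_dark, "fo_dark", lower = 0, allow_na = TRUE)
  if (any(!is.na(fm_dark) & fm_dark <= 0) ||
      any(!is.na(fm_prime) & fm_prime <= 0)) {
    stop_photo("fm_dark and fm_prime must be > 0",
               class = "photoacclim_read_error")
  }
  fv_fm <- (fm_dark - fo_dark) / fm_dark
  fo_dark / (fv_fm + fo_dark / fm_prime)
}

#' Photochemical quenching coefficient (qP)
#'
#' Puddle-model coefficient \eqn{qP = (Fm' - F) / (Fm' - Fo')}. When `fo_prime`
#' is missing it is estimated from dark-adapted values via
#' [estimate_fo_prime()] and the result carries `"fo_prime_estimated" = TRUE`;
#' when dark values are also missing the result is `NA`, never guessed.
#'
#' @param f steady-state fluorescence.
#' @param fm_prime light-adapted maximal fluorescence.
#' @param fo_prime minimal fluorescence under actinic light, or `NA`.
#' @param fo_dark,fm_dark dark-adapted values used for the Fo' estimate.
#' @return qP in \[0, 1\] with attributes `"fo_prime_estimated"`.
#' @examples
#' qp(500, 700, 300)   # 0.5
#' @export
qp <- function(f, fm_prime, fo_prime = NA_real_,
               fo_dark = NA_real_, fm_dark = NA_real_) {
  if (!is.numeric(fm_prime) || any(!is.na(fm_prime) & fm_prime <= 0)) {
    stop_photo("fm_prime must be > 0 (invalid fluorescence read)",
               class = "photoacclim_read_error")
  }
  estimated <- FALSE
  if (anyNA(fo_prime)) {
    if (!anyNA(fo_dark) && !anyNA(fm_dark)) {
      fo_prime <- estimate_fo_prime(fo_dark, fm_dark, fm_prime)
      estimated <- TRUE
    } else {
      out <- rep(NA_real_, length(f))
      attr(out, "fo_prime_estimated") <- FALSE
      return(out)
    }
  }
  if (any(fm_prime <= fo_prime)) {
    stop_photo("degenerate read: Fm' must exceed Fo'",
               class = "photoacclim_read_error")
  }
  out <- (fm_prime - f) / (fm_prime - fo_prime)
  attr(out, "fo_prime_estimated") <- estimated
  out
}
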