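#' Convert spectral absorbance to absorptance
#'
#' \eqn{A(\lambda) = 1 - 10^{-D(\lambda)}}: the fraction of incident light
#' absorbed at each wavelength, from integrating-sphere absorbance `D`.
#' Negative absorbances (imperfect blank correction) are flagged and treated
#' as zero.
#'
#' @param d spectral absorbance (dimensionless, decadic).
#' @return Absorptance in \[0, 1), with attribute `"n_negative"` counting
#'   flagged inputs.
#' @examples
#' absorbance_to_absorptance(1)   # 0.9
#' @export
absorbance_to_absorptance <- function(d) {
  if (!is.numeric(d)) {
    stop_photo("absorbance must be numeric", class = "photoacclim_input_error")
  }
  n_neg <- sum(d < 0, na.rm = TRUE)
  if (n_neg > 0) {
    warning(n_neg, " negative absorbance value(s) treated as 0")
    d <- pmax(d, 0)
  }
  out <- 1 - 10^(-d)
  attr(out, "n_negative") <- n_neg
  out
}

#' Photosynthetic absorptance by near-infrared subtraction
#'
#' Subtracts the absorptance at the 750 nm reference (assumed entirely
#' non-photosynthetic) from the whole spectrum:
#' \eqn{A_P(\lambda) = A(\lambda) - A_{750}}, clipped at zero. The number of
#' clipped points is recorded so the (physically motivated) clipping stays
#' auditable.
#'
#' @param a absorptance spectrum.
#' @param a750 absorptance at the near-infrared reference wavelength.
#' @return Non-negative photosynthetic absorptance with attribute
#'   `"n_clipped"`.
#' @export
photosynthetic_absorptance <- function(a, a750) {
  check_number(a, "a", lower = 0, upper = 1)
  check_number(a750, "a750", lower = 0, upper = 1)
  ap <- a - a750
  n_clip <- sum(ap < 0)
  ap <- pmax(ap, 0)
  attr(ap, "n_clipped") <- n_clip
  ap
}

# linear interpolation of a spectrum onto a 1-nm grid over a band
interp_band <- function(wavelength, x, band) {
  if (min(wavelength) > band[1] || max(wavelength) < band[2]) {
    stop_photo("spectrum does not cover the ", band[1], "-", band[2],
               " nm band", class = "photoacclim_coverage_error")
  }
  grid <- seq(band[1], band[2], by = 1)
  stats::approx(wavelength, x, xout = grid, ties = mean)$y
}

#' Spectral mean over the photosynthetically active band
#'
#' Unweighted mean of a spectral quantity over 400-700 nm, evaluated on a
#' uniform 1-nm grid obtained by linear interpolation (the default), or by
#' trapezoidal integration over the native grid (`method = "trapezoid"`; on
#' smooth spectra the two differ by well under 0.5%).
#'
#' @param wavelength wavelengths in nm, strictly ascending.
#' @param x spectral values (e.g. absorptance).
#' @param band two-element numeric band in nm; default `c(400, 700)`.
#' @param method `"grid1nm"` or `"trapezoid"`.
#' @return The band mean (dimensionless for absorptance).
#' @export
af_spectral_mean <- function(wavelength, x,
                             band = photo_constants$par_band_nm,
                             method = c("grid1nm", "trapezoid")) {
  method <- match.arg(method)
  if (is.unsorted(wavelength, strictly = TRUE)) {
    stop_photo("wavelength must be strictly increasing",
               class = "photoacclim_input_error")
  }
  if (method == "grid1nm") {
    mean(interp_band(wavelength, x, band))
  } else {
    if (min(wavelength) > band[1] || max(wavelength) < band[2]) {
      stop_photo("spectrum does not cover the ", band[1], "-", band[2],
                 " nm band", class = "photoacclim_coverage_error")
    }
    keep <- wavelength >= band[1] & wavelength <= band[2]
    wl <- wavelength[keep]; xx <- x[keep]
    sum(diff(wl) * (head(xx, -1) + xx[-1]) / 2) / (max(wl) - min(wl))
  }
}

#' Leaf absorption factors from a spectral absorbance scan
#'
#' Full chain for one leaf: absorbance to absorptance, near-infrared
#' correction at 750 nm (read at the grid point nearest 750), and band means
#' over 400-700 nm giving the total absorption factor `af_total` (all leaf
#' components) and the photosynthetic absorption factor `af_photo`
#' (non-photosynthetic baseline removed). `af_photo <= af_total` always.
#'
#' @param wavelength wavelengths in nm covering at least 400-750.
#' @param absorbance decadic absorbance per wavelength.
#' @return Object of class `leaf_absorptance`: list with `wavelength`,
#'   `absorptance`, `ap`, `a750`, `af_total`, `af_photo`, `n_clipped`,
#'   `n_negative`.
#' @export
leaf_absorptance <- function(wavelength, absorbance) {
  if (length(wavelength) != length(absorbance)) {
    stop_photo("wavelength and absorbance lengths differ",
               class = "photoacclim_input_error")
  }
  ord <- order(wavelength)
  wavelength <- wavelength[ord]; absorbance <- absorbance[ord]
  if (max(wavelength) < photo_constants$nir_reference_nm) {
    stop_photo("spectrum lacks near-infrared coverage (needs 750 nm)",
               class = "photoacclim_coverage_error")
  }
  a <- absorbance_to_absorptance(absorbance)
  a750 <- a[which.min(abs(wavelength - photo_constants$nir_reference_nm))]
  ap <- photosynthetic_absorptance(as.numeric(a), a750)
  structure(list(
    wavelength = wavelength,
    absorptance = as.numeric(a),
    ap = as.numeric(ap),
    a750 = a750,
    af_total = af_spectral_mean(wavelength, as.numeric(a)),
    af_photo = af_spectral_mean(wavelength, as.numeric(ap)),
    n_clipped = attr(ap, "n_clipped"),
    n_negative = attr(a, "n_negative")
  ), class = "leaf_absorptance")
}

#' @export
print.leaf_absorptance <- function(x, ...) {
  cat("Leaf absorptance:",
      sprintf("AF_total = %.3f, AF_photo = %.3f (A750 = %.3f)\n",
              x$af_total, x$af_photo, x$a750))
  if (x$n_clipped > 0) cat("  ", x$n_clipped, "points clipped at 0\n")
  invisible(x)
}

#' Re-correct an ETR fit with a measured absorption factor
#'
#' Replaces the absorption factor used when the ETR curve was built (e.g. the
#' default 0.44) with a measured one (`af_total` or `af_photo`). Because ETR
#' is exactly linear in AF, two equivalent paths exist: rescale every ETR
#' value by `af_new / af_old` and refit (default, so noisy data are treated
#' identically to the original fits), or rescale the fitted `Ps`, `alpha`
#' and `ETRmax` directly and keep `Ek` (which is AF-invariant).
#'
#' @param fit a `platt_fit`.
#' @param af_new new absorption factor in (0, 1\].
#' @param af_old old absorption factor; taken from the fit's curve if absent.
#' @param af_kind label recorded on the corrected curve.
#' @param method `"refit"` (default) or `"rescale"`.
#' @return A corrected `platt_fit`.
#' @export
correct_etr_fit <- function(fit, af_new, af_old = fit$curve$af_used,
                            af_kind = c("af_photo", "af_total", "default_044"),
                            method = c("refit", "rescale")) {
  stopifnot(inherits(fit, "platt_fit"))
  method <- match.arg(method)
  af_kind <- match.arg(af_kind)
  if (!is.numeric(af_new) || af_new <= 0 || af_new > 1 ||
      !is.numeric(af_old) || af_old <= 0 || af_old > 1) {
    stop_photo("absorption factors must lie in (0, 1]",
               class = "photoacclim_config_error")
  }
  ratio <- af_new / af_old
  if (!is.finite(ratio)) {
    stop_photo("non-finite AF ratio", class = "photoacclim_config_error")
  }
  curve <- fit$curve
  curve$etr <- curve$etr * ratio
  curve$af_used <- af_new
  curve$af_kind <- af_kind
  if (method == "refit") {
    out <- fit_platt(curve, qc = FALSE)
    out$rejected <- fit$rejected
    out$reject_reason <- fit$reject_reason
    out
  } else {
    # the Platt curve is homogeneous of degree one in (Ps, alpha, beta)
    theta <- fit$coefficients * ratio
    res <- new_platt_fit(curve, theta,
                         sse = fit$sse * ratio^2,
                         converged = fit$converged,
                         rejected = fit$rejected,
                         reason = fit$reject_reason)
    res
  }
}
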