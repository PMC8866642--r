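# photoacclim

Analysis pipeline for **photoacclimation experiments on seagrass**
(eelgrass, *Zostera marina*): shoots acclimated to a gradient of growth
irradiances are probed by PAM fluorometry, pigment extraction, leaf
spectroscopy and oxygen incubations, and the package turns those raw
measurements into photosynthetic parameters, absorption-corrected electron
transport rates, metabolic rates, hierarchical irradiance-response curves
and ecological light thresholds.

Intended users are plant ecophysiologists and seagrass ecologists who have
tabular lab exports (RLC step tables, extract absorbances, spectral scans,
O2 time series) and want a tested, scriptable path from raw readings to
acclimation curves and light requirements.

## What it computes

* **Fluorescence**: effective quantum yield Y(II) = (Fm′ − F)/Fm′,
  ETR = Y(II) × PAR × AF × 0.5, plus qP and Stern–Volmer NPQ.
* **PI-curve fitting** (`fit_platt()`): the double-exponential model with
  photoinhibition, P(E) = Ps (1 − e^(−αE/Ps)) e^(−βE/Ps), via bounded
  (Port) least squares; derived ETRmax = Ps [α/(α+β)] [β/(α+β)]^(β/α) and
  Ek = ETRmax/α; automatic rejection of curves that never saturate.
* **Pigments**: chlorophyll a/b and total carotenoids from 470/645/662 nm
  extract absorbances (100 % acetone coefficients), per g fresh weight.
* **Absorptance**: A(λ) = 1 − 10^(−D(λ)), near-infrared correction at
  750 nm, band means AF_total and AF_photo over 400–700 nm, and exact
  re-correction of ETR fits when replacing the default AF = 0.44.
* **Metabolism**: NPP, GPP and respiration from light/dark O2 slopes,
  standardized to one-sided leaf surfaces.
* **Response models** (`fit_hgam()`): hierarchical penalized-spline
  irradiance-response curves (k = 7 basis functions, date- or
  method-specific smooths, container/shoot random intercepts, mgcv
  backend) with pointwise 95 % bands, non-overlap detection and Welch
  threshold tests.
* **Light thresholds** (`estimate_mqr()`): the minimum quantum requirement
  — the irradiance at which fitted NPP crosses zero, anchored at the mean
  dark respiration — and daily-dose conversions
  (PAR × 3600 × photoperiod × 10⁻⁶ mol m⁻² d⁻¹).
* **Synthetic experiments** (`simulate_experiment()`): the full 7-treatment
  × 3-container × 3-shoot design with known ground truth, including a
  pigment package effect, for end-to-end validation.

## Worked example

```r
library(photoacclim)

# a complete seeded experiment with known truth, then the whole pipeline
ex <- simulate_experiment(sim_config(seed = 42))
pl <- run_pipeline(ex)
pl
#> Photoacclimation pipeline results
#>   RLC fits: 126 (0 rejected by QC)
#>   mean respiration: -0.366 umol O2 cm-2 h-1 (n = 63)
#>   MQR: 12.04 umol photons m-2 s-1 (0.61 mol m-2 d-1)
```

126 rapid light curves (63 shoots × 2 measurement days) were fitted and
none rejected by the saturation QC; the mean signed respiration across the
63 incubated shoots is −0.366 µmol O2 cm⁻² h⁻¹, and the fitted NPP curve
crosses zero at 12.04 µmol photons m⁻² s⁻¹ (the generator's true
compensation irradiance is 13.7). One shoot's fit:

```r
d <- subset(ex$rlc_steps, shoot_id == "T074_C1_S1" & day == 5)
fit <- fit_platt(build_etr_curve(
  rlc_trace(d$actinic_par, d$f, d$fm_prime, treatment_par = 74, day = 5)))
fit
#> Platt photosynthesis-irradiance fit
#>   Ps = 26.82, alpha = 0.1733, beta = 0
#>   ETRmax = 26.82 umol electrons m-2 s-1, Ek = 154.8 umol photons m-2 s-1
#>   SSE = 16.56, converged: TRUE
```

This shoot, acclimated to 74 µmol photons m⁻² s⁻¹, shows high
photosynthetic efficiency (alpha 0.173), a modest capacity (ETRmax 26.8)
and light saturation setting in near 155 µmol photons m⁻² s⁻¹; beta = 0
means no detectable photoinhibition. Converting instantaneous thresholds
to daily doses under the 14-h photoperiod:

```r
round(convert_par_to_daily(c(13.7, 74, 200)), 2)
#> [1]  0.69  3.73 10.08
```

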