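---
title: "Models and methods behind photoacclim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind photoacclim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photoacclim)
```

# The problem

Seagrasses such as eelgrass (*Zostera marina*) persist across steep
underwater light gradients by photoacclimation: over days to weeks they
re-tune photosynthetic efficiency, capacity, pigment complement, and leaf
optics. Quantifying that adjustment requires stitching together four very
different measurements made on the same shoots:

* PAM fluorometry **rapid light curves** (RLCs) giving electron transport
  rates (ETR) as a function of actinic irradiance;
* **pigment extracts** quantified spectrophotometrically;
* **leaf spectral absorbance**, converted to the fraction of incident
  light actually absorbed;
* sealed-bottle **oxygen incubations** giving net/gross primary production
  and respiration.

photoacclim implements each stage as a small set of composable functions,
joins them with hierarchical irradiance-response models, and ships a seeded
synthetic-experiment generator so the entire pipeline can be validated
against known ground truth.

# Fluorescence and electron transport

The effective quantum yield of PSII under actinic light is the Genty ratio
$Y(II) = (F_m' - F)/F_m'$, and electron transport follows

$$\mathrm{ETR} = Y(II) \times \mathrm{PAR} \times AF \times 0.5
\quad [\mu\mathrm{mol\ electrons\ m^{-2}\ s^{-1}}],$$

with $AF$ the leaf absorption factor and 0.5 the assumed even split of
photons between the photosystems. The default $AF = 0.44$ is the literature
mean for eelgrass leaves; it is a comparability convention, not a measured
value, which is why the absorptance module can replace it *a posteriori*.
Quenching coefficients use the standard conventions of the PAM literature —
Stern–Volmer $NPQ = (F_m - F_m')/F_m'$ and puddle-model
$qP = (F_m' - F)/(F_m' - F_o')$ — because those are the quantities diving
PAM instruments report; neither formula has a competing definition in this
context. When $F_o'$ was not recorded it is estimated by the
Oxborough–Baker relation $F_o' = F_o/(F_v/F_m + F_o/F_m')$ and flagged;
when dark-adapted values are also missing, $qP$ is reported missing rather
than guessed. Negative yields or quenching values (possible with noisy
reads) are flagged, never silently clipped, so downstream QC can decide.

# The photosynthesis–irradiance model

ETR-vs-irradiance curves are fitted with the double-exponential saturation
model with photoinhibition,

$$P(E) = P_s\,\bigl(1 - e^{-\alpha E / P_s}\bigr)\,e^{-\beta E / P_s},$$

whose closed-form derived quantities are
$\mathrm{ETR}_{max} = P_s \frac{\alpha}{\alpha+\beta}
\bigl(\frac{\beta}{\alpha+\beta}\bigr)^{\beta/\alpha}$ (continuously
$P_s$ at $\beta = 0$) and $E_k = \mathrm{ETR}_{max}/\alpha$, the onset of
light saturation.

Fitting choices:

* **Optimizer.** Bounded least squares via `nls(algorithm = "port")`,
  polished (and backed up) by `optim(method = "L-BFGS-B")`; the better SSE
  wins. Bounds: $P_s \in (0, 10\max y]$, $\alpha \in (0, 10\,s_{max}]$
  with $s_{max}$ the largest observed secant slope, $\beta \ge 0$.
* **Starts.** $\alpha_0$ is the origin-constrained OLS slope of the three
  lowest-irradiance points, $P_{s,0} = \max y$, and two starts
  $\beta_0 \in \{0,\ 0.01\,\alpha_0\}$. Fits landing on the lower bound
  report $\beta = 0$ exactly (no photoinhibition) — most healthy curves
  plateau without declining.
* **Weighting.** Unweighted SSE by default; relative weighting is a config
  option.
* **QC.** An RLC that never saturates even at the top actinic step reflects
  a technical problem. Because "no saturation" needs a quantitative rule,
  two sub-rules are applied and logged separately: fitted $E_k$ above the
  highest actinic irradiance, or a last-two-step secant slope above 50 % of
  the fitted $\alpha$. Rejection is recorded as data, not raised as an
  error.
* RLC steps last only seconds, so these are non-steady-state curves by
  construction; no steady-state correction is attempted.

The model is homogeneous of degree one in $(P_s, \alpha, \beta)$: scaling
all ETR values by $c$ scales $P_s$, $\alpha$, $\beta$ and
$\mathrm{ETR}_{max}$ by $c$ and leaves $E_k$ unchanged. This covariance is
what makes *a posteriori* absorption-factor correction exact on noiseless
data, and it is tested to $10^{-6}$ relative.

# Leaf absorptance

Integrating-sphere decadic absorbance $D(\lambda)$ becomes absorptance
$A(\lambda) = 1 - 10^{-D(\lambda)}$. The near-infrared value at 750 nm is
taken as entirely non-photosynthetic and subtracted,
$A_P(\lambda) = A(\lambda) - A_{750}$, clipped at zero (with a logged
count) so the photosynthetic absorption factor stays physical. Band means
over 400–700 nm give `af_total` and `af_photo`, and
`af_photo <= af_total < 1` always.

Numerical choices: the band mean is an unweighted average on a uniform
1-nm grid obtained by linear interpolation (a trapezoid alternative is
provided and agrees to well under 0.5 % on smooth spectra); $A_{750}$ is
read at the grid point nearest 750 nm rather than from a fitted NIR
plateau, matching how the reference wavelength is stated. ETR re-correction
defaults to rescale-then-refit so noisy curves are treated identically to
the original fits; by the covariance property the refit and the direct
parameter rescaling agree exactly on noiseless data.

# Pigments

Chlorophyll a, b and total carotenoids come from the trichromatic
equations for 100 % acetone (the extraction solvent):
chla $= 11.24\,A_{662} - 2.04\,A_{645}$,
chlb $= 20.13\,A_{645} - 4.19\,A_{662}$,
carotenoids $= (1000\,A_{470} - 1.90\,\mathrm{chla} -
63.14\,\mathrm{chlb})/214$ (µg mL⁻¹), then
$\times$ extract volume / fresh weight into mg g⁻¹ FW. The coefficient set
lives in a table keyed by solvent so another set can be swapped in. Path
length is the universal 1-cm cuvette; no turbidity (A750) correction is
applied by default. A negative intermediate concentration fails QC and is
reported missing, never truncated to zero.

# Metabolic rates

Each shoot's sealed-bottle incubation yields light- and dark-phase O2
slopes by OLS **with intercept** (the first reading is not a defined zero),
in µmol O2 L⁻¹ h⁻¹. Then

$$NPP = \frac{\alpha_{light}\,vol}{S_{photo}},\qquad
GPP = \frac{(\alpha_{light} - \alpha_{dark})\,vol}{S_{photo}},\qquad
R = \frac{\alpha_{dark}\,vol}{S_{total}},$$

with NPP/GPP standardized to one-sided photosynthetic (green) leaf surface
and respiration to one-sided total surface. Slopes keep their measured
sign, so R is normally negative; the identity
$GPP - NPP = -\alpha_{dark}\,vol/S_{photo}$ holds algebraically on every
record and is asserted in the tests. The magnitude of the mean signed
respiration across shoots anchors the NPP model at zero irradiance.

# Hierarchical irradiance-response models

Responses (alpha, ETRmax, Ek, pigment contents, absorption factors, NPP,
GPP) are modelled against growth irradiance with hierarchical generalized
additive models: a cubic regression spline in PAR with basis dimension at
most $k = 7$ (one basis function per design irradiance level, PAR treated
as continuous), optionally one smooth per group (measurement day, or
absorptance-estimation method) plus the group main effect, and Gaussian
random intercepts for containers and shoots.

`fit_hgam()` delegates the penalized fit to **mgcv** — `s(par, bs = "cr",
k = 7)`, `by =` factor smooths, and `bs = "re"` intercepts — rather than
re-implementing a spline engine. mgcv is the de-facto standard for exactly
this model class, is numerically battle-tested, and exposes everything the
pipeline needs (fixed or estimated smoothing parameters, penalized
covariance for intervals, per-term approximate tests). The properties that
matter are asserted in the test suite regardless of engine: straight lines
lie in the penalty null space and are reproduced exactly at *any* smoothing
parameter; as the smoothing parameter grows the fit converges to the OLS
line; with the penalty removed the seven-basis smooth interpolates the
seven level means.

Smoothing parameters are selected by GCV by default (REML is a config
option). Confidence bands are Gaussian pointwise intervals,
fit $\pm z\,\mathrm{se}$, from the penalized coefficient covariance, with
random effects excluded (population-level prediction); whether such bands
should be simultaneous is left open, and the band comparison tool
(`ci_overlap_regions()`) simply reports where two pointwise bands separate.
Model summaries label parametric-term statistics as $t$ and smooth-term
statistics as $F$, without conflating the two.

Threshold confirmation between two treatments uses a Welch two-sample
t-test by default (pooled-variance optional); Shapiro–Wilk and
Fligner–Killeen p-values are attached as assumption flags but never switch
the test automatically.

## The compensation-irradiance (MQR) estimate

The minimum quantum requirement is the irradiance at which fitted NPP
crosses zero. The NPP model includes the zero-irradiance anchor
$(\mathrm{PAR} = 0,\ NPP = -|\bar R|)$ as data. Because the anchor is a
population-level datum, it is replicated across the existing container
levels (total weight 1): a pull shared by all levels cannot be absorbed
into the shrunken random intercepts and therefore constrains the smooth
itself. (A single anchor row with its own pseudo-level would be soaked up
by its own intercept — in the noiseless limit entirely — leaving the
population curve unconstrained.) The smallest root is then found on
$[0, \mathrm{PAR}_{\hat{max}}]$ by bisection to an absolute tolerance of
0.01 µmol photons m⁻² s⁻¹; a curve with no sign change returns a flagged
no-root result. Instantaneous irradiances convert to daily doses as
$\mathrm{PAR} \times 3600 \times \mathrm{photoperiod} \times 10^{-6}$
mol m⁻² d⁻¹ with the 14-h experimental photoperiod.

# The synthetic experiment generator

The generator emulates the full design: 7 growth-irradiance treatments (6,
36, 74, 133, 355, 503, 860 µmol photons m⁻² s⁻¹), 3 containers per
treatment, 3 shoots per container, RLCs on days 5 and 25 over the 10-step
actinic staircase (38–1246 µmol photons m⁻² s⁻¹), and day-25 pigments,
spectra and incubations. Container and shoot effects are drawn once per
experiment and shared across data streams.

**Truth surfaces** interpolate the reported response anchors with
shape-preserving monotone cubics: ETRmax linear from 24.6 (PAR 6) to 62.7
(PAR 860); day-5 alpha peaked at 0.173 at the 74 level and depressed on
both sides, with the high-light levels raised by day 25 (the rapid-vs-
acclimated contrast); chla falling from 2.0 to 0.75 mg g⁻¹ FW (a 2.7-fold
low/high contrast); NPP anchored at $-0.35$ at zero irradiance, crossing
zero at the compensation irradiance 13.7, and plateauing near 1.0 above
the 74 level; respiration $-0.55$ and $-0.53$ in the 355 and 860
treatments and $-0.28$ elsewhere, whose balanced mean magnitude (0.354) is
consistent with the 0.35 anchor. One consistency choice deserves note: a
smooth curve crossing zero at 13.7 is necessarily still negative at PAR 6,
so the generator's truth cannot simultaneously reproduce a positive
observed NPP at the lowest treatment; the compensation irradiance, the
quantity the pipeline must recover, takes precedence.

**Noise models** (invented, all configurable): lognormal variability on
the Fm' baseline, Gaussian relative noise (default 5 %) on quantum yields,
Gaussian noise on O2 readings and extract absorbances, lognormal
multiplicative random effects on capacity (and, at half strength, on
efficiency — keeping simulated yields under the physiological ceiling of
0.83), additive random effects on metabolic rates.

**Package effect.** Leaf spectra are built from pigment-weighted Gaussian
absorption bands whose optical depth saturates in pigment content,
$D_p(\lambda) = D_{max} S(\lambda)\,(1 - e^{-s P(\lambda)})$ — the
self-shading of pigments stacked in chloroplasts — plus a flat
non-photosynthetic baseline, then compressed through
$A = 1 - 10^{-D}$. The pigment-side saturation is modelled explicitly
because the absorptance transform alone, at leaf-realistic optical depths,
cannot make absorption as insensitive to pigment content as acclimated
leaves actually are. Defaults (`package_depth = 0.42`,
`package_rate = 6`, baseline depth 0.2007, leaf-to-leaf sdlog 0.08) were
calibrated once so that simulated leaves average `af_total` ≈ 0.55 and
`af_photo` ≈ 0.18, a three-fold pigment spread moves `af_photo` by well
under 15 %, and the across-shoot chlorophyll–absorptance correlation is
weak — the package-effect signature.

**What the generator does not emulate:** tidal/diel light regimes,
carbohydrate reserve dynamics, shoot mortality, epiphyte fouling,
structured (non-uniform) data loss, or instrument drift. Passing the
recovery suite therefore demonstrates that the estimators are consistent
and well-calibrated under the design's noise structure — not that they are
robust to every pathology of field data.

# Reproducibility and problem sizes

Every stochastic routine takes an explicit integer seed; the experiment
generator derives per-stage sub-seeds deterministically (all below
$2^{31}$), so identical config + seed reproduces every table bit-for-bit.
The validation suite runs the full generator–analyzer loop on 50 seeded
experiments (63 shoots, 126 RLC traces each) for the recovery checks, 200
replicate RLC fits for the noise study, and 1000 replicates for the t-test
calibration — sizes chosen to make Monte-Carlo error a small fraction of
each tolerance while keeping the default test run fast on one core.

# Known limitations

* The Platt fit treats RLC steps as exchangeable observations; no
  autocorrelation along the staircase is modelled.
* `fit_hgam()` covers one smooth + grouped smooths + random intercepts
  with a Gaussian response — the structures this analysis uses — not the
  full GAM zoo (tensor smooths, other families).
* The MQR depends on extrapolating the NPP smooth below the lowest
  treatment (PAR 6) toward the anchor at 0; its uncertainty is inherited
  from that extrapolation and the anchor, and recovery bias of a few
  percent toward lower values is visible in the synthetic studies.
* Pigment equations assume clean 100 % acetone extracts; no turbidity or
  pheophytin correction.
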