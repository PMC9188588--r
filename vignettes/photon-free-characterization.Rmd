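---
title: "Photon-free camera characterization and sCMOS-aware localization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Photon-free camera characterization and sCMOS-aware localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(darkcal)
```

## The problem

CMOS and sCMOS sensors have per-pixel electronics: every pixel has its own
offset, noise and conversion gain. Quantitative image analysis — and
single-molecule localization microscopy (SMLM) in particular — must account
for these pixel-wise properties, or hot pixels and offset structure leak
into the results as local bias. Map-based correction algorithms and
sCMOS-specific localization fitters all need the same three inputs: an
offset map, a noise (variance) map and a photon-response map.

Acquiring those maps traditionally requires a controlled illumination
series. `darkcal` implements the photon-free alternative: the sensor's own
thermally generated electrons are used as the calibration signal. Thermal
electrons accumulate linearly in time and obey Poisson statistics exactly
like photoelectrons, so a series of *dark* frames at several exposure times
contains everything needed.

## The model

For pixel $k$ at exposure time $t$ (seconds), the camera model is

$$\mathrm{ADU}_k = \mathrm{clip}\!\left(\mathrm{round}\!\left(
  BL_k + g_k\,[\,\mathrm{Pois}(DC_k\,t) + \mathcal{N}(0, RN_k)\,]
\right),\, 0,\, 2^{b}-1\right)$$

with baseline $BL_k$ (ADU), gain $g_k$ (ADU/e⁻), dark current $DC_k$
(e⁻/s), Gaussian read noise $RN_k$ (e⁻, sd) and bit depth $b$. Because
dark-current electrons are Poisson, their variance per second equals
$DC_k$ itself; the simulator therefore has no independent thermal-noise
parameter, while the calibration estimates the thermal-noise slope
*separately* from the dark-current slope and uses the redundancy as a
self-consistency diagnostic.

Three per-pixel straight lines, each fitted by the closed-form two-parameter
least-squares solution (no iterative solver), deliver the characterization:

* mean vs. $t$: intercept $= BL_k$, slope $= g_k DC_k$ (ADU/s);
* variance vs. $t$: intercept $= g_k^2 RN_k^2$, slope $= g_k^2 DC_k$
  (ADU²/s);
* variance vs. mean: slope $= g_k$, the pixel gain. The intercept is left
  free because read noise adds a $t$-independent variance — forcing the
  line through the origin would bias the slope.

The calibration operates in the few-electron regime, so single-pixel gain
estimates are noisy; the global gain is the **median** of the per-pixel
gain map. From the fitted maps, `derive_maps()` (or
`predict(cal, exposure_time)`) materializes the exposure-time-dependent
maps for *any* $t$:

$$\mathrm{offset}_k(t) = BL_k + (g DC)_k\, t, \qquad
  \mathrm{var}_k(t) = \max\!\big(0,\ (g^2RN^2)_k + (g^2DC)_k\, t\big), \qquad
  \mathrm{pr}_k = \tilde g\, F_k$$

where $\tilde g$ is the median gain and $F_k$ the flatfield. A calibration
taken at one exposure time is *not* valid at another: the offset grows by
the mean dark current per exposure. This is exactly the error made by the
traditional fixed-exposure characterization, which `darkcal` also
implements (`traditional_light_calibration()`) as a comparison baseline.

## Design choices

* **Units.** All fitted maps are stored in the ADU domain; electron-domain
  views are computed on demand through the median gain. This avoids double
  conversions in a literature that mixes electron and count units.
  Exposure times are seconds internally; file manifests declare `ms`
  explicitly.
* **Negative intercepts.** Noise can push fitted read-noise² (rarely,
  baseline) below zero. These values are retained in the calibration
  object and flagged in the diagnostics, preserving unbiased downstream
  aggregates; the floor at zero is applied only when variance maps are
  materialized by `derive_maps()`.
* **Gain-fit exclusions.** Pixels whose mean spans less than 5 standard
  errors across the exposure series carry no slope information; their gain
  is `NA` and excluded from the median rather than polluting it.
* **Read noise is Gaussian in the simulator** but is folded into a Poisson
  model on the fitting side (below). Keeping the two sides distinct lets
  the tests measure the cost of that approximation instead of hiding it.
* **Quantization and clipping.** Frames are rounded to integers and
  clipped to the bit depth. Rounding adds a ~1/12 ADU² variance which the
  calibration absorbs into the read-noise intercept consistently; default
  baselines of ~100 ADU keep zero-clipping negligible, which is why real
  cameras offset their baseline in the first place.
* **Flatfield.** One bright, roughly uniform frame is optional. The
  offset-subtracted signal is divided by a heavily smoothed copy of itself
  (Gaussian, default $\sigma$ = 1/8 of the short image dimension;
  `Inf` = global mean), which absorbs slow illumination profiles while
  keeping per-pixel sensitivity. The kernel scale is our choice; it is a
  stand-in for dedicated flat-fielding algorithms and is exercised as such
  in the tests.

## The localization engine

`mle_fit()` implements per-pixel-variance-aware Poisson maximum-likelihood
localization with an integrated-Gaussian PSF (2D, or astigmatic 3D with
$\sigma_{x,y}(z) = \sigma_0\sqrt{1 + u^2 + Au^3 + Bu^4}$,
$u = (z \mp \gamma)/d$). ADU data are converted to photoelectrons with the
offset and photon-response maps, and the Gaussian (read + thermal) noise
variance $v_k = \mathrm{var}_k / \mathrm{pr}_k^2$ is folded into the
Poisson likelihood by the variance-shift device: effective data
$d_k = e_k + v_k$, effective model $m_k(\theta) = N E_k(\theta) + bg + v_k$,
maximizing $\sum_k d_k \ln m_k - m_k$. Dark current is thereby handled at
the exposure time the maps were derived for — its mean through
$\mathrm{offset}(t)$, its Poisson variance through $\mathrm{var}(t)$. The
optimizer is Levenberg–Marquardt on the Fisher-scoring normal equations
(analytic gradients, max 50 iterations, convergence at $10^{-4}$ px /
$10^{-2}$ photons; non-convergence is flagged, never thrown). Effective
data may be negative in noise tails; the $+v_k$ shift keeps it positive in
expectation, and the model is clamped at $10^{-6}$ only inside the
logarithm.

Coordinates: ROI pixels are unit squares in a 0-based frame with pixel
centers at half-integers; nanometre positions map through `pixel_size`
(default 98 nm). This convention is pinned by a mirror-symmetry regression
test.

`crlb()` provides the Cramér–Rao bound from the Fisher matrix
$I_{ij} = \sum_k \partial_i m_k \partial_j m_k / (m_k + v_k)$ — the
theoretically achievable localization precision for the same noise model.
With `corrected = FALSE`, `mle_fit()` replaces the per-pixel maps by their
field averages, reproducing the biased "camera treated as homogeneous"
fitting that sCMOS-specific correction removes.

The parametric astigmatic Gaussian stands in for experimentally derived
bead PSF models (deliberately out of scope); its defaults
($\sigma_0 = 127$ nm, $\gamma = 250$ nm, $d = 400$ nm) give crossing
widths at $z = 0$ and a usable range of roughly ±400 nm.

## Synthetic cameras: what they emulate, and what not

`make_synthetic_camera()` draws per-pixel maps with a smooth baseline near
100 ADU, log-normal dark current, a designated fraction of hot pixels
(≥ 10× the median dark current by construction), uniform read noise,
gain scattered around a global value and a flatfield within ~2% of 1 —
magnitudes matching characterized CMOS sensors. Two versioned fixtures are
exported: `standard_fixture_camera()` (scientific-grade-like: 64×64,
median dark current 25 e⁻/s, 1–2 e⁻ read noise, 1% hot pixels at 10–50×)
and `industry_fixture_camera()` (uncooled industry-grade-like: median
100 e⁻/s, hot pixels at 50–200×, 2–4 e⁻ read noise), the latter because
uncooled sensors are where exposure-time-dependent correction matters
most for localization.

The generator deliberately omits rolling-shutter timing, temperature
drift, pixel crosstalk, response nonlinearity and long-term parameter
drift. Passing tests therefore demonstrate the estimators' correctness
under the stated noise model, not robustness to those effects on real
hardware.

## Numerical scale of the validation experiments

The validation experiments are sized for a single CPU: 5,000 frames per
exposure time on the 64×64 fixture for map prediction and gain
comparison (real calibrations use 8,000–20,000 sets; errors scale as
$1/\sqrt{n}$, which is itself asserted by a test), 1,000 repeats per
emitter position for bias/RMSE experiments on an 8×8 grid around a hot
pixel, and 500–8,000 frames for estimator-scaling checks. Every
experiment is a pure function of (configuration, seed).

Two residual approximations are visible at these scales and worth
knowing about:

* the per-pixel *gain* scatter is not corrected by design (photon response
  uses the median gain times flatfield), leaving a ~1 nm-scale position
  bias on heterogeneous cameras — small compared to hot-pixel bias but
  present in RMSE/CRLB ratios;
* the Gaussian-as-Poisson treatment of read noise costs a few per cent in
  the noise-map prediction error, which the hold-out validation bounds.

## Known limitations

* The flatfield estimator assumes illumination varies slowly compared to
  the smoothing kernel; vignetting sharper than that leaks into the map.
* Saturated or zero-clipped pixels bias their moments; the calibration
  flags but does not censor them.
* Localization filtering rules used in experimental SMLM pipelines
  (precision and likelihood cutoffs) are not implemented; they belong to
  reconstruction workflows, not to camera characterization.
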