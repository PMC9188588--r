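# darkcal

Photon-free (s)CMOS camera characterization in R, plus an sCMOS-aware
single-molecule localization engine that shows why the resulting maps
matter.

## The problem

Every pixel of a CMOS/sCMOS sensor has its own offset, noise and gain.
Map-based correction algorithms and sCMOS-specific localization fitters
need per-pixel **offset**, **variance** and **photon-response** maps — and
because each pixel also has its own dark current, offset and variance are
functions of the exposure time, which fixed-exposure calibrations miss.

`darkcal` characterizes the camera **without any light**: thermally
generated electrons accumulate linearly in time and obey Poisson
statistics just like photoelectrons, so a series of dark frames at several
exposure times is a complete calibration signal. Per pixel *k*:

- mean vs. exposure time *t*:   intercept = baseline `BL_k` (ADU), slope =
  dark current `g_k·DC_k` (ADU/s);
- variance vs. *t*:   intercept = read noise² `g_k²·RN_k²` (ADU²), slope =
  thermal noise² `g_k²·DC_k` (ADU²/s);
- variance vs. mean:   slope = pixel gain `g_k` (ADU/e⁻); the global gain
  is the median over pixels.

From these, maps for **any** exposure time:

```
offset_k(t) = BL_k + (g·DC)_k · t
var_k(t)    = max(0, (g²RN²)_k + (g²DC)_k · t)
pr_k        = median_gain · flatfield_k
```

The package also contains a per-pixel synthetic camera model (the maps
above are its ground truth, so every estimator is validated by parameter
recovery), the traditional varying-light-level calibration as a
comparison baseline, and a localization engine: integrated-Gaussian and
astigmatic-3D PSF models, per-pixel-variance-aware Poisson MLE fitting
(Levenberg–Marquardt, compiled core), Cramér–Rao lower bounds, and seeded
bias/RMSE grid experiments around hot pixels.

## Worked example

```r
library(darkcal)

# a 64 x 64 synthetic camera with 1% hot pixels
gt <- make_synthetic_camera(c(64, 64), hot_pixel_fraction = 0.01, seed = 7)

# nested dark-frame series at five exposure times, then calibrate
series <- simulate_dark_series(gt, c(1, 5, 20, 100, 500) / 1000,
                               n_per_time = 2000, seed = 8,
                               schedule = "nested")
cal <- calibrate_camera(pixel_statistics(series))
summary(cal)
#> Photon-free camera calibration (64 x 64 px)
#>   exposure times : 1, 5, 20, 100, 500 ms (2000 frames each)
#>   baseline       : median 100.00 ADU
#>   dark current   : median 55.59 ADU/s (25.26 e-/s)
#>   read noise     : median 3.30 ADU rms (1.50 e-)
#>   median gain    : 2.200 ADU/e-
#> Diagnostics:
#>   flagged pixels : 0 negative baseline, 1 negative read noise^2, 0 missing gain
#>   median R^2     : mean~t 1.0000, var~t 0.9998, var~mean 0.9997
```

The camera's true medians were baseline 100.0 ADU, dark current
25.2 e⁻/s, read noise 1.50 e⁻ and gain 2.202 ADU/e⁻ — recovered to within
estimator noise. Maps for an exposure time never acquired:

```r
maps <- predict(cal, exposure_time = 0.5)   # 500 ms
maps
#> Derived camera maps at 500 ms exposure time
#>   offset : median 127.82 ADU   noise: median 8.56 ADU rms   photon response: median 2.200 ADU/e-
write_maps(maps, "maps_500ms")   # offset_500ms.tif, variance_500ms.tif,
                                 # photon_response.tif + JSON sidecar
```

The median offset grew from 100.0 to 127.8 ADU: that is the dark-current
contribution at 500 ms, the part a fixed-exposure calibration gets wrong.
Localizing emitters with and without these per-pixel maps:

```r
psf <- psf_astigmatic3d()              # 98 nm pixels, sigma0 = 127 nm
pre <- modality_preset("storm")        # 9,000 photons, 50 ms
rep <- bias_rmse_experiment(gt, psf, pre,
                            grid = cbind(30:33, 30:33), n_repeats = 1000,
                            seed = 1)
print(rep)
```

which reports, per emitter position and fitter, the localization bias,
RMSE and the sqrt-CRLB: with per-pixel maps the RMSE sits at the bound;
with field-averaged camera values emitters near hot pixels are biased by
tens of nanometres.

A thin CLI covers the same pipeline
(`inst/cli/darkcal simulate-darks | calibrate | derive-maps | validate`).

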