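# spectroct

Spectroscopic and polarization-sensitive OCT biomarkers for ocular melanin.

Melanin shields the outer retina from oxidative stress, and its loss with
age is implicated in age-related macular degeneration — but almost no
in-vivo measure of it exists. `spectroct` implements two biomarkers that
need nothing beyond a standard OCT volume, plus the polarization comparator
used to validate them:

* **SSCoV** — the slope of the spectral coefficient of variation. The raw
  interferogram is reconstructed through a bank of 20 narrow Gaussian
  windows in k-space (evenly spaced in wavelength over 803–888 nm, uniform
  width in k), giving per-wavelength depth profiles `I_λ(z)`. A chromophore
  with wavelength-dependent attenuation makes them diverge with depth;
  `CoV(z) = σ_λ(z) / Ī_λ(z)` condenses the divergence, and its axial slope
  (mm⁻¹, fitted in a 21-pixel sliding window or over a fixed choroidal ROI)
  is proportional to local chromophore concentration — with no assumed
  chromophore spectrum.
* **RC ratio** — the maximum linear-scale RPE intensity over the maximum
  linear-scale choroidal intensity in a normalized axial profile; being a
  ratio of peaks in one profile, it is robust to global intensity drift.
* **1 − DOPU** — depolarization from the degree of polarization uniformity,
  computed from kernel-averaged Stokes vectors with a noise-bias
  correction.

Around these sit the supporting chain (annular averaging about the optic
nerve head, radial reslicing, profile normalization and cross-correlation
alignment, cross-sectional compositing with intensity-threshold masking),
longitudinal group statistics (rank-sum comparisons, age-trend fits with
CIs, slope-difference tests, metric correlations), and a Beer-Lambert
speckle simulator that generates dilution-series phantoms and layered
retinas so the whole pipeline runs without real OCT data.

## Worked example

Simulate one dilution step of the ICG/Intralipid phantom series, reconstruct
it spectroscopically, and measure the two coupled biomarkers:

```r
library(spectroct)

conc <- recipe_concentrations(dilution_series())
conc[c(1, 7), c("icg_um", "intralipid_pct")]
#> # A tibble: 2 × 2
#>   icg_um intralipid_pct
#>    <dbl>          <dbl>
#> 1 1290.            16
#> 2   64.5            0.8

scene <- phantom_scene(icg_um = 1290, intralipid_pct = 16)
vol   <- simulate_fringe_volume(scene, lateral_size = c(32, 32), seed = 1)

cov <- scov(spectral_profiles(spectral_reconstruct(vol)))
sscov_roi(cov, roi_start_px = 33, roi_len_px = 50)
#> [1] 4.706913

tom <- reconstruct(vol)
dp  <- one_minus_dopu(dopu(stokes_from_channels(tom),
                           noise_variance = estimate_noise_variance(tom, c(4, 40))))
mean(lateral_mean(dp)$value[33:83])
#> [1] 0.683545
```

The ROI SSCoV of 4.7 mm⁻¹ says the spectral channels fan out at about 4.7
coefficient-of-variation units per millimetre of depth — the fingerprint of a
strong absorber whose µₐ varies across the band. The mean 1 − DOPU of 0.68
says the Intralipid scrambles most of the polarization. Rerunning across
the seven dilution steps, both numbers fall together with concentration;
`plot_dilution_response()` draws the ladder.

A synthetic two-group longitudinal cohort goes through the full pipeline in
one call:

```r
spec <- cohort_spec(eyes_per_group = 2, ages_months = c(5, 11, 17),
                    lateral_size = c(16, 16), pitch_xy = 60)
ch  <- generate_cohort(spec)
res <- run_pipeline(ch$volumes, ch$metadata,
                    params = pipeline_params(roi_len_px = 31, roi_offset_px = 3),
                    pitch_xy = spec$pitch_xy)
res$trends[, c("metric", "p_group", "slope_a", "slope_b", "p_slope_diff")]
```

which returns the per-metric group means, rank-sum p-values, per-group age
slopes with 95% CIs and the slope-difference tests as one tibble. Fitted
trends are `trend_fit` objects with `tidy()`, `glance()` and `autoplot()`
methods.

A thin CLI wraps the same functions (`exec/spectroct`): `simulate`,
`spectral`, `dopu`, `reduce`, `analyze`.

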