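---
title: "Spectroscopic and polarization OCT biomarkers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectroscopic and polarization OCT biomarkers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectroct)
```

# The problem

Melanin in the retinal pigment epithelium (RPE) and choroid protects the
photoreceptors from oxidative stress, and its age-related loss is implicated
in macular degeneration, yet few in-vivo measures of ocular melanin exist.
`spectroct` implements two biomarkers computable from standard OCT volumes —
no extra hardware — together with the polarization-based comparator used to
validate them:

* **SSCoV**, the axial slope of the spectral coefficient of variation: a
  spectroscopic measure of chromophore concentration;
* the **RC ratio**, the RPE-to-choroid peak intensity ratio: an
  intensity-drift-robust summary of outer-retinal pigmentation;
* **1 − DOPU**, depolarization from dual-channel polarization-sensitive OCT,
  a gold-standard melanin proxy.

Because no public OCT data accompany these methods, the package also ships a
physically motivated forward simulator (Beer-Lambert attenuation plus fully
developed speckle), so every processing stage is testable end to end.

# The SSCoV model

Reconstructing the interferogram through a bank of narrow Gaussian windows
in k-space yields per-window (per-wavelength) depth profiles
$I_\lambda(z)$. A chromophore with wavelength-dependent attenuation
$\mu_a(\lambda)$ makes these profiles diverge with depth: on linear scale,

$$ I_\lambda(z) \propto \exp(-2\,\mu_a(\lambda)\, z), $$

with the factor 2 for the roundtrip path. The spectral coefficient of
variation condenses the divergence into one number per depth,

$$ \mathrm{CoV}(z) = \frac{\sigma_\lambda(z)}{\bar I_\lambda(z)}, $$

the population standard deviation over the mean of the linear-scale window
intensities. Normalizing by the mean makes the quantity unitless and
insensitive to overall backscattered power. To first order in the optical
depth, $\mathrm{CoV}(z) \approx 2\,\sigma_\mu\, z$ where $\sigma_\mu$ is the
spread of $\mu_a$ across the windows — so the axial **slope** of the CoV
(the SSCoV, in mm⁻¹) is proportional to local chromophore concentration,
without assuming any particular chromophore spectrum. The package's tests
pin this limit against the closed-form Beer-Lambert oracle (5% tolerance
where the roundtrip optical depth is below 0.1) and pin the sliding-window
fit against a brute-force per-window least-squares oracle exactly.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| band | 803–888 | nm | source bandwidth the windows span |
| windows | 20 | — | spectral sampling density |
| resolution factor | 6 | — | windowed vs full-band axial resolution (FWHM/FWHM) |
| SSCoV sliding window | 21 | px (42 µm) | suppresses high-frequency fit noise |
| choroidal ROI | 11 | px (22 µm) | fixed-depth slope for longitudinal comparison |
| annulus | 370–460 | µm | ONH-centred ring where the retina is flattest |
| DOPU kernel | 4×4×4 | px | spatial support of the polarization-state average |
| intensity threshold | 0.2 | norm. units | masks noise-dominated metric pixels |

Window widths are uniform in k-space and centers are evenly spaced in
wavelength. The shared width is set by a FWHM-to-FWHM convention: the full
band, treated as a Gaussian whose FWHM spans the band in k, divided by the
resolution factor. Under this convention the default bank's adjacent-window
area overlap in wavelength space is 68–74%; the bank reports its computed
overlap (`design_window_bank()` prints it) rather than forcing a particular
value, since several width conventions circulate and they shift the overlap
by a few percent.

# DOPU and its noise-bias correction

Stokes components are built voxelwise from the co- and cross-polarized
complex fields ($s_0 = |E_{co}|^2+|E_{cr}|^2$, $s_1 = |E_{co}|^2-|E_{cr}|^2$,
$s_2 = 2\,\mathrm{Re}\,E_{co}E_{cr}^*$, $s_3 = 2\,\mathrm{Im}\,E_{co}E_{cr}^*$),
averaged over a uniform kernel (components first, then the ratio — the
other ordering, per-voxel normalization before averaging, also appears in
the literature), and condensed to
$\mathrm{DOPU} = \sqrt{\bar s_1^2+\bar s_2^2+\bar s_3^2}/\bar s_0$.

Additive detector noise biases this estimator: the squared means of
$s_{1,2,3}$ inherit the variance of their noise fluctuations, which inflates
DOPU exactly where there is no signal to support it (noise makes 1 − DOPU
trend upward in tissue, but makes raw DOPU spuriously nonzero in empty
regions). The correction subtracts the estimated noise variance
$(2v\bar s_{0,sig} + 2v^2)/N$ from each squared component mean (clamped at
zero) and $2v$ from the denominator, with the denominator bounded below at
half the raw $\bar s_0$. The bound is a deliberate numerical choice: an
unbounded $\bar s_0 - 2v$ crosses zero in noise-dominated voxels and turns
the estimator into a clipped 0/0 ratio that is biased *towards one* — the
opposite of the intended correction. With the bounded form, a uniform
polarization state buried in noise is restored to DOPU ≈ 1 at any
signal-to-noise ratio we tested, while pure-noise volumes fall well below
the uncorrected estimate. Edge voxels use shrink-at-edges averaging (the
valid kernel intersection), so profiles keep their full depth extent.

# The forward simulator

Each A-line draws a Poisson number of sub-resolution scatterers per layer
(default 0.3/µm), sums their cosine fringes over the k grid with continuous
random depths (fully developed speckle; single-A-line contrast ≈ 1), and
attenuates each scatterer by the cumulative roundtrip Beer-Lambert factor
of all overlying absorbers evaluated at λ(k). A layer's depolarization
fraction couples scatterer amplitudes into the cross channel with
independent random phase. Additive white Gaussian noise models the
detector floor. The k→z transform zero-pads to the next power of two at
least twice the sample count; with the default 489-sample 803–888 nm grid
this puts the axial pitch at 2.0 µm per pixel, so that the 42 µm sliding
window is 21 pixels and the 22 µm ROI is 11.

What the simulator does **not** emulate: Mie-resonant scattering spectra
and melanosome shape/orientation effects, ocular aberrations and motion,
vessel flow voids, retinal curvature (volumes are generated flat), and
polarization-dependent absorption. Passing tests therefore demonstrate the
correctness and calibration of the *processing chain* under a physically
sensible attenuation + depolarization model — not clinical performance on
real eyes.

## Phantom presets

The dilution-series presets reproduce the ICG/Intralipid mixing arithmetic
(5 mg/mL ICG stock, molar mass 774.96 g/mol for the sodium salt — the
constant the arithmetic needs but concentration tables do not print;
Intralipid 20% stock), giving 1290 µM…64.5 µM ICG and 16%…0.8% Intralipid
across the seven mixing ratios. Shipped absorption spectra are synthetic
shapes (Gaussian band, monotone ramp, flat) rather than digitized
literature curves; solvent dependence is expressed through the peak
position/magnitude parameters. The ICG-like default peaks near 805 nm at
0.01 µm⁻¹ for the 1290 µM reference — the order of magnitude implied by the
dye's NIR molar absorptivity (~10⁵ L mol⁻¹ cm⁻¹), reduced to allow for
aggregation at high concentration. Melanin-like absorption uses a smooth
monotone decline across the band (no public melanin µₐ table at this band
is bundled; only the spread σ_µ matters for SSCoV).

# Desk-scale study conditions

Simulated cohorts image a 32×32 A-line grid at 30 µm pitch, which puts
roughly 260 A-lines inside the 370–460 µm annulus. Real volumes put tens of
thousands there, so the per-volume SSCoV measurement is noisier in
simulation than in vivo. Two processing choices respond to this, both
following the same logic the original ROI selection used (fix the fit where
the signal is most stable):

* the cohort pipeline fits the choroidal SSCoV over 31 pixels (62 µm)
  starting 3 pixels below the choroidal intensity peak — sited by a
  calibration ladder of melanin scales (response gain 7.5 mm⁻¹ per unit
  scale, residual sd 0.88 mm⁻¹, versus 5.3/1.3 for a peak-anchored 21-pixel
  fit). The exported `sscov_roi()` keeps the 11-pixel default;
* phantom ladders fit over ~100 µm of the 200 µm simulated medium.

The synthetic cohort defaults encode a two-group longitudinal design: 4
eyes per group at 6 ages from 5 to 17 months (24 volumes per group),
choroidal melanin declining at 0.45 scale/yr in knockouts versus 0.05 in
controls, RPE melanin baseline 25% lower in knockouts, per-eye baseline
variability 5%. Statistics-layer calibrations (CI coverage, slope
recovery) use a fast tabular generator with residual sd 0.75 and the
reported per-year decline magnitudes (−0.69 and −2.56 mm⁻¹/yr) as the
generating slopes.

# Statistical conventions

* Group comparisons use the two-sided Wilcoxon rank-sum test; the exact
  permutation distribution whenever there are no ties and groups are small
  (the `stats::wilcox.test` default), normal approximation with continuity
  correction otherwise.
* Age trends are ordinary least squares of metric on age in years (slopes
  in units per year), each eye-timepoint treated as independent — no
  mixed-effects structure, matching the per-point fitting of the original
  longitudinal analysis. Fellow-eye correlation is therefore ignored; this
  is a documented simplification.
* Slope differences use a two-sided t with pooled standard errors and
  Welch-Satterthwaite degrees of freedom.
* Metric-metric association is the Pearson correlation, with the
  least-squares slope and 95% CI alongside.
* No multiple-testing correction is applied (p < 0.05 throughout), matching
  the source analysis; callers comparing many metrics should adjust.

# Numerical choices and degenerate inputs

* Population (divide-by-N) standard deviation in the CoV — a descriptive
  statistic over a fixed window set, not a sample estimate.
* SCoV is masked (`NA`), not zeroed, where the mean intensity is
  non-positive; sliding fits propagate the mask and mask half a window at
  profile edges, so downstream averages skip rather than dilute.
* Cross-correlation alignments use integer-pixel lags against the mean
  channel (spectral) or a designated reference (profiles); ties break
  toward zero lag.
* Annulus membership uses pixel-center distance on the half-open ring
  `[inner, outer)`.
* Radial reslicing uses bilinear interpolation at 0.5° increments.
* Peak localization takes the two most prominent local maxima separated by
  a valley at least 10% below the lower peak ("peaks not resolved"
  otherwise); the cohort pipeline smooths the profile with a 5-pixel boxcar
  first, since speckle survives desk-scale annular averaging.
* The profile normalization requires a strictly positive reference-band
  maximum after noise subtraction and errors otherwise.

# Known limitations

* The simulator's depolarization model (amplitude fraction with random
  phase) is a convenience, not melanosome physics; it spans the DOPU range
  monotonically, which is all the calibration claims.
* SSCoV is curved, not linear, at high optical depths; the phantom fits
  stay within a range where a linear estimate is fair, as the metric's own
  description requires.
* The RC ratio depends on peak localization; profiles whose RPE/choroid
  peaks merge (strong smoothing, thin choroid) fail loudly rather than
  silently returning a ratio of the wrong peaks.
* Absolute biomarker values in simulation are not calibrated to any
  animal's values; only directions, orderings, correlations and test
  calibration are claimed, and those are what the test suite asserts.
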