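#' ICG/Intralipid phantom recipes and dilution arithmetic
#'
#' The dilution-series phantom mixes an indocyanine green (ICG) stock with
#' Intralipid 20% and saline in integer part ratios. `phantom_recipe()` builds
#' one recipe row; `dilution_series()` returns the seven-step series
#' (1:4:0 through 1:4:95) used throughout the examples;
#' `recipe_concentrations()` converts part ratios to the resulting molar ICG
#' concentration and Intralipid volume fraction:
#' \deqn{c_{ICG} = \frac{\rho_{stock}}{M_{ICG}}\cdot\frac{p_{ICG}}{p_{tot}},\qquad
#'       f_{IL} = f_{stock}\cdot\frac{p_{IL}}{p_{tot}}}
#'
#' @param icg_parts,intralipid_parts,saline_parts integer mixing parts
#'   (all >= 0, `icg_parts + intralipid_parts > 0`).
#' @param icg_stock_mg_ml ICG stock mass concentration, mg/mL.
#' @param icg_molar_mass ICG molar mass, g/mol (sodium salt).
#' @param intralipid_stock_fraction stock Intralipid volume fraction.
#'
#' @return A tibble with columns `icg_parts`, `intralipid_parts`,
#'   `saline_parts`, plus the stock parameters.
#' @examples
#' recipe_concentrations(dilution_series())
#' @export
phantom_recipe <- function(icg_parts = 1, intralipid_parts = 4, saline_parts = 0,
                           icg_stock_mg_ml = 5, icg_molar_mass = 774.96,
                           intralipid_stock_fraction = 0.20) {
  if (any(c(icg_parts, intralipid_parts, saline_parts) < 0))
    abort("mixing parts must be >= 0")
  if (any(icg_parts + intralipid_parts <= 0))
    abort("zero total parts: icg_parts + intralipid_parts must be > 0")
  tibble(icg_parts = icg_parts, intralipid_parts = intralipid_parts,
         saline_parts = saline_parts, icg_stock_mg_ml = icg_stock_mg_ml,
         icg_molar_mass = icg_molar_mass,
         intralipid_stock_fraction = intralipid_stock_fraction)
}

#' @rdname phantom_recipe
#' @export
dilution_series <- function() {
  phantom_recipe(saline_parts = c(0, 1, 2, 3, 4, 5, 95))
}

#' @param recipe a tibble of recipes from [phantom_recipe()].
#' @rdname phantom_recipe
#' @export
recipe_concentrations <- function(recipe) {
  total <- recipe$icg_parts + recipe$intralipid_parts + recipe$saline_parts
  if (any(total <= 0)) abort("zero total parts")
  stock_um <- recipe$icg_stock_mg_ml / recipe$icg_molar_mass * 1e6 # g/L over g/mol -> mol/L; to uM
  dplyr::mutate(recipe,
    icg_um = stock_um * .data$icg_parts / total,
    intralipid_pct = 100 * .data$intralipid_stock_fraction *
      .data$intralipid_parts / total)
}

#' Synthetic absorption spectra over the 803--888 nm band
#'
#' Builds a 20-point absorption coefficient table on the spectral-window
#' center wavelengths. The shapes are synthetic stand-ins parameterized to
#' mimic qualitative chromophore behaviour in this band: `"gaussian"` (a dye
#' band peaking near `peak_nm`, e.g. ICG-like), `"ramp"` (a smooth monotone
#' decline with wavelength, melanin-like), and `"flat"`. The `solvent` label
#' is carried along so solvent-dependent variants (e.g. a shifted, weakened
#' peak in water versus albumin) can be expressed through `peak_nm` /
#' `peak_mu` rather than hard-coded literature data.
#'
#' @param shape spectral shape.
#' @param peak_mu peak absorption coefficient, 1/um, at the reference
#'   concentration (`concentration_scale = 1`).
#' @param peak_nm band center for `"gaussian"`, nm.
#' @param width_nm Gaussian width (sd), nm.
#' @param decline fractional drop across the band for `"ramp"`.
#' @param band wavelength band, nm.
#' @param n number of wavelength samples (the window-bank size).
#' @param solvent context label: `"albumin"`, `"water"` or `"lipid"`.
#'
#' @return A tibble with columns `wavelength_nm`, `mu_a` (1/um), `solvent`.
#' @export
absorption_spectrum <- function(shape = c("gaussian", "ramp", "flat"),
                                peak_mu = 3e-3, peak_nm = 805, width_nm = 35,
                                decline = 0.5, band = c(803, 888), n = 20,
                                solvent = c("albumin", "water", "lipid")) {
  shape <- match.arg(shape)
  solvent <- match.arg(solvent)
  wl <- seq(band[1], band[2], length.out = n)
  mu <- switch(shape,
    gaussian = peak_mu * exp(-(wl - peak_nm)^2 / (2 * width_nm^2)),
    ramp = peak_mu * (1 - decline * (wl - band[1]) / diff(band)),
    flat = rep(peak_mu, n))
  if (any(mu < 0)) abort("absorption coefficients must be >= 0")
  tibble(wavelength_nm = wl, mu_a = mu, solvent = solvent)
}

#' Closed-form Beer-Lambert spectral depth profiles
#'
#' Noise-free forward model of the spectral intensities in a homogeneous
#' absorbing medium: channel \eqn{\lambda} at depth \eqn{z} has intensity
#' \deqn{I_\lambda(z) = I_0 \exp(-2\,\mu_a(\lambda)\, s\, z)}
#' with the roundtrip factor 2 (OCT measures backscattered light) and a
#' dimensionless concentration scale \eqn{s}. All channels are normalized to
#' \eqn{I_0 = 1} at the surface.
#'
#' @param spectrum an [absorption_spectrum()] tibble.
#' @param concentration_scale dimensionless concentration multiplier (>= 0).
#' @param depth_max maximum depth, um.
#' @param pitch depth sampling pitch, um.
#'
#' @return A long tibble with columns `depth_um`, `wavelength_nm`,
#'   `intensity`.
#' @examples
#' sp <- absorption_spectrum("gaussian")
#' beer_lambert_profiles(sp, 1, depth_max = 200, pitch = 2)
#' @export
beer_lambert_profiles <- function(spectrum, concentration_scale = 1,
                                  depth_max = 200, pitch = 2) {
  if (concentration_scale < 0) abort("`concentration_scale` must be >= 0")
  if (depth_max <= 0 || pitch <= 0) abort("`depth_max` and `pitch` must be > 0")
  z <- seq(0, depth_max, by = pitch)
  tidyr::crossing(depth_um = z,
                  spectrum[, c("wavelength_nm", "mu_a")]) |>
    dplyr::mutate(intensity = exp(-2 * .data$mu_a * concentration_scale *
                                    .data$depth_um)) |>
    dplyr::select("depth_um", "wavelength_nm", "intensity")
}
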