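#' Scene description for the fringe simulator
#'
#' A scene is a stack of non-overlapping layers, each with a top depth and
#' thickness (um, optical depth), a backscattering reflectivity, an optional
#' per-wavelength absorption table (an [absorption_spectrum()] tibble, scaled
#' by `absorption_scale`), and a depolarization fraction in \[0, 1\] giving
#' the relative amplitude each scatterer couples into the cross-polarized
#' channel.
#'
#' @param layers a tibble with columns `name`, `top_um`, `thickness_um`,
#'   `reflectivity`, `depolarization`, and a list-column `absorption` of
#'   absorption-spectrum tibbles (or `NULL` entries), plus optionally
#'   `absorption_scale`.
#' @param noise_floor standard deviation of the additive Gaussian detector
#'   noise on the fringes.
#' @param scatterer_density mean sub-resolution scatterers per um of layer
#'   thickness per A-line.
#' @param refractive_index bulk tissue index used when converting optical to
#'   geometric depth for reporting; the simulator itself works in optical
#'   depth.
#'
#' @return An object of class `scene_config`.
#' @seealso [simulate_fringe_volume()], [phantom_scene()], [make_retina_scene()]
#' @export
scene_config <- function(layers, noise_floor = 0.05, scatterer_density = 0.3,
                         refractive_index = 1.38) {
  layers <- as_tibble(layers)
  need <- c("name", "top_um", "thickness_um", "reflectivity", "depolarization")
  if (!all(need %in% names(layers)))
    abort(paste("`layers` needs columns:", paste(need, collapse = ", ")))
  if (!"absorption" %in% names(layers))
    layers$absorption <- vector("list", nrow(layers))
  if (!"absorption_scale" %in% names(layers)) layers$absorption_scale <- 1
  layers <- layers[order(layers$top_um), ]
  if (any(layers$thickness_um <= 0)) abort("layer thickness must be > 0")
  if (nrow(layers) > 1) {
    bottoms <- layers$top_um + layers$thickness_um
    if (any(layers$top_um[-1] < bottoms[-nrow(layers)] - 1e-9))
      abort("layers must be non-overlapping")
  }
  if (any(layers$depolarization < 0 | layers$depolarization > 1))
    abort("depolarization fraction must lie in [0, 1]")
  if (any(layers$reflectivity < 0)) abort("reflectivity must be >= 0")
  for (a in layers$absorption)
    if (!is.null(a) && any(a$mu_a < 0)) abort("absorption coefficients must be >= 0")
  if (any(layers$absorption_scale < 0)) abort("negative concentration_scale")
  structure(list(layers = layers, noise_floor = noise_floor,
                 scatterer_density = scatterer_density,
                 refractive_index = refractive_index),
            class = "scene_config")
}

#' @export
print.scene_config <- function(x, ...) {
  cat(sprintf("<scene_config> %d layers, noise floor %.3g, %.2f scatterers/um\n",
              nrow(x$layers), x$noise_floor, x$scatterer_density))
  print(x$layers[, c("name", "top_um", "thickness_um", "reflectivity",
                     "depolarization")])
  invisible(x)
}

#' Read/write scene configurations as YAML
#'
#' @param scene a [scene_config()].
#' @param path YAML file path.
#' @return `read_scene_config` returns a [scene_config()];
#'   `write_scene_config` returns `path` invisibly.
#' @export
write_scene_config <- function(scene, path) {
  stopifnot(inherits(scene, "scene_config"))
  ll <- lapply(seq_len(nrow(scene$layers)), function(i) {
    l <- scene$layers[i, ]
    out <- list(name = l$name, top_um = l$top_um,
                thickness_um = l$thickness_um, reflectivity = l$reflectivity,
                depolarization = l$depolarization,
                absorption_scale = l$absorption_scale)
    a <- l$absorption[[1]]
    if (!is.null(a))
      out$absorption <- list(wavelength_nm = a$wavelength_nm, mu_a = a$mu_a)
    out
  })
  yaml::write_yaml(list(layers = ll, noise_floor = scene$noise_floor,
                        scatterer_density = scene$scatterer_density,
                        refractive_index = scene$refractive_index), path,
                   precision = 12)
  invisible(path)
}

#' @rdname write_scene_config
#' @export
read_scene_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  y <- yaml::read_yaml(path)
  layers <- dplyr::bind_rows(lapply(y$layers, function(l) {
    tibble(name = l$name, top_um = l$top_um, thickness_um = l$thickness_um,
           reflectivity = l$reflectivity, depolarization = l$depolarization,
           absorption_scale = l$absorption_scale %||% 1,
           absorption = list(
             if (!is.null(l[["absorption"]]))
               tibble(wavelength_nm = as.numeric(l[["absorption"]]$wavelength_nm),
                      mu_a = as.numeric(l[["absorption"]]$mu_a))))
  }))
  scene_config(layers, noise_floor = y$noise_floor %||% 0.05,
               scatterer_density = y$scatterer_density %||% 0.3,
               refractive_index = y$refractive_index %||% 1.38)
}

#' Simulate a speckled dual-polarization fringe volume
#'
#' Forward model: each A-line draws a Poisson number of sub-resolution
#' scatterers per layer (uniform depths within the layer), so the coherent sum
#' over random optical phases produces fully developed speckle. Per-scatterer
#' amplitudes are attenuated by the cumulative roundtrip Beer-Lambert factor
#' through all overlying absorbing media evaluated at \eqn{\lambda(k)}, making
#' the spectral channels diverge with depth exactly as a real chromophore
#' would. A layer with depolarization fraction \eqn{f} couples each
#' scatterer's amplitude times \eqn{f} into the cross-polarized channel with
#' an independent uniform phase; additive white Gaussian detector noise is
#' applied to both channels. Deterministic for a fixed `seed`.
#'
#' @param scene a [scene_config()].
#' @param band wavelength band (nm) spanned by the k grid.
#' @param n_k number of k samples (>= 256). The default 489 makes the
#'   reconstructed axial pitch 2.0 um (see [reconstruct()]), so a 42 um
#'   sliding window is 21 pixels.
#' @param lateral_size `(nx, ny)` A-line grid.
#' @param pitch_xy lateral pitch, um.
#' @param seed RNG seed (set for reproducibility; `NULL` leaves the RNG
#'   state alone).
#' @param channels `c("co", "cross")` for dual polarization or `"co"`.
#'
#' @return An [oct_volume()].
#' @export
simulate_fringe_volume <- function(scene, band = c(803, 888), n_k = 489,
                                   lateral_size = c(8, 8), pitch_xy = 40,
                                   seed = NULL, channels = c("co", "cross")) {
  stopifnot(inherits(scene, "scene_config"))
  if (n_k < 256) abort("`n_k` must be >= 256")
  if (!is.null(seed)) set.seed(seed)
  k <- seq(lambda_to_k(band[2]), lambda_to_k(band[1]), length.out = n_k)
  dk <- diff(k[1:2])
  z_max <- pi / (2 * dk) # deepest unambiguous depth after the k->z transform
  layers <- scene$layers
  bottoms <- layers$top_um + layers$thickness_um
  if (max(bottoms) > z_max)
    abort(sprintf(
      "scene deeper than the unambiguous depth range (%.0f > %.0f um) for n_k = %d",
      max(bottoms), z_max, n_k))
  lam <- k_to_lambda(k)
  # per-layer attenuation coefficient on the k grid (zero rows for clear media)
  mu <- vapply(seq_len(nrow(layers)), function(i) {
    a <- layers$absorption[[i]]
    if (is.null(a)) rep(0, n_k)
    else stats::approx(a$wavelength_nm, a$mu_a, xout = lam, rule = 2)$y *
      layers$absorption_scale[i]
  }, numeric(n_k))
  mu <- matrix(mu, nrow = n_k)
  tops <- layers$top_um
  nx <- lateral_size[1]; ny <- lateral_size[2]
  n_a <- nx * ny
  n_ch <- length(channels)
  scat_layers <- which(layers$reflectivity > 0)
  dens <- scene$scatterer_density
  # draw all scatterers of all A-lines at once (A-line major order)
  counts <- matrix(stats::rpois(length(scat_layers) * n_a,
                                dens * layers$thickness_um[scat_layers]),
                   nrow = length(scat_layers))
  layer_of <- rep(rep(scat_layers, n_a), times = as.vector(counts))
  n_s <- length(layer_of)
  zs <- tops[layer_of] + stats::runif(n_s) * layers$thickness_um[layer_of]
  # amplitude sqrt(refl / density): mean intensity per unit depth = refl
  amps <- sqrt(layers$reflectivity[layer_of] / dens)
  depf <- layers$depolarization[layer_of]
  # one-way path of each scatterer through each layer
  paths <- outer(zs, seq_len(nrow(layers)), function(z, l)
    pmin(pmax(z - tops[l], 0), layers$thickness_um[l]))
  start <- c(0L, cumsum(colSums(counts)))
  fr <- array(0, c(n_k, nx, ny, n_ch))
  fr[, , , 1] <- fringe_accumulate_volume(k, zs, amps, numeric(n_s), mu,
                                          paths, start)
  if (n_ch == 2) {
    ph <- stats::runif(n_s, 0, 2 * pi)
    fr[, , , 2] <- fringe_accumulate_volume(k, zs, amps * depf, ph, mu,
                                            paths, start)
  }
  if (scene$noise_floor > 0)
    fr <- fr + stats::rnorm(length(fr), sd = scene$noise_floor)
  v <- oct_volume(fr, k, channels = channels)
  v$meta <- list(pitch_xy = pitch_xy)
  v
}

#' Dilution-series phantom scene
#'
#' Builds the capillary-phantom scene for one dilution step: an empty air
#' gap, a bright specular glass interface, and a 200 um absorbing/scattering
#' medium whose absorption scales with the ICG concentration and whose
#' scattering and depolarization scale with the Intralipid fraction.
#'
#' @param icg_um ICG concentration, uM.
#' @param intralipid_pct Intralipid volume percentage.
#' @param spectrum absorption table at the reference concentration
#'   `reference_um`. The default is an ICG-like band peaking near 805 nm
#'   with a peak coefficient of 0.01 1/um at 1290 uM, the order implied by
#'   the dye's near-infrared molar absorptivity (~1e5 L/mol/cm, reduced for
#'   aggregation at high concentration).
#' @param reference_um concentration at which `spectrum` applies.
#' @param depth_um medium thickness, um.
#' @param interface_reflectivity reflectivity of the glass interface.
#' @param noise_floor detector noise level.
#' @param depol_k50 Intralipid percentage at which the depolarization
#'   fraction reaches 0.5 (saturating map `il / (il + depol_k50)`).
#'
#' @return A [scene_config()].
#' @export
phantom_scene <- function(icg_um, intralipid_pct,
                          spectrum = absorption_spectrum("gaussian",
                                                         peak_mu = 0.01),
                          reference_um = 1290, depth_um = 200,
                          interface_reflectivity = 4, noise_floor = 0.05,
                          depol_k50 = 4) {
  layers <- tibble(
    name = c("interface", "medium"),
    top_um = c(50, 54),
    thickness_um = c(4, depth_um),
    reflectivity = c(interface_reflectivity,
                     pmax(intralipid_pct, 0.05) / 16),
    depolarization = c(0, intralipid_pct / (intralipid_pct + depol_k50)),
    absorption = list(NULL, spectrum),
    absorption_scale = c(1, icg_um / reference_um))
  scene_config(layers, noise_floor = noise_floor)
}
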