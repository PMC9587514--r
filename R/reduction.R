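#' Annular region of interest around the optic nerve head
#'
#' The lateral ROI used to reduce volumes to depth profiles: all A-lines
#' whose pixel-center distance to the ONH center lies in the half-open ring
#' `[inner_um, outer_um)` (half-open so boundary pixels are never counted
#' twice by complementary rings). The defaults give the 90 um thick annulus
#' between 370 and 460 um where the laminar retinal structure is flattest.
#'
#' @param center ONH center `(x, y)` in pixel coordinates (may be
#'   fractional).
#' @param inner_um,outer_um ring radii in um, `0 < inner < outer`.
#' @return An object of class `annular_roi`.
#' @export
annular_roi <- function(center, inner_um = 370, outer_um = 460) {
  if (!(inner_um > 0 && inner_um < outer_um))
    abort("need 0 < inner_um < outer_um")
  if (length(center) != 2) abort("`center` must be (x, y)")
  structure(list(center = as.numeric(center), inner_um = inner_um,
                 outer_um = outer_um), class = "annular_roi")
}

annulus_mask <- function(nx, ny, roi, pitch_xy) {
  if (!is.finite(pitch_xy) || pitch_xy <= 0)
    abort("valid `pitch_xy` required for annulus membership")
  gx <- (seq_len(nx) - roi$center[1]) * pitch_xy
  gy <- (seq_len(ny) - roi$center[2]) * pitch_xy
  d <- sqrt(outer(gx^2, gy^2, `+`))
  as.vector(d >= roi$inner_um & d < roi$outer_um)
}

#' Reduce a volume to an axial profile by annular averaging
#'
#' Unweighted mean over all lateral positions inside the annulus, per depth
#' pixel; masked (`NA`) voxels are excluded from the mean rather than
#' diluted.
#'
#' @param x a `(z, x, y)` numeric array, an [oct_tomogram()] (co-channel
#'   intensity), a `spectral_tomogram` (per-window profiles), or a
#'   [dopu()] volume.
#' @param roi an [annular_roi()].
#' @param pitch_xy lateral pitch in um (taken from the object when it
#'   carries one).
#' @param pitch_z axial pitch in um for the `depth_um` column.
#' @param ... unused.
#' @return A tibble `depth_px`, `depth_um`, `value` (or the long spectral
#'   format for spectral tomograms).
#' @export
annular_average <- function(x, roi, ...) UseMethod("annular_average")

#' @rdname annular_average
#' @export
annular_average.array <- function(x, roi, pitch_xy, pitch_z = NA_real_, ...) {
  d <- dim(x)
  keep <- annulus_mask(d[2], d[3], roi, pitch_xy)
  if (!any(keep)) abort("empty annulus: no A-lines inside the ROI")
  m <- matrix(x, d[1], d[2] * d[3])
  tibble(depth_px = seq_len(d[1]),
         depth_um = (seq_len(d[1]) - 1) * pitch_z,
         value = rowMeans(m[, keep, drop = FALSE], na.rm = TRUE))
}

#' @rdname annular_average
#' @export
annular_average.oct_tomogram <- function(x, roi, pitch_xy = NULL, ...) {
  annular_average(intensity(x, "co"), roi,
                  pitch_xy = pitch_xy %||% x$pitch_xy, pitch_z = x$pitch_z)
}

#' @rdname annular_average
#' @export
annular_average.dopu_volume <- function(x, roi, pitch_xy = NULL, ...) {
  annular_average(x$dopu, roi, pitch_xy = pitch_xy %||% x$pitch_xy,
                  pitch_z = x$pitch_z)
}

#' @rdname annular_average
#' @export
annular_average.spectral_tomogram <- function(x, roi, pitch_xy = NULL, ...) {
  spectral_profiles(x, roi = roi, pitch_xy = pitch_xy %||% x$pitch_xy)
}

#' Reduce a volume to an axial profile by averaging all A-lines
#'
#' Plain lateral mean over every A-line -- the reduction used for
#' laterally homogeneous samples such as the dilution phantoms, where no
#' anatomical ROI is needed.
#'
#' @param x a `(z, x, y)` numeric array or a [dopu()] volume / tomogram.
#' @param pitch_z axial pitch in um for the `depth_um` column.
#' @return A tibble `depth_px`, `depth_um`, `value`.
#' @export
lateral_mean <- function(x, pitch_z = NA_real_) {
  if (inherits(x, "dopu_volume")) { pitch_z <- x$pitch_z; x <- x$dopu }
  if (inherits(x, "oct_tomogram")) { pitch_z <- x$pitch_z; x <- intensity(x) }
  d <- dim(x)
  tibble(depth_px = seq_len(d[1]),
         depth_um = (seq_len(d[1]) - 1) * pitch_z,
         value = rowMeans(matrix(x, d[1], prod(d[-1])), na.rm = TRUE))
}

#' Radial reslicing around the ONH
#'
#' Reslices a volume into planes through the ONH center at `dtheta_deg`
#' angular increments (720 slices at the 0.5 degree default), sampling each
#' plane by bilinear interpolation, and averages the slices into a single
#' (depth x radius) image showing the laminar structure as a function of
#' distance from the pivot.
#'
#' @param x a `(z, x, y)` numeric array.
#' @param center pivot `(x, y)` in pixel coordinates; must be inside the
#'   lateral field.
#' @param pitch_xy lateral pitch, um.
#' @param dtheta_deg angular increment, degrees.
#' @param r_max_um maximum radius sampled (default: to the nearest edge).
#' @param dr_um radial sampling step (default `pitch_xy`).
#' @return A matrix `(z, radius)` with attribute `radius_um`.
#' @export
radial_reslice <- function(x, center, pitch_xy, dtheta_deg = 0.5,
                           r_max_um = NULL, dr_um = NULL) {
  d <- dim(x)
  if (center[1] < 1 || center[1] > d[2] || center[2] < 1 || center[2] > d[3])
    abort("center outside field")
  dr_um <- dr_um %||% pitch_xy
  r_max_um <- r_max_um %||%
    (min(center[1] - 1, d[2] - center[1], center[2] - 1, d[3] - center[2]) *
       pitch_xy)
  radii <- seq(0, r_max_um, by = dr_um)
  theta <- seq(0, 360 - dtheta_deg, by = dtheta_deg) * pi / 180
  # accumulate bilinear weights of every (angle, radius) sample into a
  # sparse lateral weight matrix, then reslice all depths in one product
  w <- matrix(0, d[2] * d[3], length(radii))
  for (j in seq_along(radii)) {
    px <- center[1] + radii[j] / pitch_xy * cos(theta)
    py <- center[2] + radii[j] / pitch_xy * sin(theta)
    x0 <- floor(px); y0 <- floor(py)
    fx <- px - x0; fy <- py - y0
    for (corner in list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))) {
      cx <- x0 + corner[1]; cy <- y0 + corner[2]
      wt <- (if (corner[1] == 0) 1 - fx else fx) *
            (if (corner[2] == 0) 1 - fy else fy)
      ok <- cx >= 1 & cx <= d[2] & cy >= 1 & cy <= d[3] & wt > 0
      if (!any(ok)) next
      lin <- (cy[ok] - 1) * d[2] + cx[ok]
      acc <- tapply(wt[ok], lin, sum)
      w[as.integer(names(acc)), j] <- w[as.integer(names(acc)), j] + acc
    }
  }
  tot <- colSums(w)
  if (any(tot == 0)) abort("radius exceeds the lateral field everywhere")
  out <- (matrix(x, d[1], d[2] * d[3]) %*% w) / rep(tot, each = d[1])
  attr(out, "radius_um") <- radii
  out
}

#' Normalize an axial profile
#'
#' Subtracts the mean over a signal-free noise range (vitreous, or air for
#' phantoms) and divides by the maximum over a bright reference band
#' (NFL/GCL, or the air-glass interface), computed after the subtraction.
#' Idempotent, and it makes downstream peak ratios invariant to global
#' intensity rescaling of the raw volume.
#'
#' @param profile a tibble with `depth_um` and `value` columns.
#' @param noise_range,peak_range depth ranges `(min, max)` in um; must not
#'   overlap.
#' @return The normalized tibble, with a `normalization` attribute recording
#'   the noise mean and the peak value/location.
#' @export
normalize_profile <- function(profile, noise_range, peak_range) {
  if (noise_range[1] <= peak_range[2] && peak_range[1] <= noise_range[2])
    abort("noise and peak ranges must not overlap")
  z <- profile$depth_um
  ni <- which(z >= noise_range[1] & z <= noise_range[2])
  pi_ <- which(z >= peak_range[1] & z <= peak_range[2])
  if (!length(ni) || !length(pi_)) abort("ranges outside the profile")
  noise <- mean(profile$value[ni], na.rm = TRUE)
  shifted <- profile$value - noise
  pk <- max(shifted[pi_], na.rm = TRUE)
  if (!is.finite(pk) || pk <= 0) abort("non-positive peak after noise subtraction")
  out <- dplyr::mutate(profile, value = shifted / pk)
  attr(out, "normalization") <-
    list(noise_mean = noise, peak_value = pk,
         peak_depth_um = z[pi_[which.max(shifted[pi_])]])
  out
}

#' Normalize spectral profiles per channel
#'
#' Applies the [normalize_profile()] convention to each spectral channel of a
#' long profile tibble independently (each channel is divided by its own
#' reference-band maximum).
#'
#' @param profiles long tibble from [spectral_profiles()].
#' @param noise_range,peak_range depth ranges in um.
#' @return The normalized long tibble.
#' @export
normalize_spectral_profiles <- function(profiles, noise_range, peak_range) {
  profiles |>
    dplyr::group_by(.data$wavelength_nm) |>
    dplyr::group_modify(function(df, key) {
      p <- normalize_profile(
        dplyr::rename(df, value = "intensity"), noise_range, peak_range)
      dplyr::rename(p, intensity = "value")
    }) |>
    dplyr::ungroup() |>
    dplyr::relocate("wavelength_nm", .after = "depth_um")
}

#' Align axial profiles to a reference by cross-correlation
#'
#' Recovers the integer axial lag of each profile relative to a reference
#' (the shift to apply so features line up; ties broken toward zero). The
#' same offsets are reusable across metrics: depolarization profiles are
#' shifted by the offsets found on the intensity profiles.
#'
#' @param profiles list of profile tibbles (columns `depth_um`, `value`).
#' @param reference reference profile tibble.
#' @param range_um optional depth range used for matching (default: all).
#' @param max_lag largest |lag| searched, pixels.
#' @return Integer vector of lags, one per profile.
#' @export
align_profiles <- function(profiles, reference, range_um = NULL, max_lag = 15) {
  if (!length(profiles)) abort("empty profile list")
  ref <- reference$value
  idx <- if (is.null(range_um)) seq_along(ref)
  else which(reference$depth_um >= range_um[1] &
               reference$depth_um <= range_um[2])
  vapply(profiles, function(p) xcorr_lag(p$value, ref, idx, max_lag),
         integer(1))
}

#' Shift a profile by an integer lag
#'
#' @param profile tibble with a `value` column.
#' @param lag pixels to shift by (`new(z) = old(z - lag)`).
#' @return The shifted tibble.
#' @export
apply_profile_offset <- function(profile, lag) {
  dplyr::mutate(profile, value = shift_vec(.data$value, lag))
}

#' Boxcar-smooth an axial profile
#'
#' Centered moving average used to suppress residual speckle before peak
#' localization; edge pixels without a full window are `NA`.
#'
#' @param profile tibble with a `value` column.
#' @param window_px odd window length in pixels.
#' @return The smoothed tibble.
#' @export
smooth_profile <- function(profile, window_px = 5) {
  if (window_px %% 2 == 0) abort("`window_px` must be odd")
  dplyr::mutate(profile, value = as.numeric(
    stats::filter(.data$value, rep(1 / window_px, window_px), sides = 2)))
}

#' Locate the RPE and choroid intensity peaks and the RC ratio
#'
#' Finds the two most prominent local maxima of a normalized intensity
#' profile within the outer-retina search range, requires them to be
#' separated by a local minimum at least `valley_drop` below the lower peak,
#' orders them by depth (RPE above choroid), and reports the RC ratio: the
#' linear-scale RPE peak intensity divided by the choroidal peak intensity.
#' Being a ratio of two peaks of the same profile, it is invariant to global
#' intensity drift.
#'
#' @param profile normalized profile tibble (`depth_um`, `value`).
#' @param search_range depth range `(min, max)` in um covering RPE through
#'   choroid.
#' @param valley_drop required fractional dip between the peaks.
#' @param min_height smallest peak height considered.
#' @return A one-row tibble: `rpe_px`, `rpe_um`, `rpe_intensity`,
#'   `choroid_px`, `choroid_um`, `choroid_intensity`, `rc_ratio`.
#' @export
find_rpe_choroid_peaks <- function(profile, search_range, valley_drop = 0.1,
                                   min_height = 0.05) {
  idx <- which(profile$depth_um >= search_range[1] &
                 profile$depth_um <= search_range[2])
  if (length(idx) < 5) abort("search range too small")
  v <- profile$value[idx]
  pk <- pracma::findpeaks(v, minpeakheight = min_height, nups = 1, ndowns = 1)
  if (is.null(pk) || nrow(pk) < 2) abort("peaks not resolved")
  pk <- pk[order(pk[, 1], decreasing = TRUE), , drop = FALSE]
  first <- pk[1, ]
  second <- NULL
  for (i in 2:nrow(pk)) {
    cand <- pk[i, ]
    lo <- min(first[2], cand[2]); hi <- max(first[2], cand[2])
    valley <- min(v[lo:hi])
    if (valley <= (1 - valley_drop) * min(first[1], cand[1])) {
      second <- cand; break
    }
  }
  if (is.null(second)) abort("peaks not resolved")
  pair <- rbind(first, second)
  pair <- pair[order(pair[, 2]), ]
  gi <- idx[pair[, 2]]
  tibble(rpe_px = unname(gi[1]), rpe_um = profile$depth_um[gi[1]],
         rpe_intensity = unname(pair[1, 1]),
         choroid_px = unname(gi[2]), choroid_um = profile$depth_um[gi[2]],
         choroid_intensity = unname(pair[2, 1]),
         rc_ratio = unname(pair[1, 1] / pair[2, 1]))
}

#' Composite cross-sectional image
#'
#' Averages a block of adjacent B-scans (and their repeats, when the volume
#' carries a repeat dimension) into one cross-section to suppress speckle.
#'
#' @param x a `(z, x, y)` array of B-scans or a `(z, x, y, repeat)` array.
#' @param y_start first B-scan of the block.
#' @param n_bscans number of adjacent B-scans averaged.
#' @param n_repeats repeats per B-scan (for 3-d input, a multiplicative
#'   block along y).
#' @return A `(z, x)` matrix.
#' @export
composite_bscan <- function(x, y_start = 1, n_bscans = 50, n_repeats = 5) {
  d <- dim(x)
  block <- if (length(d) == 4) n_bscans else n_bscans * n_repeats
  if (y_start < 1 || y_start + block - 1 > d[3])
    abort("B-scan block exceeds the volume extent")
  ys <- y_start:(y_start + block - 1)
  sub <- if (length(d) == 4) x[, , ys, , drop = FALSE]
  else x[, , ys, drop = FALSE]
  matrix(rowMeans(matrix(sub, d[1] * d[2]), na.rm = TRUE), d[1], d[2])
}

#' Mask a metric image below an intensity threshold
#'
#' Sets metric pixels to `NA` (masked, not zeroed) wherever the co-registered
#' normalized intensity falls below `threshold` -- used to suppress
#' noise-dominated depolarization/SSCoV pixels in display images. The 0.2
#' default balances noise removal against preservation of real signal.
#'
#' @param image metric image (matrix or array).
#' @param intensity_image normalized linear-scale intensity, same shape.
#' @param threshold normalized intensity cut-off.
#' @return `image` with sub-threshold pixels masked.
#' @export
threshold_mask <- function(image, intensity_image, threshold = 0.2) {
  if (!identical(dim(image), dim(intensity_image)))
    abort("`image` and `intensity_image` must have identical dimensions")
  image[intensity_image < threshold] <- NA_real_
  image
}
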