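# Shared fixtures: small deterministic volumes built in code.

default_k_grid <- function(n_k = 489, band = c(803, 888)) {
  seq(lambda_to_k(band[2]), lambda_to_k(band[1]), length.out = n_k)
}

# raw volume holding pure cosine tones at the given optical depths (um)
tone_volume <- function(depths_um, amps = rep(1, length(depths_um)),
                        n_k = 489, nx = 1, ny = 1, channels = "co") {
  k <- default_k_grid(n_k)
  fr <- rowSums(vapply(seq_along(depths_um),
                       function(i) amps[i] * cos(2 * k * depths_um[i]),
                       numeric(n_k)))
  oct_volume(array(rep(fr, nx * ny * length(channels)),
                   c(n_k, nx, ny, length(channels))),
             k, channels = channels)
}

# spectral profile tibble from the closed-form Beer-Lambert forward model
# (speckle-free; the independent oracle for the SCoV/SSCoV math)
bl_profile_tbl <- function(spectrum, concentration_scale = 1,
                           depth_max = 200, pitch = 2) {
  beer_lambert_profiles(spectrum, concentration_scale, depth_max, pitch) |>
    dplyr::group_by(.data$wavelength_nm) |>
    dplyr::mutate(depth_px = dplyr::row_number()) |>
    dplyr::ungroup()
}

# uniform-state dual-channel tomogram with optional additive complex noise
pure_state_tomogram <- function(d = c(16, 6, 6), sig = 1, noise_v = 0) {
  n <- prod(d)
  f <- array(complex(real = 0), c(d, 2))
  f[, , , 1] <- array(complex(real = stats::rnorm(n, sd = sqrt(sig / 2)),
                              imaginary = stats::rnorm(n, sd = sqrt(sig / 2))),
                      d)
  if (noise_v > 0)
    f <- f + array(complex(real = stats::rnorm(2 * n, sd = sqrt(noise_v / 2)),
                           imaginary = stats::rnorm(2 * n,
                                                    sd = sqrt(noise_v / 2))),
                   c(d, 2))
  oct_tomogram(f, pitch_z = 2, pitch_xy = 2)
}

# brute-force sliding least-squares slope oracle (per mm)
brute_sscov <- function(cov, window, pitch_um) {
  half <- (window - 1) / 2
  n <- length(cov)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i <= half || i > n - half) next
    idx <- (i - half):(i + half)
    y <- cov[idx]
    if (anyNA(y)) next
    out[i] <- unname(coef(lm(y ~ idx))[2]) / (pitch_um / 1000)
  }
  out
}

skinny_phantom <- function(icg_um, il_pct = 8, seed = 1, lateral = 8) {
  sc <- phantom_scene(icg_um, il_pct)
  simulate_fringe_volume(sc, lateral_size = c(lateral, lateral), seed = seed)
}
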