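test_that("window bank design follows the band and width conventions", {
  b <- design_window_bank(c(803, 888), 20, 6)
  expect_length(b$centers_nm, 20)
  expect_equal(diff(b$centers_nm), rep(85 / 19, 19))
  expect_length(b$sigma_k, 1) # one shared width
  full <- design_window_bank(c(803, 888), 20, 1)
  expect_equal(b$sigma_k, full$sigma_k / 6)
  # resolution_factor 1 reproduces the full-band Gaussian's sigma
  dk_band <- lambda_to_k(803) - lambda_to_k(888)
  expect_equal(full$sigma_k, dk_band / (2 * sqrt(2 * log(2))))
  # minimal bank: two windows at the band edges
  b2 <- design_window_bank(c(803, 888), 2, 6)
  expect_equal(b2$centers_nm, c(803, 888))
  expect_equal(b2$sigma_k, b$sigma_k)
  # the bank reports a contiguous adjacent-overlap band
  expect_true(all(b$overlap_range > 0 & b$overlap_range < 1))
  expect_lte(b$overlap_range[1], b$overlap_range[2])
  expect_error(design_window_bank(c(888, 803)), "degenerate")
  expect_equal(nrow(tidy(b)), 20)
})

test_that("spectral reconstruction is achromatic for an ideal reflector", {
  v <- tone_volume(150)
  st <- spectral_reconstruct(v)
  peaks <- apply(st$intensities[, 1, 1, ], 2, which.max)
  expect_true(all(peaks == peaks[1]))
  mags <- apply(st$intensities[, 1, 1, ], 2, max)
  # windows >= 3 sigma inside the sampled band are fully supported -> equal
  # power; band-edge windows lose truncated tails
  interior <- mags[6:15]
  expect_lt(diff(range(interior)) / mean(interior), 0.02)
  expect_lt(mags[1], mean(interior))

  zero <- oct_volume(array(0, c(489, 1, 1, 1)), default_k_grid(489),
                     channels = "co")
  expect_true(all(spectral_reconstruct(zero)$intensities == 0))

  narrow <- oct_volume(array(0, c(300, 1, 1, 1)),
                       seq(lambda_to_k(880), lambda_to_k(820),
                           length.out = 300), channels = "co")
  expect_error(spectral_reconstruct(narrow), "band mismatch")
})

test_that("channel-wise decay rates track the configured absorption", {
  # strong linear-in-lambda absorption ramp; windowed decay per channel
  # should recover mu(lambda) up to window-mixing blur
  sp <- absorption_spectrum("ramp", peak_mu = 0.004, decline = 0.9)
  layers <- tibble::tibble(name = "m", top_um = 60, thickness_um = 300,
                           reflectivity = 1, depolarization = 0,
                           absorption = list(sp))
  sc <- scene_config(layers, noise_floor = 0)
  v <- simulate_fringe_volume(sc, lateral_size = c(24, 24), seed = 21,
                              channels = "co")
  st <- spectral_reconstruct(v)
  prof <- spectral_profiles(st)
  rates <- prof |>
    dplyr::filter(.data$depth_um > 100, .data$depth_um < 280) |>
    dplyr::group_by(.data$wavelength_nm) |>
    dplyr::summarise(rate = -stats::coef(stats::lm(
      log(.data$intensity) ~ .data$depth_um))[2] / 2)
  sub <- rates[3:18, ]
  expected <- stats::approx(sp$wavelength_nm, sp$mu_a,
                            xout = sub$wavelength_nm)$y
  # blue channels decay faster than red, rates within 20% of configured
  expect_lt(stats::cor(sub$rate, sub$wavelength_nm), -0.95)
  expect_lt(max(abs(sub$rate - expected) / expected), 0.2)
})

test_that("scov matches the population-sd convention and is scale invariant", {
  tbl <- tibble::tibble(depth_px = 1, depth_um = 0,
                        wavelength_nm = c(810, 840, 870),
                        intensity = c(1, 2, 3))
  expect_equal(scov(tbl)$scov, sqrt(2 / 3) / 2)
  same <- dplyr::mutate(tbl, intensity = 5)
  expect_equal(scov(same)$scov, 0)
  # scale invariance
  expect_equal(scov(dplyr::mutate(tbl, intensity = 37.2 * intensity))$scov,
               scov(tbl)$scov)
  # masked where mean <= 0
  z <- dplyr::mutate(tbl, intensity = 0)
  expect_true(is.na(scov(z)$scov))
  expect_error(scov(tbl[1, ]), "2 spectral channels")
  # voxelwise variant agrees with the profile variant on a 1-A-line volume
  v <- tone_volume(150)
  st <- spectral_reconstruct(v)
  vox <- scov(st)
  prof <- scov(spectral_profiles(st))
  expect_equal(vox[, 1, 1], prof$scov)
})

test_that("scov of a weak Beer-Lambert absorber approaches 2 z sigma_mu", {
  sp <- absorption_spectrum("ramp", peak_mu = 4e-4, decline = 0.8)
  sigma_mu <- sqrt(mean((sp$mu_a - mean(sp$mu_a))^2))
  tbl <- bl_profile_tbl(sp, 1, depth_max = 100, pitch = 2)
  co <- scov(tbl)
  keep <- co$depth_um > 0 & 2 * max(sp$mu_a) * co$depth_um < 0.1
  expect_true(any(keep))
  pred <- 2 * co$depth_um[keep] * sigma_mu
  expect_lt(max(abs(co$scov[keep] - pred) / pred), 0.05)
})

test_that("sscov equals the brute-force sliding least-squares oracle", {
  set.seed(4)
  n <- 80
  cov_vals <- 0.2 + 0.01 * seq_len(n) + rnorm(n, sd = 0.02)
  tbl <- tibble::tibble(depth_px = seq_len(n), depth_um = (seq_len(n) - 1) * 2,
                        scov = cov_vals)
  got <- sscov(tbl, fit_window_px = 9)$sscov_per_mm
  want <- brute_sscov(cov_vals, 9, 2)
  expect_equal(got, want, tolerance = 1e-10)
  # edges masked
  expect_true(all(is.na(got[c(1:4, (n - 3):n)])))

  # constant profile -> slope 0; exact line -> exact slope
  flat <- dplyr::mutate(tbl, scov = 0.5)
  expect_equal(max(abs(sscov(flat, 9)$sscov_per_mm), na.rm = TRUE), 0)
  a <- 3.2 # per mm
  line <- dplyr::mutate(tbl, scov = a * .data$depth_um / 1000)
  interior <- sscov(line, 9)$sscov_per_mm
  expect_equal(unique(round(interior[!is.na(interior)], 9)), a)

  expect_error(sscov(tbl, fit_window_px = 8), "odd")
  expect_error(sscov(tbl[1:5, ], fit_window_px = 9), "shorter")
})

test_that("a step in scov maximizes |slope| at the step and decays away", {
  n <- 61
  cov_vals <- c(rep(0.2, 30), rep(0.5, 31))
  tbl <- tibble::tibble(depth_px = 1:n, depth_um = (0:(n - 1)) * 2,
                        scov = cov_vals)
  s <- sscov(tbl, 11)$sscov_per_mm
  expect_equal(which.max(abs(s)), 30, tolerance = 1)
  expect_equal(s[c(20, 45)], c(0, 0), tolerance = 1e-9)
})

test_that("sscov_roi fits the stated window exactly and checks bounds", {
  tbl <- tibble::tibble(depth_px = 1:50, depth_um = (0:49) * 2,
                        scov = 1.7 * (0:49) * 2 / 1000 + 0.1)
  expect_equal(sscov_roi(tbl, 10, 11), 1.7)
  expect_error(sscov_roi(tbl, 45, 11), "out of bounds")
  # pure-noise ROI: slope indistinguishable from zero over repeated draws
  set.seed(7)
  slopes <- replicate(200, {
    noisy <- dplyr::mutate(tbl, scov = rnorm(50, 0.3, 0.05))
    sscov_roi(noisy, 10, 11)
  })
  expect_lt(abs(mean(slopes)) / (sd(slopes) / sqrt(200)), 3)
})

test_that("chromatic alignment recovers known shifts, ties toward zero", {
  set.seed(11)
  base <- exp(-((1:120) - 40)^2 / 50) + 0.5 * exp(-((1:120) - 80)^2 / 80)
  shifts <- c(-2, -1, 0, 1, 2)
  tbl <- purrr::map_dfr(seq_along(shifts), function(j) {
    v <- spectroct:::shift_vec(base, shifts[j])
    tibble::tibble(depth_px = 1:120, depth_um = (0:119) * 2,
                   wavelength_nm = 800 + 5 * j,
                   intensity = ifelse(is.na(v), 0, v))
  })
  lags <- align_spectral_profiles(tbl, c(20, 200), max_lag = 5)
  expect_equal(lags$lag, -shifts)
  # identical channels -> all zero lags
  same <- dplyr::mutate(tbl, intensity = rep(base, 5))
  expect_equal(align_spectral_profiles(same, c(20, 200))$lag, rep(0L, 5))
  expect_error(align_spectral_profiles(tbl, c(50, 50)), "empty reference")
  # applying the recovered lags undoes the shifts
  realigned <- apply_spectral_offsets(tbl, lags)
  wide <- tidyr::pivot_wider(realigned, names_from = "wavelength_nm",
                             values_from = "intensity")
  inner <- wide[10:110, -(1:2)]
  expect_lt(max(abs(inner - inner[[3]])), 1e-9)
})

test_that("alignment is robust to speckle noise across many draws", {
  # realistic setting: many channels, a linear dispersion ramp of shifts,
  # independent noise per channel
  set.seed(23)
  base <- exp(-((1:150) - 50)^2 / 60) + 0.8 * exp(-((1:150) - 95)^2 / 100)
  n_ch <- 10
  hits <- 0L; total <- 0L
  n_rep <- 100
  for (r in seq_len(n_rep)) {
    shifts <- round(seq(-2, 2, length.out = n_ch))
    tbl <- purrr::map_dfr(seq_len(n_ch), function(j) {
      v <- spectroct:::shift_vec(base, shifts[j]) + rnorm(150, sd = 0.05)
      tibble::tibble(depth_px = 1:150, depth_um = (0:149) * 2,
                     wavelength_nm = 800 + 5 * j,
                     intensity = ifelse(is.na(v), 0, v))
    })
    lags <- align_spectral_profiles(tbl, c(30, 260), max_lag = 5)
    hits <- hits + sum(lags$lag == -shifts)
    total <- total + n_ch
  }
  expect_gte(hits, 0.9 * total)
})
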