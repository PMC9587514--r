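test_that("annular averaging matches pixel enumeration exactly", {
  roi <- annular_roi(c(5.5, 5.5), 30, 80)
  # constant volume
  vol <- array(3.7, c(6, 10, 10))
  prof <- annular_average(vol, roi, pitch_xy = 20, pitch_z = 2)
  expect_equal(prof$value, rep(3.7, 6))
  # laterally uniform f(z)
  fz <- array(rep(sin(1:6), 100), c(6, 10, 10))
  expect_equal(annular_average(fz, roi, pitch_xy = 20)$value, sin(1:6))
  # checkerboard against a brute-force enumeration oracle
  vol2 <- array(0, c(4, 10, 10))
  for (ix in 1:10) for (iy in 1:10) vol2[, ix, iy] <- (ix + iy) %% 2
  got <- annular_average(vol2, roi, pitch_xy = 20)$value
  inside <- sel <- matrix(FALSE, 10, 10)
  vals <- c()
  for (ix in 1:10) for (iy in 1:10) {
    d <- 20 * sqrt((ix - 5.5)^2 + (iy - 5.5)^2)
    if (d >= 30 && d < 80) vals <- c(vals, (ix + iy) %% 2)
  }
  expect_equal(got, rep(mean(vals), 4))
  # half-open membership: a pixel exactly on the outer radius is excluded
  roi_edge <- annular_roi(c(1, 1), 20, 40)
  m <- spectroct:::annulus_mask(3, 1, roi_edge, 20) # distances 0, 20, 40
  expect_equal(m, c(FALSE, TRUE, FALSE))
  expect_error(annular_average(vol, annular_roi(c(50, 50), 370, 460),
                               pitch_xy = 1), "empty annulus")
})

test_that("radial reslicing preserves symmetric volumes", {
  nx <- 21
  c0 <- 11
  vol <- array(0, c(4, nx, nx))
  for (ix in 1:nx) for (iy in 1:nx) {
    r <- sqrt((ix - c0)^2 + (iy - c0)^2)
    vol[, ix, iy] <- exp(-((r - 5)^2) / 4) # bright ring at r = 5 px
  }
  res <- radial_reslice(vol, c(c0, c0), pitch_xy = 10, dtheta_deg = 0.5)
  radii <- attr(res, "radius_um")
  # constant volume reslices to a constant
  resc <- radial_reslice(array(2, c(4, nx, nx)), c(c0, c0), pitch_xy = 10)
  expect_equal(max(abs(resc - 2)), 0, tolerance = 1e-9)
  # ring peaks at radius 50 um in every depth row
  peak_r <- radii[apply(res, 1, which.max)]
  expect_true(all(peak_r == 50))
  # radially symmetric: resliced image equals the radial cut of the volume
  cut <- vol[1, c0:(c0 + 10), c0]
  expect_equal(as.numeric(res[1, 1:11]), cut, tolerance = 0.05)
  expect_error(radial_reslice(vol, c(100, 5), pitch_xy = 10),
               "center outside")
})

test_that("profile normalization does its arithmetic and is idempotent", {
  prof <- tibble::tibble(depth_um = (0:99) * 2,
                         value = 0.1 + c(rep(0, 40), 2 * exp(-((40:99) - 60)^2 / 30)))
  np <- normalize_profile(prof, noise_range = c(0, 70), peak_range = c(100, 160))
  rec <- attr(np, "normalization")
  expect_equal(mean(np$value[prof$depth_um <= 70]), 0, tolerance = 1e-12)
  expect_equal(max(np$value[prof$depth_um >= 100 & prof$depth_um <= 160]), 1)
  expect_equal(rec$noise_mean, 0.1, tolerance = 1e-9)
  # idempotence
  np2 <- normalize_profile(np, c(0, 70), c(100, 160))
  expect_equal(np2$value, np$value, tolerance = 1e-12)
  # degenerate all-noise profile
  flat <- tibble::tibble(depth_um = (0:99) * 2, value = 0.1)
  expect_error(normalize_profile(flat, c(0, 70), c(100, 160)),
               "non-positive peak")
  expect_error(normalize_profile(prof, c(0, 100), c(80, 160)),
               "must not overlap")
})

test_that("profile alignment recovers shifts and reuses offsets", {
  base <- exp(-((1:200) - 70)^2 / 40) + 0.6 * exp(-((1:200) - 130)^2 / 60)
  ref <- tibble::tibble(depth_um = (0:199) * 2, value = base)
  shifted <- lapply(c(-4, 0, 3), function(s)
    tibble::tibble(depth_um = (0:199) * 2,
                   value = {
                     v <- spectroct:::shift_vec(base, s)
                     ifelse(is.na(v), 0, v)
                   }))
  lags <- align_profiles(shifted, ref)
  expect_equal(lags, c(4L, 0L, -3L))
  expect_equal(align_profiles(list(ref), ref), 0L)
  expect_error(align_profiles(list(), ref), "empty")
  # applying the offset re-registers the profile
  re <- apply_profile_offset(shifted[[1]], lags[1])
  expect_equal(re$value[20:180], base[20:180], tolerance = 1e-12)
  # robustness over noisy draws
  set.seed(31)
  hits <- 0
  for (r in 1:100) {
    s <- sample(-5:5, 1)
    noisy <- tibble::tibble(depth_um = (0:199) * 2,
                            value = {
                              v <- spectroct:::shift_vec(base, s)
                              ifelse(is.na(v), 0, v) + rnorm(200, sd = 0.05)
                            })
    if (align_profiles(list(noisy), ref, max_lag = 8) == -s) hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("RPE/choroid peak localization and the RC ratio behave", {
  z <- (0:199) * 2
  mk <- function(rpe_amp, ch_amp = 0.8) tibble::tibble(
    depth_um = z,
    value = rpe_amp * exp(-(z - 300)^2 / 60) + ch_amp * exp(-(z - 350)^2 / 120))
  eq <- find_rpe_choroid_peaks(mk(0.8), c(240, 420))
  expect_equal(eq$rc_ratio, 1, tolerance = 1e-6)
  expect_lt(eq$rpe_um, eq$choroid_um)
  # scaling the RPE peak scales the ratio linearly
  sc <- find_rpe_choroid_peaks(mk(0.6), c(240, 420))
  expect_equal(sc$rc_ratio, 0.75, tolerance = 1e-6)
  # and scaling the choroid peak scales it inversely
  inv <- find_rpe_choroid_peaks(mk(0.8, 0.4), c(240, 420))
  expect_equal(inv$rc_ratio, 2, tolerance = 0.01)
  # monotone decay with no second peak errors
  mono <- tibble::tibble(depth_um = z, value = exp(-z / 100))
  expect_error(find_rpe_choroid_peaks(mono, c(240, 420)), "not resolved")
  # two maxima without a sufficient valley error too
  shoulder <- tibble::tibble(
    depth_um = z, value = exp(-(z - 300)^2 / 5000) +
      0.02 * exp(-(z - 340)^2 / 20))
  expect_error(find_rpe_choroid_peaks(shoulder, c(240, 420)), "not resolved")
})

test_that("composite B-scans average blocks and cut speckle contrast", {
  set.seed(13)
  one <- matrix(rexp(40 * 8), 40, 8)
  vol <- array(rep(one, 10), c(40, 8, 10))
  comp <- composite_bscan(vol, 1, n_bscans = 5, n_repeats = 2)
  expect_equal(comp, one)
  expect_error(composite_bscan(vol, 5, n_bscans = 5, n_repeats = 2),
               "exceeds")
  # independent speckled repeats: contrast drops like 1/sqrt(N)
  volr <- array(rexp(40 * 8 * 16), c(40, 8, 16))
  comp16 <- composite_bscan(volr, 1, n_bscans = 16, n_repeats = 1)
  c1 <- sd(volr[, , 1]) / mean(volr[, , 1])
  c16 <- sd(comp16) / mean(comp16)
  expect_equal(c16 / c1, 1 / 4, tolerance = 0.25)
})

test_that("threshold masking masks exactly the sub-threshold pixels", {
  img <- matrix(1:6, 2, 3)
  inten <- matrix(c(0.1, 0.3, 0.19, 0.21, 0.3, 0.1), 2, 3)
  out <- threshold_mask(img, inten, 0.2)
  expect_equal(is.na(out), inten < 0.2)
  expect_equal(out[!is.na(out)], img[inten >= 0.2])
  expect_error(threshold_mask(img, inten[, 1:2]), "identical dimensions")
})

test_that("lateral_mean and smooth_profile keep tibble contracts", {
  vol <- array(rep(1:5, 8), c(5, 4, 2))
  lm_ <- lateral_mean(vol, pitch_z = 2)
  expect_equal(lm_$value, 1:5)
  expect_equal(lm_$depth_um, (0:4) * 2)
  sm <- smooth_profile(tibble::tibble(depth_um = (0:9) * 2, value = rep(c(0, 1), 5)),
                       window_px = 3)
  expect_equal(sm$value[2:9], rep(c(1 / 3, 2 / 3), 4), tolerance = 1e-12)
  expect_error(smooth_profile(lm_, 4), "odd")
})
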