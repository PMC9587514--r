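#' Stokes vectors from a dual-channel tomogram
#'
#' Builds per-voxel Stokes components from the co- and cross-polarized
#' complex fields:
#' \deqn{s_0 = |E_{co}|^2 + |E_{cr}|^2,\quad s_1 = |E_{co}|^2 - |E_{cr}|^2,}
#' \deqn{s_2 = 2\,\mathrm{Re}(E_{co}E_{cr}^*),\quad
#'       s_3 = 2\,\mathrm{Im}(E_{co}E_{cr}^*).}
#' A single coherent voxel is fully polarized
#' (\eqn{s_1^2+s_2^2+s_3^2 = s_0^2}); depolarization only appears after
#' spatial averaging.
#'
#' @param tomogram an [oct_tomogram()] with exactly two channels.
#' @return An object of class `stokes_volume`: arrays `s0`, `s1`, `s2`, `s3`
#'   indexed `(z, x, y)` plus pitches.
#' @export
stokes_from_channels <- function(tomogram) {
  stopifnot(inherits(tomogram, "oct_tomogram"))
  if (dim(tomogram$field)[4] != 2L)
    abort("Stokes construction needs exactly 2 channels")
  co <- match("co", tomogram$channels); cr <- match("cross", tomogram$channels)
  if (is.na(co) || is.na(cr)) { co <- 1L; cr <- 2L }
  d <- dim(tomogram$field)[1:3]
  eco <- array(tomogram$field[, , , co], d)
  ecr <- array(tomogram$field[, , , cr], d)
  i_co <- Mod(eco)^2; i_cr <- Mod(ecr)^2
  cross <- eco * Conj(ecr)
  structure(list(s0 = i_co + i_cr, s1 = i_co - i_cr,
                 s2 = 2 * Re(cross), s3 = 2 * Im(cross),
                 pitch_z = tomogram$pitch_z, pitch_xy = tomogram$pitch_xy),
            class = "stokes_volume")
}

# Uniform boxcar mean along one array dimension with shrink-at-edges
# (average over the valid intersection). Even kernel sizes are centered with
# the extra sample on the shallow side: offsets -floor(k/2) .. ceil(k/2)-1.
box_mean_dim <- function(a, dim, size) {
  if (size <= 1) return(a)
  d <- dim(a)
  perm <- c(dim, setdiff(seq_along(d), dim))
  m <- matrix(aperm(a, perm), d[dim])
  n <- nrow(m)
  lo <- floor(size / 2); hi <- size - 1 - lo
  cs <- rbind(0, apply(m, 2, cumsum))
  upper <- pmin(seq_len(n) + hi, n)
  lower <- pmax(seq_len(n) - lo, 1)
  sums <- cs[upper + 1L, , drop = FALSE] - cs[lower, , drop = FALSE]
  out <- sums / (upper - lower + 1L)
  aperm(array(out, d[perm]), order(perm))
}

box_mean <- function(a, kernel) {
  for (i in seq_along(kernel)) a <- box_mean_dim(a, i, kernel[i])
  a
}

box_count <- function(d, kernel) {
  cnt <- array(1, d)
  for (i in seq_along(kernel)) {
    n <- d[i]; size <- kernel[i]
    lo <- floor(size / 2); hi <- size - 1 - lo
    c1 <- pmin(seq_len(n) + hi, n) - pmax(seq_len(n) - lo, 1) + 1
    shape <- rep(1, length(d)); shape[i] <- n
    cnt <- cnt * array(rep(c1, each = prod(d[seq_len(i - 1)])), d)
  }
  cnt
}

#' Degree of polarization uniformity (DOPU)
#'
#' Averages the Stokes components over a uniform spatial kernel and forms
#' \deqn{DOPU = \sqrt{\bar s_1^2 + \bar s_2^2 + \bar s_3^2} / \bar s_0,}
#' clipped to \[0, 1\]. Uniform polarization states give 1; states scrambled
#' within the kernel approach the random-walk floor \eqn{\approx 1/\sqrt N}.
#'
#' Additive detector noise biases the estimate upward: the squared kernel
#' means of \eqn{s_{1,2,3}} are inflated by the variance of their
#' noise-driven fluctuations, so noise-dominated regions report spurious
#' polarization uniformity. With `bias_correction = TRUE` each squared
#' component mean is reduced by its estimated noise variance
#' \eqn{(2 v \bar s_{0,sig} + 2v^2)/N} (the sum clamped at zero), where `v`
#' is the per-channel noise power `noise_variance`,
#' \eqn{\bar s_{0,sig} = \max(\bar s_0 - 2v, 0)} the signal part of
#' \eqn{\bar s_0}, and `N` the kernel count. The noise power \eqn{2v} is
#' likewise subtracted from the denominator \eqn{\bar s_0}, bounded below at
#' half the raw \eqn{\bar s_0} so the ratio stays finite in noise-dominated
#' voxels; there the corrected numerator collapses to ~0 and DOPU is pulled
#' towards 0 instead of being inflated by noise.
#'
#' @param stokes a [stokes_from_channels()] volume.
#' @param kernel smoothing kernel size in pixels `(z, x, y)`; the default
#'   4 x 4 x 4 corresponds to 8 x 8 x 10 um at the synthetic pitches. Edges
#'   use the valid intersection (shrink-at-edges), so profiles keep their
#'   full depth extent.
#' @param noise_variance per-channel additive noise power in the
#'   reconstructed field (see [estimate_noise_variance()]).
#' @param bias_correction apply the noise-bias correction.
#' @param mask_threshold optional: mask voxels whose uncorrected
#'   \eqn{\bar s_0} falls below this value.
#'
#' @return An object of class `dopu_volume`: `dopu` array `(z, x, y)` (NA
#'   where masked), plus `kernel` and pitches.
#' @export
dopu <- function(stokes, kernel = c(4, 4, 4), noise_variance = 0,
                 bias_correction = TRUE, mask_threshold = NULL) {
  stopifnot(inherits(stokes, "stokes_volume"))
  d <- dim(stokes$s0)
  if (any(kernel > d)) abort("kernel larger than volume")
  if (noise_variance < 0) abort("`noise_variance` must be >= 0")
  m0 <- box_mean(stokes$s0, kernel)
  m1 <- box_mean(stokes$s1, kernel)
  m2 <- box_mean(stokes$s2, kernel)
  m3 <- box_mean(stokes$s3, kernel)
  v <- noise_variance
  num2 <- m1^2 + m2^2 + m3^2
  m0c <- m0
  if (bias_correction && v > 0) {
    nk <- box_count(d, kernel)
    bias <- 3 * (2 * v * pmax(m0 - 2 * v, 0) + 2 * v^2) / nk
    num2 <- pmax(num2 - bias, 0)
    # denominator correction bounded at half the raw s0 so the ratio stays
    # finite in noise-dominated voxels (where s0 - 2v crosses zero)
    m0c <- pmax(m0 - 2 * v, 0.5 * m0)
  }
  out <- sqrt(num2) / m0c
  out[m0c <= 0] <- NA_real_
  out <- pmin(pmax(out, 0), 1)
  if (!is.null(mask_threshold)) out[m0 < mask_threshold] <- NA_real_
  structure(list(dopu = array(out, d), kernel = kernel,
                 pitch_z = stokes$pitch_z, pitch_xy = stokes$pitch_xy),
            class = "dopu_volume")
}

#' Depolarization (1 - DOPU)
#'
#' @param x a [dopu()] volume.
#' @return A `dopu_volume` whose array holds `1 - DOPU` (masks propagated).
#' @export
one_minus_dopu <- function(x) {
  stopifnot(inherits(x, "dopu_volume"))
  x$dopu <- 1 - x$dopu
  x
}

#' Estimate the per-channel noise power of a reconstructed field
#'
#' Mean squared field magnitude per channel over a signal-free depth range
#' (vitreous or air above the sample), averaged across channels.
#'
#' @param tomogram an [oct_tomogram()].
#' @param z_range_um depth range `(min, max)` in um known to contain no
#'   structure.
#' @return Scalar noise power `v` (per channel), for [dopu()]'s
#'   `noise_variance`.
#' @export
estimate_noise_variance <- function(tomogram, z_range_um) {
  stopifnot(inherits(tomogram, "oct_tomogram"))
  z <- (seq_len(dim(tomogram$field)[1]) - 1) * tomogram$pitch_z
  idx <- which(z >= z_range_um[1] & z <= z_range_um[2])
  if (!length(idx)) abort("empty noise range")
  mean(Mod(tomogram$field[idx, , , , drop = FALSE])^2)
}
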