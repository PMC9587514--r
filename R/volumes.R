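#' Raw spectral fringe volume
#'
#' Container for k-sampled OCT interferograms, one real-valued fringe per
#' A-line per polarization channel, prior to reconstruction. The wavenumber
#' grid must be uniform because the depth reconstruction is a discrete Fourier
#' transform along k.
#'
#' @param fringes numeric array indexed `(k, x, y, channel)`.
#' @param k_grid strictly increasing, uniformly spaced wavenumber samples in
#'   rad/um, conventionally spanning the 803--888 nm band.
#' @param background per-k mean background spectrum: either a vector of length
#'   `length(k_grid)` shared by all channels or a `k x channel` matrix.
#'   Subtracted before the k-to-z transform.
#' @param channels character labels, `c("co", "cross")` or `"co"`.
#' @param meta optional [volume_metadata()] list.
#'
#' @return An object of class `oct_volume`.
#' @seealso [reconstruct()], [simulate_fringe_volume()], [read_oct_h5()]
#' @export
oct_volume <- function(fringes, k_grid, background = NULL,
                       channels = c("co", "cross"), meta = NULL) {
  if (length(dim(fringes)) != 4L)
    abort("`fringes` must be a 4-d array (k, x, y, channel)")
  n_k <- dim(fringes)[1]
  n_ch <- dim(fringes)[4]
  if (!n_ch %in% 1:2) abort("number of channels must be 1 or 2")
  if (length(channels) != n_ch) abort("`channels` must match the channel dimension")
  if (length(k_grid) != n_k) abort("`k_grid` length must match the k dimension")
  if (any(!is.finite(fringes))) abort("`fringes` must be finite")
  check_uniform_grid(k_grid, "k_grid")
  if (is.null(background)) background <- matrix(0, n_k, n_ch)
  if (is.null(dim(background))) background <- matrix(background, n_k, n_ch)
  if (nrow(background) != n_k || ncol(background) != n_ch)
    abort("`background` must be per-k (optionally per-channel)")
  structure(
    list(fringes = fringes, k_grid = as.numeric(k_grid),
         background = background, channels = channels, meta = meta),
    class = "oct_volume")
}

check_uniform_grid <- function(k, name) {
  if (length(k) < 2L) abort(sprintf("`%s` needs at least 2 samples", name))
  dk <- diff(k)
  if (any(dk <= 0)) abort(sprintf("`%s` must be strictly increasing", name))
  if (max(abs(dk - dk[1])) > 1e-8 * abs(dk[1]))
    abort(sprintf("`%s` must be uniformly spaced (non-uniform grid)", name))
  invisible(TRUE)
}

#' Complex depth-resolved tomogram
#'
#' @param field complex array indexed `(z, x, y, channel)`; depth index 1 is
#'   the shallowest (vitreous) side.
#' @param pitch_z axial pixel pitch in um.
#' @param pitch_xy lateral pixel pitch in um.
#' @param channels channel labels.
#' @param meta optional [volume_metadata()] list.
#'
#' @return An object of class `oct_tomogram`.
#' @export
oct_tomogram <- function(field, pitch_z, pitch_xy = NA_real_,
                         channels = c("co", "cross"), meta = NULL) {
  if (length(dim(field)) != 4L)
    abort("`field` must be a 4-d array (z, x, y, channel)")
  if (!is.numeric(pitch_z) || pitch_z <= 0) abort("`pitch_z` must be > 0")
  if (length(channels) != dim(field)[4])
    abort("`channels` must match the channel dimension")
  structure(
    list(field = field, pitch_z = as.numeric(pitch_z),
         pitch_xy = as.numeric(pitch_xy), channels = channels, meta = meta),
    class = "oct_tomogram")
}

#' Per-volume acquisition metadata
#'
#' @param eye eye identifier string.
#' @param group group label, `"control"` or `"knockout"`.
#' @param age_months age at acquisition in months (> 0).
#' @param onh_center optic-nerve-head center `(x, y)` in pixels (the manual
#'   annotation the reductions pivot on).
#'
#' @return A named list of class `volume_metadata`.
#' @export
volume_metadata <- function(eye, group = c("control", "knockout"),
                            age_months, onh_center) {
  group <- match.arg(group)
  if (age_months <= 0) abort("`age_months` must be > 0")
  if (length(onh_center) != 2L) abort("`onh_center` must be (x, y)")
  structure(list(eye = as.character(eye), group = group,
                 age_months = as.numeric(age_months),
                 onh_center = as.numeric(onh_center)),
            class = "volume_metadata")
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$fringes)
  lam <- rev(range(2 * pi / x$k_grid) * 1e3)
  cat(sprintf("<oct_volume> %d k-samples x %d x %d A-lines, channels: %s\n",
              d[1], d[2], d[3], paste(x$channels, collapse = ", ")))
  cat(sprintf("  band %.0f-%.0f nm\n", lam[1], lam[2]))
  invisible(x)
}

#' @export
print.oct_tomogram <- function(x, ...) {
  d <- dim(x$field)
  cat(sprintf("<oct_tomogram> %d z x %d x %d, channels: %s, pitch_z %.3f um\n",
              d[1], d[2], d[3], paste(x$channels, collapse = ", "), x$pitch_z))
  invisible(x)
}

#' Intensity of a tomogram channel
#'
#' Squared field magnitude on linear scale.
#'
#' @param tomogram an [oct_tomogram()].
#' @param channel channel label or index (default the co-polarized channel).
#' @return numeric array `(z, x, y)`.
#' @export
intensity <- function(tomogram, channel = "co") {
  stopifnot(inherits(tomogram, "oct_tomogram"))
  if (is.character(channel)) channel <- match(channel, tomogram$channels)
  if (is.na(channel)) abort("unknown channel")
  f <- tomogram$field[, , , channel, drop = FALSE]
  array(Mod(f)^2, dim = dim(f)[1:3])
}

#' Reconstruct a complex tomogram from raw fringes
#'
#' Subtracts the stored background spectrum, optionally applies a spectral
#' window, and Fourier transforms along k. The transform is zero-padded to
#' the next power of two at least twice the k-sample count (finer axial
#' sampling without changing resolution; pass `n_fft` to override), and only
#' non-negative depths are retained. The axial pixel pitch follows from the
#' k-grid spacing: `pitch_z = pi / (n_fft * dk)`; at the default 489-sample
#' 803--888 nm grid this gives 2.0 um per pixel.
#'
#' @param volume an [oct_volume()].
#' @param window optional per-k weight vector (length = k samples), e.g. a
#'   Gaussian for spectral shaping of the full band.
#' @param n_fft optional minimum transform length (rounded up to a power of 2).
#' @param pitch_xy lateral pitch to stamp on the result, um.
#'
#' @return An [oct_tomogram()] with `dim = (n_fft/2, x, y, channel)`.
#' @examples
#' k <- seq(2 * pi / 0.888, 2 * pi / 0.803, length.out = 489)
#' z0 <- 100 # um
#' fr <- array(cos(2 * k * z0), c(489, 1, 1, 1))
#' v <- oct_volume(fr, k, channels = "co")
#' tom <- reconstruct(v)
#' which.max(Mod(tom$field[, 1, 1, 1])) # ~ z0 / tom$pitch_z + 1
#' @export
reconstruct <- function(volume, window = NULL, n_fft = NULL, pitch_xy = NA_real_) {
  stopifnot(inherits(volume, "oct_volume"))
  d <- dim(volume$fringes)
  n_k <- d[1]
  if (!is.null(window) && length(window) != n_k)
    abort("`window` length must equal the number of k samples")
  n_fft <- next_pow2(max(n_k, n_fft %||% (2L * n_k)))
  dk <- (volume$k_grid[n_k] - volume$k_grid[1]) / (n_k - 1)
  pitch_z <- pi / (n_fft * dk)
  n_z <- n_fft %/% 2L
  out <- array(complex(real = 0), c(n_z, d[2], d[3], d[4]))
  for (ch in seq_len(d[4])) {
    m <- matrix(volume$fringes[, , , ch], n_k, d[2] * d[3]) -
      volume$background[, ch]
    if (!is.null(window)) m <- m * window
    padded <- matrix(0, n_fft, ncol(m))
    padded[seq_len(n_k), ] <- m
    spec <- mvfft(padded)[seq_len(n_z), , drop = FALSE]
    out[, , , ch] <- array(spec, c(n_z, d[2], d[3]))
  }
  oct_tomogram(out, pitch_z = pitch_z,
               pitch_xy = if (is.na(pitch_xy)) volume$meta$pitch_xy %||% NA_real_ else pitch_xy,
               channels = volume$channels, meta = volume$meta)
}

next_pow2 <- function(n) 2L^ceiling(log2(n))

#' Wavelength/wavenumber conversions
#'
#' @param lambda_nm wavelength in nm.
#' @param k wavenumber in rad/um.
#' @return the converted quantity.
#' @export
lambda_to_k <- function(lambda_nm) 2 * pi / (lambda_nm * 1e-3)

#' @rdname lambda_to_k
#' @export
k_to_lambda <- function(k) 2 * pi / k * 1e3
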