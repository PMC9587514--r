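#' Read an OCT volume or tomogram from disk
#'
#' HDF5 is the canonical container. Layout: raw fringe volumes store datasets
#' `/fringes` (k, x, y, channel), `/k_grid`, `/background`, and optionally
#' `/meta` (JSON-serialized [volume_metadata()]); complex tomograms store
#' `/field_real`, `/field_imag`, `/pitch_z`, `/pitch_xy`. Multi-page TIFF is
#' supported read-only for interchange: one page per (y, channel) pair, each
#' page a (k x x) image, with `k_grid` supplied alongside (TIFF carries no
#' wavenumber axis).
#'
#' @param path file path.
#' @param layout `"auto"` (by extension), `"hdf5"` or `"tiff"`.
#' @param ... passed to [read_oct_tiff()] for TIFF input.
#' @return An [oct_volume()] or [oct_tomogram()].
#' @export
read_volume <- function(path, layout = c("auto", "hdf5", "tiff"), ...) {
  layout <- match.arg(layout)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (layout == "auto") {
    layout <- if (grepl("\\.(h5|hdf5)$", path, ignore.case = TRUE)) "hdf5"
    else if (grepl("\\.(tif|tiff)$", path, ignore.case = TRUE)) "tiff"
    else abort("cannot infer layout from extension; pass `layout`")
  }
  switch(layout, hdf5 = read_oct_h5(path), tiff = read_oct_tiff(path, ...))
}

h5_has <- function(path, name) {
  ls <- rhdf5::h5ls(path)
  name %in% ls$name
}

#' @rdname read_volume
#' @export
read_oct_h5 <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  meta <- if (h5_has(path, "meta")) {
    m <- jsonlite::fromJSON(rhdf5::h5read(path, "meta"))
    if (!is.null(m$eye))
      volume_metadata(m$eye, m$group, m$age_months, m$onh_center)
    else m
  }
  if (h5_has(path, "fringes")) {
    if (!h5_has(path, "k_grid"))
      abort("malformed volume file: missing k grid (/k_grid dataset)")
    fr <- rhdf5::h5read(path, "fringes")
    if (length(dim(fr)) != 4L)
      abort("malformed volume file: /fringes must have dimensions (k, x, y, channel)")
    ch <- if (h5_has(path, "channels")) as.character(rhdf5::h5read(path, "channels"))
    else c("co", "cross")[seq_len(dim(fr)[4])]
    bg <- if (h5_has(path, "background")) rhdf5::h5read(path, "background")
    oct_volume(fr, as.numeric(rhdf5::h5read(path, "k_grid")),
               background = bg, channels = ch, meta = meta)
  } else if (h5_has(path, "field_real")) {
    re <- rhdf5::h5read(path, "field_real")
    im <- rhdf5::h5read(path, "field_imag")
    ch <- if (h5_has(path, "channels")) as.character(rhdf5::h5read(path, "channels"))
    else c("co", "cross")[seq_len(dim(re)[4])]
    oct_tomogram(array(complex(real = re, imaginary = im), dim(re)),
                 pitch_z = as.numeric(rhdf5::h5read(path, "pitch_z")),
                 pitch_xy = as.numeric(rhdf5::h5read(path, "pitch_xy")),
                 channels = ch, meta = meta)
  } else {
    abort("malformed volume file: neither /fringes nor /field_real present")
  }
}

#' Write an OCT volume or tomogram to HDF5
#'
#' @param x an [oct_volume()] or [oct_tomogram()].
#' @param path destination file (overwritten if present).
#' @return `path`, invisibly.
#' @export
write_oct_h5 <- function(x, path) {
  if (file.exists(path)) unlink(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5createFile(path)
  if (inherits(x, "oct_volume")) {
    rhdf5::h5write(x$fringes, path, "fringes")
    rhdf5::h5write(x$k_grid, path, "k_grid")
    rhdf5::h5write(x$background, path, "background")
  } else if (inherits(x, "oct_tomogram")) {
    rhdf5::h5write(Re(x$field), path, "field_real")
    rhdf5::h5write(Im(x$field), path, "field_imag")
    rhdf5::h5write(x$pitch_z, path, "pitch_z")
    rhdf5::h5write(x$pitch_xy, path, "pitch_xy")
  } else abort("`x` must be an oct_volume or oct_tomogram")
  rhdf5::h5write(x$channels, path, "channels")
  if (!is.null(x$meta))
    rhdf5::h5write(as.character(jsonlite::toJSON(unclass(x$meta),
                                                 auto_unbox = TRUE)),
                   path, "meta")
  invisible(path)
}

#' @param k_grid wavenumber grid for the TIFF pages (rad/um); if `NULL`, a
#'   sidecar `<path>.json` with fields `k_grid` and `channels` is read.
#' @param channels channel labels for TIFF input.
#' @rdname read_volume
#' @export
read_oct_tiff <- function(path, k_grid = NULL, channels = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  sidecar <- paste0(path, ".json")
  if (is.null(k_grid) && file.exists(sidecar)) {
    side <- jsonlite::fromJSON(sidecar)
    k_grid <- side$k_grid
    channels <- channels %||% side$channels
  }
  if (is.null(k_grid)) abort("missing k grid: pass `k_grid` or provide a sidecar JSON")
  channels <- channels %||% c("co", "cross")
  pages <- tiff::readTIFF(path, all = TRUE)
  n_ch <- length(channels)
  if (length(pages) %% n_ch != 0L)
    abort(sprintf(
      "dimension error: %d TIFF pages not divisible by %d channels",
      length(pages), n_ch))
  n_y <- length(pages) %/% n_ch
  d1 <- dim(pages[[1]])
  fr <- array(0, c(d1[1], d1[2], n_y, n_ch))
  for (y in seq_len(n_y)) for (ch in seq_len(n_ch)) {
    pg <- pages[[(y - 1L) * n_ch + ch]]
    if (!identical(dim(pg), d1)) abort("dimension error: TIFF pages differ in size")
    fr[, , y, ch] <- pg
  }
  oct_volume(fr, k_grid, channels = channels)
}
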