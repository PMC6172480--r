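#' Reconstructed or synthetic 2D image container
#'
#' A light container for 2D rasters on the imaging grid. Rows index depth
#' (increasing z, away from the probe surface), columns index the lateral
#' position along the array. All coordinates are millimetres.
#'
#' @param data numeric matrix, `length(z)` rows by `length(x)` columns.
#' @param x lateral pixel-centre coordinates (mm).
#' @param z depth pixel-centre coordinates (mm).
#' @param spacing grid spacing (mm).
#' @param wavelength illumination wavelength (nm) or `NA` for non-optical
#'   rasters such as the synthetic B-mode background.
#' @param meta named list of provenance metadata (filter chain, speed of
#'   sound, seeds, ...).
#' @return An object of class `oa_image`.
#' @export
oa_image <- function(data, x, z, spacing, wavelength = NA_real_, meta = list()) {
  data <- as.matrix(data)
  if (nrow(data) != length(z) || ncol(data) != length(x))
    stop_oa("image dims must be length(z) x length(x)")
  if (!all(is.finite(data))) stop_oa("image values must be finite")
  structure(list(data = data, x = as.numeric(x), z = as.numeric(z),
                 spacing = spacing, wavelength = wavelength, meta = meta),
            class = "oa_image")
}

#' @export
print.oa_image <- function(x, ...) {
  cat(sprintf("<oa_image> %d x %d px, spacing %.3g mm, wavelength %s nm\n",
              nrow(x$data), ncol(x$data), x$spacing,
              ifelse(is.na(x$wavelength), "-", format(x$wavelength))))
  cat(sprintf("  lateral [%.1f, %.1f] mm, depth [%.1f, %.1f] mm\n",
              min(x$x), max(x$x), min(x$z), max(x$z)))
  invisible(x)
}

#' @export
as.matrix.oa_image <- function(x, ...) x$data

same_grid <- function(a, b) {
  isTRUE(all.equal(a$x, b$x)) && isTRUE(all.equal(a$z, b$z))
}

#' Sinogram container
#'
#' Channel-by-time pressure record of an optoacoustic acquisition, with the
#' sampling metadata required by the conditioning and reconstruction stages.
#'
#' @param data numeric matrix, one row per transducer element, one column per
#'   time sample (relative pressure units).
#' @param fs sampling rate (MHz).
#' @param wavelength illumination wavelength (nm).
#' @param pulse_ns laser pulse duration (ns).
#' @param sos speed of sound used for the time axis (mm/us).
#' @param x_elem element-centre lateral coordinates (mm).
#' @param meta named list of provenance metadata.
#' @return An object of class `oa_sinogram`.
#' @export
oa_sinogram <- function(data, fs, wavelength = NA_real_, pulse_ns = 0,
                        sos = 1.54, x_elem, meta = list()) {
  data <- as.matrix(data)
  if (!all(is.finite(data))) stop_oa("sinogram values must be finite")
  if (nrow(data) != length(x_elem))
    stop_oa("one row per element required")
  structure(list(data = data, fs = fs, wavelength = wavelength,
                 pulse_ns = pulse_ns, sos = sos,
                 x_elem = as.numeric(x_elem), meta = meta),
            class = "oa_sinogram")
}

#' @export
print.oa_sinogram <- function(x, ...) {
  cat(sprintf(
    "<oa_sinogram> %d elements x %d samples @ %g MHz, %s nm, sos %.3g mm/us\n",
    nrow(x$data), ncol(x$data), x$fs,
    ifelse(is.na(x$wavelength), "-", format(x$wavelength)), x$sos))
  invisible(x)
}

#' Time axis of a sinogram
#' @param sino an `oa_sinogram`.
#' @return sample times in microseconds, starting at 0.
#' @export
time_axis <- function(sino) (seq_len(ncol(sino$data)) - 1) / sino$fs

#' Write or read a package container
#'
#' Self-describing serialized container for sinograms, images, functional
#' maps and overlays: the object is stored with its class, grid metadata and
#' provenance intact, so every stage can be re-run from its input file alone.
#'
#' @param x object to store.
#' @param path file path (conventionally `.rds`).
#' @return `oa_write` returns `path` invisibly; `oa_read` returns the object.
#' @export
oa_write <- function(x, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  saveRDS(x, path)
  invisible(path)
}

#' @rdname oa_write
#' @export
oa_read <- function(path) readRDS(path)
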