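#' Segment the brightest objects on an image
#'
#' Marks pixels whose brightness exceeds a rowwise-robust level (per-depth
#' median plus `threshold_sigma` robust standard deviations) and closes the
#' mask morphologically, so that blood vessels and tumors are excluded from
#' the background statistics used for depth normalization.
#'
#' @param image an [oa_image()].
#' @param threshold_sigma threshold in robust standard deviations above the
#'   per-row median (default 3).
#' @param close_radius radius (pixels) of the disc brush used for
#'   morphological closing; 0 skips closing.
#' @return logical matrix of the same shape as the image.
#' @export
segment_bright <- function(image, threshold_sigma = 3, close_radius = 2) {
  d <- image$data
  med <- apply(d, 1, median)
  dev <- apply(d, 1, mad)
  # rows with no texture fall back to the global scale
  gdev <- mad(d)
  dev[dev <= 0] <- gdev
  mask <- d > med + threshold_sigma * dev
  mask[!is.finite(mask)] <- FALSE
  if (close_radius > 0 && any(mask)) {
    brush <- EBImage::makeBrush(2 * close_radius + 1, "disc")
    mask <- EBImage::closing(mask * 1, brush) > 0.5
  }
  mask
}

#' Depth normalization by the background row mean
#'
#' Divides each pixel by the average brightness of its horizontal row
#' (constant depth) computed over background pixels only (segmented bright
#' objects excluded), making the background brightness depth independent.
#' Rows that are fully masked, have too few background pixels, or a
#' nonpositive mean are filled by interpolation from neighbouring rows and
#' reported in the `interpolated_rows` attribute.
#'
#' @param image an [oa_image()].
#' @param mask logical matrix of excluded (bright-object) pixels, same
#'   shape; `NULL` uses all pixels.
#' @param scale multiplier applied after normalization; the pipeline passes
#'   the bulk background absorption so both wavelengths return to a common
#'   relative-mu_a scale before unmixing.
#' @param min_frac minimum fraction of unmasked pixels for a row mean to be
#'   trusted.
#' @param smooth odd width of a running-mean window over the row means
#'   (1 = no smoothing).
#' @param profile optional analytic background-brightness profile, one
#'   value per row (e.g. `mu_a_bg * F(z)`). When given it replaces the
#'   measured row means as the per-depth divisor; the pipeline uses this
#'   mode because a smooth homogeneous background reconstructs to nearly
#'   zero under band-limited tomography, leaving nothing to measure.
#' @return the normalized [oa_image()].
#' @export
normalize_depth <- function(image, mask = NULL, scale = 1, min_frac = 0.05,
                            smooth = 1, profile = NULL) {
  d <- image$data
  if (is.null(mask)) mask <- matrix(FALSE, nrow(d), ncol(d))
  if (!all(dim(mask) == dim(d))) stop_oa("mask shape must match the image")
  bad <- rep(FALSE, nrow(d))
  if (!is.null(profile)) {
    if (length(profile) != nrow(d))
      stop_oa("profile must have one value per image row")
    if (any(profile <= 0)) stop_oa("profile values must be positive")
    rm_ <- profile
  } else {
    keep <- !mask
    cnt <- rowSums(keep)
    rm_ <- rowSums(d * keep) / pmax(cnt, 1)
    bad <- cnt < min_frac * ncol(d) | rm_ <= 0
    rm_[bad] <- NA_real_
    if (all(is.na(rm_)))
      stop_oa("no usable background rows for normalization")
    if (anyNA(rm_)) {
      ok <- which(!is.na(rm_))
      rm_ <- approx(image$z[ok], rm_[ok], xout = image$z, rule = 2)$y
    }
    if (smooth > 1) {
      k <- (smooth - 1) %/% 2
      n <- length(rm_)
      padded <- c(rep(rm_[1], k), rm_, rep(rm_[n], k))
      rm_ <- vapply(seq_len(n), function(i) mean(padded[i:(i + 2 * k)]),
                    numeric(1))
    }
  }
  out <- image
  out$data <- d / rm_ * scale
  out$meta$depth_normalized <- TRUE
  attr(out, "interpolated_rows") <- which(bad)
  out
}

#' Functional maps container
#'
#' @param thb relative total hemoglobin map (matrix).
#' @param so2 oxygen saturation map (fraction, `NA` where undefined).
#' @param valid logical matrix: pixels where `so2` is defined.
#' @param x,z,spacing grid metadata shared with the source images.
#' @param wavelengths wavelength pair (nm) used for unmixing.
#' @param reference optional reference-region statistics (see
#'   [set_reference()]).
#' @return An object of class `oa_funcmaps`.
#' @export
functional_maps <- function(thb, so2, valid, x, z, spacing,
                            wavelengths, reference = NULL) {
  structure(list(thb = thb, so2 = so2, valid = valid, x = x, z = z,
                 spacing = spacing, wavelengths = wavelengths,
                 reference = reference),
            class = "oa_funcmaps")
}

#' @export
print.oa_funcmaps <- function(x, ...) {
  cat(sprintf("<oa_funcmaps> %d x %d px, wavelengths %s nm, %.1f%% valid sO2\n",
              nrow(x$thb), ncol(x$thb),
              paste(x$wavelengths, collapse = "/"),
              100 * mean(x$valid)))
  invisible(x)
}

#' Dual-wavelength spectral unmixing
#'
#' Pixelwise exact inversion of the two-chromophore system
#' `mu_a(lambda_i) = Hb eps_Hb(lambda_i) + HbO2 eps_HbO2(lambda_i)`:
#' total hemoglobin is `Hb + HbO2` and oxygen saturation the
#' oxyhemoglobin fraction `HbO2 / (Hb + HbO2)`. Inputs are the two
#' co-registered, depth-normalized images treated as proportional to
#' `mu_a` on a common relative scale. `so2` is clamped to \[0, 1\] and
#' marked undefined where `thb` falls below `thb_floor_frac` of the
#' 99th-percentile `thb` (the saturation ratio is unstable at low signal);
#' `thb` is clamped at zero after that floor is recorded.
#'
#' @param img1,img2 [oa_image()] objects at the two wavelengths (grids must
#'   match; wavelengths are read from the images).
#' @param table chromophore table.
#' @param thb_floor_frac validity floor as a fraction of the
#'   99th-percentile total hemoglobin.
#' @return An [functional_maps()] object.
#' @export
unmix <- function(img1, img2, table = chromophore_table(),
                  thb_floor_frac = 0.05) {
  if (!same_grid(img1, img2)) stop_oa("images are not co-registered")
  l1 <- img1$wavelength; l2 <- img2$wavelength
  eH1 <- extinction(table, l1, "Hb");  eO1 <- extinction(table, l1, "HbO2")
  eH2 <- extinction(table, l2, "Hb");  eO2 <- extinction(table, l2, "HbO2")
  D <- eH1 * eO2 - eH2 * eO1
  if (abs(D) < 1e-9 * max(abs(c(eH1 * eO2, eH2 * eO1))))
    stop_oa("extinction matrix is singular: wavelengths carry no contrast")
  m1 <- img1$data; m2 <- img2$data
  hb  <- (m1 * eO2 - m2 * eO1) / D
  hbo <- (m2 * eH1 - m1 * eH2) / D
  thb <- hb + hbo
  floor_ <- thb_floor_frac * quantile(thb, 0.99, names = FALSE)
  valid <- is.finite(thb) & thb >= max(floor_, 0)
  so2 <- hbo / thb
  so2[!valid] <- NA_real_
  so2 <- pmin(pmax(so2, 0), 1)
  fm <- functional_maps(pmax(thb, 0), so2, valid, img1$x, img1$z,
                        img1$spacing, c(l1, l2))
  # unclamped fields for ROI-level (ratio-of-means) statistics
  fm$thb_raw <- thb
  fm$hbo2_raw <- hbo
  fm
}

#' Statistical mapping against a reference region
#'
#' Offsets a map by the reference-region mean and scales it by the
#' reference-region standard deviation, so displayed values are in units of
#' background standard deviations.
#'
#' @param map numeric matrix (e.g. the `thb` or `so2` field of
#'   [functional_maps()]).
#' @param reference logical matrix selecting the reference region (same
#'   shape), nonempty with nonzero variance.
#' @return standardized matrix `(map - mean_ref) / sd_ref`.
#' @export
statistical_map <- function(map, reference) {
  if (!all(dim(reference) == dim(map))) stop_oa("reference shape mismatch")
  v <- map[reference]
  v <- v[is.finite(v)]
  if (length(v) < 2) stop_oa("reference region is empty")
  s <- sd(v)
  if (s == 0) stop_oa("reference region has zero variance")
  (map - mean(v)) / s
}

#' Default background reference region
#'
#' A band of background pixels between two depths, excluding segmented
#' bright objects.
#'
#' @param fmaps_or_image an [functional_maps()] or [oa_image()] providing
#'   grid axes.
#' @param mask logical matrix of bright-object pixels to exclude (or
#'   `NULL`).
#' @param depth_range depth band (mm), default 5-15 mm.
#' @return logical matrix selecting the reference region.
#' @export
reference_region <- function(fmaps_or_image, mask = NULL,
                             depth_range = c(5, 15)) {
  z <- fmaps_or_image$z; x <- fmaps_or_image$x
  ref <- matrix(z >= depth_range[1] & z <= depth_range[2],
                length(z), length(x))
  if (!is.null(mask)) ref <- ref & !mask
  ref
}

#' Attach reference statistics to functional maps
#'
#' @param fmaps an [functional_maps()].
#' @param reference logical reference-region matrix.
#' @return `fmaps` with per-map reference mean/sd stored in `$reference`.
#' @export
set_reference <- function(fmaps, reference) {
  stat <- function(m) {
    v <- m[reference]; v <- v[is.finite(v)]
    c(mean = mean(v), sd = sd(v))
  }
  fmaps$reference <- list(region = reference,
                          thb = stat(fmaps$thb), so2 = stat(fmaps$so2))
  fmaps
}
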