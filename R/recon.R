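#' Reconstruction grid
#'
#' @param x_range lateral range `c(min, max)` (mm).
#' @param z_range depth range `c(min, max)` (mm), within the 0-40 mm system
#'   design depth.
#' @param spacing pixel spacing (mm).
#' @param sos speed of sound used when sampling traces (mm/us).
#' @return An object of class `oa_grid`.
#' @export
recon_grid <- function(x_range = c(-19, 19), z_range = c(0, 38),
                       spacing = 0.15, sos = 1.54) {
  if (spacing <= 0) stop_oa("`spacing` must be > 0")
  if (z_range[1] < 0 || z_range[2] > 40)
    stop_oa("depth range must lie within [0, 40] mm")
  nx <- max(1L, round(diff(x_range) / spacing))
  nz <- max(1L, round(diff(z_range) / spacing))
  structure(list(x = x_range[1] + (seq_len(nx) - 0.5) * spacing,
                 z = z_range[1] + (seq_len(nz) - 0.5) * spacing,
                 spacing = spacing, sos = sos),
            class = "oa_grid")
}

#' Reconstruction grid matching a phantom raster
#'
#' @param phantom an `oa_phantom`.
#' @param sos speed of sound (mm/us); default the phantom's.
#' @return An `oa_grid` co-registered with the phantom grid.
#' @export
grid_from_phantom <- function(phantom, sos = phantom$acoustic$speed_of_sound) {
  e <- phantom$extent
  recon_grid(e[1:2], e[3:4], phantom$spacing, sos)
}

#' Back-projection data function
#'
#' The filtered trace `p(t) - t dp/dt` back-projected by the tomographic
#' inversion; the derivative term acts like the ramp filter in the
#' frequency domain. The derivative uses central differences (one-sided at
#' the ends).
#'
#' @param trace pressure trace (vector), uniformly sampled.
#' @param t sample times (us), same length as `trace`.
#' @return filtered trace, same length.
#' @export
data_function <- function(trace, t) {
  n <- length(trace)
  if (n < 3) stop_oa("trace must have at least 3 samples")
  if (length(t) != n) stop_oa("time axis length mismatch")
  dt <- t[2] - t[1]
  dp <- (trace[c(2:n, n)] - trace[c(1, 1:(n - 1))]) / (2 * dt)
  dp[1] <- (trace[2] - trace[1]) / dt
  dp[n] <- (trace[n] - trace[n - 1]) / dt
  trace - t * dp
}

#' Weighted filtered back-projection
#'
#' Reconstructs a 2D image from a conditioned sinogram: for each pixel the
#' data function of every element trace is sampled at the arrival time
#' `t = |rT - r| / c` (linear interpolation) and summed with the solid-angle
#' weight `R dOmega / Omega0`, where `dOmega` is the element aperture seen
#' from the pixel and `Omega0` the total aperture of the array at that
#' pixel (limited-view normalization). The three-dimensional weights are
#' applied in-plane. If the sinogram was tagged by [deconvolve_sir()] (or
#' `sir_correct = TRUE`), the regularized inverse element directivity is
#' applied per pixel-element pair. Pixels whose arrival time falls beyond
#' the trace receive no contribution from that element.
#'
#' @param sino an [oa_sinogram()].
#' @param grid an [recon_grid()]; its `sos` is used for the isochrones.
#' @param probe an `oa_probe`.
#' @param sir_correct apply inverse-directivity weighting; defaults to the
#'   sinogram's [deconvolve_sir()] tag.
#' @param sir_floor directivity regularization floor.
#' @return An [oa_image()] (linear in the sinogram data).
#' @export
backproject <- function(sino, grid, probe, sir_correct = NULL,
                        sir_floor = NULL) {
  sir <- sino$meta$sir
  if (is.null(sir_correct)) sir_correct <- isTRUE(sir$correct)
  if (is.null(sir_floor)) sir_floor <- sir$floor %||% 0.2
  t <- time_axis(sino)
  df <- t(apply(sino$data, 1, data_function, t = t))
  px <- rep(grid$x, each = length(grid$z))
  pz <- rep(grid$z, times = length(grid$x))
  dir_coef <- pi * probe$element_width * probe$sir_ref_MHz / grid$sos
  v <- backproject_cpp(df, sino$fs, grid$sos, sino$x_elem, px, pz,
                       dir_coef, isTRUE(sir_correct), sir_floor)
  oa_image(matrix(v, length(grid$z), length(grid$x)),
           grid$x, grid$z, grid$spacing, sino$wavelength,
           meta = c(sino$meta,
                    list(sos = grid$sos, sir_correct = isTRUE(sir_correct))))
}

fwhm_profile <- function(v, coord, peak_idx) {
  half <- v[peak_idx] / 2
  left <- NA_real_; right <- NA_real_
  i <- peak_idx
  while (i > 1 && v[i - 1] >= half) i <- i - 1
  if (i > 1) {
    f <- (v[i] - half) / (v[i] - v[i - 1])
    left <- coord[i] - f * (coord[i] - coord[i - 1])
  } else left <- coord[1]
  i <- peak_idx
  n <- length(v)
  while (i < n && v[i + 1] >= half) i <- i + 1
  if (i < n) {
    f <- (v[i] - half) / (v[i] - v[i + 1])
    right <- coord[i] + f * (coord[i + 1] - coord[i])
  } else right <- coord[n]
  right - left
}

#' Point-spread-function metrics
#'
#' Full width at half maximum along the depth (axial) and lateral axes
#' through the dominant peak of a reconstructed point-target image.
#'
#' @param image an [oa_image()].
#' @param peak optional expected peak location `c(x, z)` (mm); the maximum
#'   is searched within `radius` mm of it.
#' @param radius search radius around `peak` (mm).
#' @return list with `axial` and `lateral` FWHM (mm) and the peak location.
#' @export
psf_metrics <- function(image, peak = NULL, radius = 3) {
  d <- image$data
  cand <- matrix(TRUE, nrow(d), ncol(d))
  if (!is.null(peak)) {
    cand <- outer(abs(image$z - peak[2]) <= radius,
                  abs(image$x - peak[1]) <= radius, "&")
  }
  dm <- d; dm[!cand] <- -Inf
  idx <- arrayInd(which.max(dm), dim(d))
  pk <- d[idx]
  if (!is.finite(pk) || pk <= 0 || pk < max(d) / 2)
    stop_oa("no dominant peak above half-maximum at the stated location")
  list(axial = fwhm_profile(d[, idx[2]], image$z, idx[1]),
       lateral = fwhm_profile(d[idx[1], ], image$x, idx[2]),
       peak = c(x = image$x[idx[2]], z = image$z[idx[1]]))
}

#' Synthesize a grayscale B-mode-like background
#'
#' Deterministic speckle-textured grayscale raster co-registered with the
#' reconstruction grid, standing in for the anatomical ultrasound image in
#' overlay rendering: a fully developed multiplicative speckle field
#' (magnitude of a smoothed complex Gaussian) over an echogenicity map in
#' which inclusions are hypoechoic and an optional skin line is bright.
#'
#' @param phantom an `oa_phantom`.
#' @param grid an [recon_grid()].
#' @param seed RNG seed; the speckle field is reproducible bit-for-bit.
#' @param inclusion_echo relative echogenicity of inclusions (< 1:
#'   hypoechoic).
#' @return An [oa_image()] with values in \[0, ~3\] (relative echo
#'   amplitude).
#' @export
synthesize_bmode <- function(phantom, grid, seed = 1L, inclusion_echo = 0.3) {
  nz <- length(grid$z); nx <- length(grid$x)
  echo <- matrix(1, nz, nx)
  for (inc in phantom$inclusions)
    echo[inclusion_mask(inc, grid$x, grid$z)] <- inclusion_echo
  if (!is.null(phantom$skin_depth))
    echo[grid$z <= phantom$skin_depth, ] <- 1.6
  spk <- with_seed(seed, {
    re <- matrix(rnorm(nz * nx), nz, nx)
    im <- matrix(rnorm(nz * nx), nz, nx)
    sm <- function(m) {
      out <- m
      out[2:(nz - 1), 2:(nx - 1)] <-
        (m[1:(nz - 2), 1:(nx - 2)] + m[1:(nz - 2), 2:(nx - 1)] +
         m[1:(nz - 2), 3:nx] + m[2:(nz - 1), 1:(nx - 2)] +
         m[2:(nz - 1), 2:(nx - 1)] + m[2:(nz - 1), 3:nx] +
         m[3:nz, 1:(nx - 2)] + m[3:nz, 2:(nx - 1)] + m[3:nz, 3:nx]) / 9
      out
    }
    sqrt(sm(re)^2 + sm(im)^2)
  })
  oa_image(echo * spk, grid$x, grid$z, grid$spacing, NA_real_,
           meta = list(stage = "bmode", seed = seed))
}
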