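#' Per-channel calibration
#'
#' Gain factors and the list of bad (dead) elements to zero.
#'
#' @param gains per-element gain factors (relative); recycled if scalar.
#' @param bad integer indices of bad elements.
#' @param n_elements number of elements.
#' @return An object of class `oa_calibration`.
#' @export
channel_calibration <- function(gains = 1, bad = integer(), n_elements = 128) {
  gains <- rep_len(gains, n_elements)
  bad <- as.integer(bad)
  if (length(bad) && (min(bad) < 1 || max(bad) > n_elements))
    stop_oa("bad element indices out of range")
  live <- setdiff(seq_len(n_elements), bad)
  if (any(gains[live] <= 0)) stop_oa("gain <= 0 on a live channel")
  structure(list(gains = gains, bad = bad, n_elements = n_elements),
            class = "oa_calibration")
}

#' Compensate channel gains and zero bad elements
#'
#' Each live channel is divided by its gain factor; bad channels are set to
#' exactly zero.
#'
#' @param raw an [oa_sinogram()].
#' @param cal an [channel_calibration()] matching the element count.
#' @return the compensated sinogram.
#' @export
compensate_channels <- function(raw, cal) {
  if (cal$n_elements != nrow(raw$data))
    stop_oa("calibration length does not match element count")
  live <- setdiff(seq_len(cal$n_elements), cal$bad)
  if (any(cal$gains[live] <= 0)) stop_oa("gain <= 0 on a live channel")
  raw$data[live, ] <- raw$data[live, , drop = FALSE] / cal$gains[live]
  if (length(cal$bad)) raw$data[cal$bad, ] <- 0
  raw$meta$calibrated <- TRUE
  raw
}

#' Wiener deconvolution of the electro-acoustic impulse response
#'
#' Restores the intrinsic ultrasonic spectrum of the detected traces by
#' applying the per-channel frequency-domain Wiener inverse
#' `H* / (|H|^2 + nsr |H|^2_max)` of the probe EIR. In the noise-free limit
#' (`nsr -> 0`) deconvolution inverts convolution for in-band signals;
#' `nsr -> Inf` drives the output to zero.
#'
#' @param sino an [oa_sinogram()].
#' @param probe an `oa_probe` whose EIR was (or is assumed to have been)
#'   applied to the data.
#' @param nsr noise-to-signal power ratio, relative to the EIR peak power
#'   (nonnegative scalar), or `"auto"` for the full Wiener filter: the
#'   signal power spectrum is estimated from the channel-pooled data and
#'   the white-noise floor from the upper spectral tail, so frequencies
#'   where thermal noise dominates are suppressed rather than amplified.
#' @param psd_from optional sinogram (or list of sinograms) whose pooled
#'   data are used for the `"auto"` signal-spectrum estimate; the pipeline
#'   pools both wavelengths so that one common filter is applied to the
#'   frame pair and the dual-wavelength ratio is not biased by
#'   wavelength-dependent filtering.
#' @return the deconvolved sinogram.
#' @export
wiener_deconvolve_eir <- function(sino, probe, nsr = 1e-3,
                                  psd_from = NULL) {
  n <- ncol(sino$data)
  H <- eir_response(probe, sino$fs, n)
  pk <- max(H^2)
  if (pk <= 0) stop_oa("EIR response is identically zero")
  if (identical(nsr, "auto")) {
    src <- psd_from %||% sino
    if (inherits(src, "oa_sinogram")) src <- list(src)
    dat <- do.call(rbind, lapply(src, function(s) {
      if (ncol(s$data) != n) stop_oa("psd_from trace length mismatch")
      s$data
    }))
    S_y <- colMeans(Mod(t(apply(dat, 1, fft)))^2)
    k <- max(3L, n %/% 64)
    S_y <- stats::filter(c(S_y, S_y[seq_len(k)]), rep(1 / k, k),
                         circular = FALSE)[seq_len(n)]
    S_y[is.na(S_y)] <- S_y[which(!is.na(S_y))[1]]
    f <- abs(fft_freqs(n, sino$fs))
    tail_band <- f > 0.8 * sino$fs / 2
    N0 <- median(S_y[tail_band])
    S_x <- pmax(S_y - N0, 0.01 * N0) / pmax(H^2, 1e-6)
    nsr_f <- pmin(pmax(N0 / S_x, 1e-8), 1e8)
    W <- H / (H^2 + nsr_f)
  } else {
    if (!is.numeric(nsr) || nsr < 0) stop_oa("`nsr` must be >= 0 or \"auto\"")
    W <- H / (H^2 + nsr * pk)
  }
  sino$data <- t(apply(sino$data, 1, function(r)
    Re(fft(fft(r) * W, inverse = TRUE)) / n))
  sino$meta$eir_deconvolved <- list(nsr = nsr)
  sino
}

#' Bandpass filter specification
#'
#' @param low low cutoff (MHz); default 0.067 (67 kHz), with the 100 kHz
#'   artifact-suppression variant available by setting `low = 0.1`.
#' @param high high cutoff (MHz); default the 12 MHz transducer band edge.
#' @param order Butterworth order of each (high-/low-pass) section.
#' @return An object of class `oa_filterspec`.
#' @export
filter_spec <- function(low = 0.067, high = 12, order = 4) {
  if (low <= 0 || high <= low) stop_oa("need 0 < low < high")
  structure(list(low = low, high = high, order = order),
            class = "oa_filterspec")
}

#' Zero-phase bandpass filtering
#'
#' Forward-backward (zero-phase) Butterworth filtering of each channel,
#' applied as a cascade of a high-pass and a low-pass section for numerical
#' robustness at the very low 67 kHz corner. DC is removed; arrival times
#' of symmetric pulses are preserved.
#'
#' @param sino an [oa_sinogram()].
#' @param spec an [filter_spec()]; cutoffs must lie inside the Nyquist band.
#' @return the filtered sinogram.
#' @export
bandpass <- function(sino, spec = filter_spec()) {
  nyq <- sino$fs / 2
  if (spec$high > nyq || spec$low >= nyq)
    stop_oa("filter cutoffs must lie below the Nyquist frequency")
  hp <- signal::butter(spec$order, spec$low / nyq, type = "high")
  lp <- signal::butter(spec$order, spec$high / nyq, type = "low")
  # odd-reflection padding of several low-cutoff periods keeps the
  # forward-backward transient of the 67 kHz corner out of the trace
  npad <- min(ncol(sino$data) - 1L, ceiling(3 * sino$fs / spec$low))
  sino$data <- t(apply(sino$data, 1, function(r) {
    n <- length(r)
    head_pad <- 2 * r[1] - r[(npad + 1):2]
    tail_pad <- 2 * r[n] - r[(n - 1):(n - npad)]
    x <- c(head_pad, r, tail_pad)
    x <- signal::filtfilt(hp, x)
    if (spec$high < nyq) x <- signal::filtfilt(lp, x)
    x[(npad + 1):(npad + n)]
  }))
  sino$meta$bandpass <- list(low = spec$low, high = spec$high,
                             order = spec$order)
  sino
}

#' Regularized inverse directivity weight
#'
#' The spatial-impulse-response correction applied during back-projection:
#' the reciprocal of the forward element directivity, with the directivity
#' floored so the weight never exceeds `1 / floor`.
#'
#' @param sin_theta sine of the incidence angle.
#' @param probe an `oa_probe`.
#' @param sos speed of sound (mm/us).
#' @param floor directivity floor in (0, 1\].
#' @return weight `1 / max(directivity, floor)`.
#' @export
inverse_directivity_weight <- function(sin_theta, probe, sos = 1.54,
                                       floor = 0.2) {
  d <- element_directivity(sin_theta, probe, sos)
  1 / pmax(d, floor)
}

#' Request spatial-impulse-response correction
#'
#' The SIR correction acts in reconstruction coordinates (it widens the
#' effective angular directivity of each element), so it is implemented as
#' angle-dependent weighting inside [backproject()]. This helper tags a
#' conditioned sinogram so that the reconstruction applies the regularized
#' inverse directivity weighting.
#'
#' @param sino an [oa_sinogram()].
#' @param probe an `oa_probe`.
#' @param floor directivity regularization floor (see
#'   [inverse_directivity_weight()]).
#' @return the sinogram tagged for SIR correction.
#' @export
deconvolve_sir <- function(sino, probe, floor = 0.2) {
  if (floor <= 0 || floor > 1) stop_oa("`floor` must be in (0, 1]")
  sino$meta$sir <- list(correct = TRUE, floor = floor)
  sino
}
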