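#' Linear-array probe model
#'
#' Geometry and response model of the hand-held dual-modality probe: a
#' 128-element linear transducer array with an ultrawide-band
#' electro-acoustic impulse response (EIR, -6 dB band 0.1-12 MHz), a
#' far-field rectangular-element directivity (spatial impulse response,
#' SIR), and two rectangular illumination windows flanking the array.
#'
#' @param n_elements number of elements (128).
#' @param element_width element width (mm); must not exceed the pitch.
#' @param pitch element pitch (mm); the default gives a 40 mm aperture,
#'   matching the illumination window length.
#' @param eir_band -6 dB band edges of the EIR (MHz).
#' @param eir_order Butterworth magnitude order of each EIR skirt.
#' @param nep_Pa noise-equivalent pressure of one element (Pa).
#' @param illum illumination description: window `length` and `width` (mm),
#'   `edge` profile (`"sharp"` or `"gaussian"`) and edge `sigma` (mm).
#' @param sir_ref_MHz reference frequency at which the scalar directivity
#'   weight is evaluated.
#' @return An object of class `oa_probe`.
#' @export
probe_model <- function(n_elements = 128, element_width = 0.25,
                        pitch = 40 / 128, eir_band = c(0.1, 12),
                        eir_order = 2, nep_Pa = 1.3,
                        illum = list(length = 40, width = 6,
                                     edge = "sharp", sigma = 2),
                        sir_ref_MHz = 6) {
  if (element_width > pitch) stop_oa("element_width must be <= pitch")
  if (eir_band[1] <= 0 || eir_band[2] <= eir_band[1])
    stop_oa("eir_band must be increasing and positive")
  x <- (seq_len(n_elements) - (n_elements + 1) / 2) * pitch
  structure(list(n_elements = n_elements, element_width = element_width,
                 pitch = pitch, x = x, aperture = n_elements * pitch,
                 eir_band = eir_band, eir_order = eir_order,
                 nep_Pa = nep_Pa, illum = illum, sir_ref_MHz = sir_ref_MHz),
            class = "oa_probe")
}

#' @export
print.oa_probe <- function(x, ...) {
  cat(sprintf("<oa_probe> %d elements, pitch %.4g mm (aperture %.1f mm), EIR %g-%g MHz\n",
              x$n_elements, x$pitch, x$aperture, x$eir_band[1], x$eir_band[2]))
  invisible(x)
}

fft_freqs <- function(n, fs) {
  k <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1)
  if (n == 1) k <- 0
  k * fs / n
}

#' Electro-acoustic frequency response of the probe
#'
#' Zero-phase (real, nonnegative) EIR magnitude evaluated on the FFT
#' frequency grid of an `n`-sample trace at rate `fs`. The band-pass
#' magnitude is a product of Butterworth high- and low-pass skirts whose
#' corner frequencies are placed so that the response crosses -6 dB
#' (factor 0.5) exactly at the nominal band edges.
#'
#' @param probe an `oa_probe`.
#' @param fs sampling rate (MHz).
#' @param n trace length (samples).
#' @return real vector of length `n`: `|H(f)|` on the FFT grid.
#' @export
eir_response <- function(probe, fs, n) {
  f <- abs(fft_freqs(n, fs))
  m <- probe$eir_order
  # |H| = 0.5 at the printed -6 dB edges
  fc_lo <- probe$eir_band[1] * 3^(1 / (2 * m))
  fc_hi <- probe$eir_band[2] / 3^(1 / (2 * m))
  hp <- sqrt((f / fc_lo)^(2 * m) / (1 + (f / fc_lo)^(2 * m)))
  lp <- sqrt(1 / (1 + (f / fc_hi)^(2 * m)))
  hp * lp
}

#' Laser-pulse spectral factor
#'
#' Spectrum magnitude of a rectangular laser pulse of the given duration on
#' the FFT grid, normalized to 1 at DC. Longer pulses low-pass the source
#' term, so the 50 ns source yields a broader point-spread function than
#' the 15 ns source.
#'
#' @param pulse_ns pulse duration (ns); 0 returns all ones.
#' @param fs sampling rate (MHz).
#' @param n trace length.
#' @return real vector of length `n`.
#' @export
pulse_response <- function(pulse_ns, fs, n) {
  if (pulse_ns <= 0) return(rep(1, n))
  f <- abs(fft_freqs(n, fs))
  x <- pi * f * pulse_ns * 1e-3  # MHz * us
  ifelse(x < 1e-12, 1, sin(x) / x)
}

#' Default laser pulse duration per wavelength
#'
#' 50 ns for the 757 nm (Alexandrite) source and 15 ns for the 1064 nm
#' (Nd:YAG) source.
#'
#' @param wavelength wavelength (nm).
#' @return pulse duration (ns).
#' @export
laser_pulse_ns <- function(wavelength) {
  if (isTRUE(wavelength == 757)) 50
  else if (isTRUE(wavelength == 1064)) 15
  else 20
}

#' Apply the detection system response to traces
#'
#' Zero-phase convolution (frequency-domain product) of each row of `x`
#' with the probe EIR and, optionally, the rectangular laser-pulse factor.
#'
#' @param x numeric matrix (channels x samples) or vector.
#' @param probe an `oa_probe`.
#' @param fs sampling rate (MHz).
#' @param pulse_ns laser pulse duration (ns), default 0 (EIR only).
#' @return filtered traces, same shape as `x`.
#' @export
apply_system_response <- function(x, probe, fs, pulse_ns = 0) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, 1)
  n <- ncol(x)
  H <- eir_response(probe, fs, n) * pulse_response(pulse_ns, fs, n)
  out <- t(apply(x, 1, function(r) Re(fft(fft(r) * H, inverse = TRUE)) / n))
  if (vec) out <- drop(out)
  out
}

#' Far-field element directivity
#'
#' Scalar in-plane directivity of a flat rectangular element of width `w`
#' at the reference frequency: `sinc(w f sin(theta) / c)`. This is the
#' forward SIR weight; its regularized inverse is applied during
#' reconstruction (see [inverse_directivity_weight()]).
#'
#' @param sin_theta sine of the incidence angle from the element normal.
#' @param probe an `oa_probe`.
#' @param sos speed of sound (mm/us).
#' @param f evaluation frequency (MHz); defaults to `probe$sir_ref_MHz`.
#' @return directivity in (0, 1].
#' @export
element_directivity <- function(sin_theta, probe, sos = 1.54,
                                f = probe$sir_ref_MHz) {
  x <- pi * probe$element_width * f * abs(sin_theta) / sos
  ifelse(x < 1e-9, 1, sin(x) / x)
}
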