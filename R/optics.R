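#' Optical properties
#'
#' Per-wavelength absorption and reduced scattering plus the (relative)
#' Grueneisen thermoacoustic efficiency. The Grueneisen parameter is treated
#' as constant across a scene, so images and pressures are on a relative
#' brightness scale.
#'
#' @param wavelengths wavelengths (nm) the coefficients refer to.
#' @param mu_a absorption coefficients (cm^-1), one per wavelength.
#' @param mu_sp reduced scattering coefficients (cm^-1), one per wavelength.
#' @param grueneisen relative thermoacoustic efficiency (default 1).
#' @return An object of class `oa_optics`.
#' @export
optical_properties <- function(wavelengths, mu_a, mu_sp, grueneisen = 1) {
  if (length(mu_a) != length(wavelengths) || length(mu_sp) != length(wavelengths))
    stop_oa("mu_a and mu_sp must have one value per wavelength")
  if (any(mu_a < 0) || any(mu_sp < 0) || grueneisen < 0)
    stop_oa("optical properties must be nonnegative")
  structure(list(wavelengths = wavelengths, mu_a = mu_a, mu_sp = mu_sp,
                 grueneisen = grueneisen),
            class = "oa_optics")
}

optics_at <- function(opt, wavelength) {
  i <- match(wavelength, opt$wavelengths)
  if (is.na(i))
    stop_oa(sprintf("no optical properties at %s nm", format(wavelength)))
  list(mu_a = opt$mu_a[i], mu_sp = opt$mu_sp[i], grueneisen = opt$grueneisen)
}

#' Acoustic properties
#'
#' @param speed_of_sound speed of sound (mm/us), default 1.54 (soft tissue).
#' @param alpha_us amplitude attenuation coefficient in dB cm^-1 MHz^-1.5,
#'   default 0.32 (average breast, 70/30 fat/fibroglandular mix).
#' @return An object of class `oa_acoustics`.
#' @export
acoustic_properties <- function(speed_of_sound = 1.54, alpha_us = 0.32) {
  if (speed_of_sound <= 0) stop_oa("speed_of_sound must be > 0")
  if (alpha_us < 0) stop_oa("alpha_us must be >= 0")
  structure(list(speed_of_sound = speed_of_sound, alpha_us = alpha_us),
            class = "oa_acoustics")
}

#' Average breast background optical properties
#'
#' Bulk optical properties of average breast tissue at the two system
#' wavelengths: absorption 0.039 cm^-1 at 757 nm and 0.122 cm^-1 at
#' 1064 nm; reduced scattering taken as the midpoints of the reported
#' ranges, 9.0 cm^-1 at 757 nm and 4.0 cm^-1 at 1064 nm. No interpolation
#' to other wavelengths is attempted.
#'
#' @param wavelength 757 or 1064 (nm).
#' @return An [optical_properties()] object for the single wavelength.
#' @export
breast_background <- function(wavelength) {
  tab <- list(`757`  = c(mu_a = 0.039, mu_sp = 9.0),
              `1064` = c(mu_a = 0.122, mu_sp = 4.0))
  v <- tab[[as.character(wavelength)]]
  if (is.null(v))
    stop_oa("breast background properties are defined at 757 and 1064 nm only")
  optical_properties(wavelength, v[["mu_a"]], v[["mu_sp"]])
}

#' Default malignant-tumor optical properties
#'
#' Mean bulk absorption of cancerous breast tumors: 0.130 cm^-1 at 757 nm
#' (2- to 3-fold above background) and 0.154 cm^-1 at 1064 nm; scattering
#' as the breast background.
#'
#' @return An [optical_properties()] object at 757 and 1064 nm.
#' @export
tumor_optics <- function() {
  optical_properties(c(757, 1064), mu_a = c(0.130, 0.154), mu_sp = c(9.0, 4.0))
}
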