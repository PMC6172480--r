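#' Scene inclusion
#'
#' A geometric inclusion in a digital phantom: a tube (circular
#' cross-section), sphere, or ellipse, filled either with blood (so that its
#' optical absorption follows the hemoglobin spectrum) or with explicit
#' optical properties.
#'
#' @param shape `"tube"`, `"sphere"` or `"ellipse"`.
#' @param center inclusion centre `c(x, z)` in mm (z is depth).
#' @param size diameter in mm (scalar), or `c(width, height)` diameters for
#'   an ellipse.
#' @param blood an [blood_state()] for blood-filled inclusions.
#' @param optics an [optical_properties()] for explicitly specified ones.
#' @return An object of class `oa_inclusion`.
#' @export
inclusion <- function(shape = c("tube", "sphere", "ellipse"), center, size,
                      blood = NULL, optics = NULL) {
  shape <- match.arg(shape)
  if (length(center) != 2) stop_oa("`center` must be c(x, z)")
  if (shape == "ellipse" && length(size) == 1) size <- c(size, size)
  if (any(size <= 0)) stop_oa("`size` must be positive")
  if (is.null(blood) == is.null(optics))
    stop_oa("give exactly one of `blood` or `optics`")
  structure(list(shape = shape, center = as.numeric(center),
                 size = as.numeric(size), blood = blood, optics = optics),
            class = "oa_inclusion")
}

#' Digital phantom
#'
#' A voxelized 2D scene: a homogeneous background medium plus a list of
#' inclusions, on the standard 38 x 38 mm display grid. The background
#' medium is `"breast"` (average breast-tissue optics, soft-tissue
#' acoustics), `"aqueous"` (a scattering emulsion matched to average breast
#' optics in a water bath: water speed of sound and negligible acoustic
#' attenuation), or an explicit [optical_properties()] object.
#'
#' @param extent `c(x_min, x_max, z_min, z_max)` in mm.
#' @param spacing pixel spacing (mm); the default 0.15 mm sits below the
#'   system axial resolution so discretization does not dominate the PSF.
#' @param medium `"breast"`, `"aqueous"` or an [optical_properties()].
#' @param acoustic an [acoustic_properties()]; defaults depend on `medium`.
#' @param inclusions list of [inclusion()] objects; all must lie inside the
#'   grid.
#' @param skin_depth optional skin-layer thickness (mm) used by the
#'   beam-edge artifact model and the B-mode synthesizer.
#' @return An object of class `oa_phantom`.
#' @export
digital_phantom <- function(extent = c(-19, 19, 0, 38), spacing = 0.15,
                            medium = "breast", acoustic = NULL,
                            inclusions = list(), skin_depth = NULL) {
  if (length(extent) != 4 || extent[2] <= extent[1] || extent[4] <= extent[3])
    stop_oa("`extent` must be c(x_min, x_max, z_min, z_max) with positive spans")
  assert_scalar_num(spacing, "spacing")
  if (spacing <= 0) stop_oa("`spacing` must be > 0")
  if (is.character(medium)) {
    medium <- match.arg(medium, c("breast", "aqueous"))
  } else if (!inherits(medium, "oa_optics")) {
    stop_oa("`medium` must be \"breast\", \"aqueous\" or optical_properties()")
  }
  if (is.null(acoustic)) {
    acoustic <- if (identical(medium, "aqueous"))
      acoustic_properties(speed_of_sound = 1.49, alpha_us = 0)
    else acoustic_properties()
  }
  ph <- structure(list(extent = as.numeric(extent), spacing = spacing,
                       medium = medium, acoustic = acoustic,
                       inclusions = inclusions, skin_depth = skin_depth),
                  class = "oa_phantom")
  for (inc in inclusions) check_inside(ph, inc)
  ph
}

check_inside <- function(phantom, inc) {
  rx <- if (length(inc$size) == 2) inc$size[1] / 2 else inc$size / 2
  rz <- if (length(inc$size) == 2) inc$size[2] / 2 else inc$size / 2
  e <- phantom$extent
  ok <- inc$center[1] - rx >= e[1] && inc$center[1] + rx <= e[2] &&
        inc$center[2] - rz >= e[3] && inc$center[2] + rz <= e[4]
  if (!ok)
    stop_oa(sprintf("inclusion at (%.1f, %.1f) mm does not fit in the grid",
                    inc$center[1], inc$center[2]))
  invisible(TRUE)
}

#' @export
print.oa_phantom <- function(x, ...) {
  med <- if (is.character(x$medium)) x$medium else "explicit optics"
  cat(sprintf("<oa_phantom> %s background, %.0f x %.0f mm @ %.3g mm, %d inclusion(s)\n",
              med, diff(x$extent[1:2]), diff(x$extent[3:4]), x$spacing,
              length(x$inclusions)))
  invisible(x)
}

#' Background optical properties of a phantom at one wavelength
#'
#' @param phantom an `oa_phantom`.
#' @param wavelength wavelength (nm).
#' @return list with `mu_a`, `mu_sp` (cm^-1) and `grueneisen`.
#' @export
background_optics <- function(phantom, wavelength) {
  if (is.character(phantom$medium)) {
    # the aqueous bath is index-matched to average breast optics
    optics_at(breast_background(wavelength), wavelength)
  } else {
    optics_at(phantom$medium, wavelength)
  }
}

phantom_axes <- function(phantom) {
  e <- phantom$extent; h <- phantom$spacing
  nx <- max(1L, round(diff(e[1:2]) / h))
  nz <- max(1L, round(diff(e[3:4]) / h))
  list(x = e[1] + (seq_len(nx) - 0.5) * h,
       z = e[3] + (seq_len(nz) - 0.5) * h)
}

inclusion_mask <- function(inc, x, z) {
  sx <- if (length(inc$size) == 2) inc$size[1] else inc$size
  sz <- if (length(inc$size) == 2) inc$size[2] else inc$size
  xn <- (x - inc$center[1]) / (sx / 2)
  zn <- (z - inc$center[2]) / (sz / 2)
  outer(zn^2, xn^2, "+") <= 1
}

inclusion_mu_a <- function(inc, wavelength, phantom, table) {
  if (!is.null(inc$blood)) {
    # blood_mu_a is on the relative extinction scale; the raster carries
    # physical cm^-1, so apply the table's whole-blood conversion factor
    k <- attr(table, "mu_a_per_extinction") %||% 1
    k * blood_mu_a(inc$blood, wavelength, table)
  } else {
    optics_at(inc$optics, wavelength)$mu_a
  }
}

#' Rasterize a phantom at one wavelength
#'
#' @param phantom an `oa_phantom`.
#' @param wavelength wavelength (nm).
#' @param table chromophore table used for blood-filled inclusions.
#' @return list with the `mu_a` raster (cm^-1, depth x lateral), the scene
#'   `grueneisen` value, per-inclusion logical `masks`, and the grid axes.
#' @export
rasterize_phantom <- function(phantom, wavelength, table = chromophore_table()) {
  ax <- phantom_axes(phantom)
  bg <- background_optics(phantom, wavelength)
  mu <- matrix(bg$mu_a, length(ax$z), length(ax$x))
  masks <- vector("list", length(phantom$inclusions))
  for (i in seq_along(phantom$inclusions)) {
    inc <- phantom$inclusions[[i]]
    m <- inclusion_mask(inc, ax$x, ax$z)
    mu[m] <- inclusion_mu_a(inc, wavelength, phantom, table)
    masks[[i]] <- m
  }
  list(mu_a = mu, grueneisen = bg$grueneisen, masks = masks,
       x = ax$x, z = ax$z, spacing = phantom$spacing)
}

#' Two-tube validation phantom
#'
#' Two blood-filled tubes with circular cross-section at a common depth,
#' laterally symmetric about the array centre -- the layout of the
#' flowing-blood validation scenes (2.4 mm tubes at 10 or 20 mm in the
#' breast-mimicking medium; 1.5 mm tubes at 13-32 mm in the aqueous bath).
#'
#' @param depth tube-centre depth (mm), in \[5, 35\].
#' @param diameter tube diameter (mm).
#' @param so2_left,so2_right oxygen saturation fraction of each tube.
#' @param hematocrit blood hematocrit fraction (both tubes).
#' @param medium `"breast"` or `"aqueous"` (see [digital_phantom()]).
#' @param separation centre-to-centre lateral distance (mm); must exceed
#'   `diameter` or the tubes would overlap.
#' @param spacing,extent grid parameters, see [digital_phantom()].
#' @return An `oa_phantom` with two tube inclusions (left first).
#' @export
make_two_tube_phantom <- function(depth = 10, diameter = 2.4,
                                  so2_left = 1.0, so2_right = 0.5,
                                  hematocrit = 0.27, medium = "breast",
                                  separation = 10, spacing = 0.15,
                                  extent = c(-19, 19, 0, 38)) {
  if (depth < 5 || depth > 35) stop_oa("`depth` must be in [5, 35] mm")
  if (separation <= diameter) stop_oa("tubes overlap: separation <= diameter")
  tubes <- list(
    inclusion("tube", c(-separation / 2, depth), diameter,
              blood = blood_state(so2_left, hematocrit)),
    inclusion("tube", c(separation / 2, depth), diameter,
              blood = blood_state(so2_right, hematocrit)))
  digital_phantom(extent = extent, spacing = spacing, medium = medium,
                  inclusions = tubes)
}

#' Tumor phantom
#'
#' A single elliptical tumor-like inclusion in average breast background.
#' By default the inclusion carries the mean reported tumor absorption
#' (0.130 cm^-1 at 757 nm, 0.154 cm^-1 at 1064 nm); alternatively a
#' fold-contrast over the background can be requested (`contrast_fold = 1`
#' reproduces the background exactly).
#'
#' @param size tumor lateral diameter (mm), in \[3, 20\].
#' @param depth tumor-centre depth (mm).
#' @param contrast_fold optional absorption fold-change over background at
#'   both wavelengths; `NULL` uses the reported tumor means.
#' @param aspect depth/lateral diameter ratio of the ellipse.
#' @param spacing,extent grid parameters.
#' @return An `oa_phantom` with one ellipse inclusion.
#' @export
make_tumor_phantom <- function(size = 10, depth = 20, contrast_fold = NULL,
                               aspect = 0.75, spacing = 0.15,
                               extent = c(-19, 19, 0, 38)) {
  if (size < 3 || size > 20) stop_oa("`size` must be in [3, 20] mm")
  opt <- if (is.null(contrast_fold)) {
    tumor_optics()
  } else {
    assert_scalar_num(contrast_fold, "contrast_fold", lo = 0)
    optical_properties(c(757, 1064),
                       mu_a = contrast_fold * c(0.039, 0.122),
                       mu_sp = c(9.0, 4.0))
  }
  digital_phantom(extent = extent, spacing = spacing, medium = "breast",
                  inclusions = list(
                    inclusion("ellipse", c(0, depth), c(size, aspect * size),
                              optics = opt)))
}

# ---- scene files ----------------------------------------------------------

optics_to_list <- function(o) {
  list(wavelengths = o$wavelengths, mu_a = o$mu_a, mu_sp = o$mu_sp,
       grueneisen = o$grueneisen)
}

optics_from_list <- function(l) {
  optical_properties(unlist(l$wavelengths), unlist(l$mu_a), unlist(l$mu_sp),
                     l$grueneisen %||% 1)
}

#' Write or read a phantom scene file
#'
#' Scenes are stored as YAML with units of mm (geometry) and cm^-1
#' (optics). A phantom round-trips through write/read bit-identically.
#'
#' @param phantom an `oa_phantom`.
#' @param path file path (`.yaml`).
#' @return `write_scene` returns `path` invisibly; `read_scene` the phantom.
#' @export
write_scene <- function(phantom, path) {
  incs <- lapply(phantom$inclusions, function(inc) {
    out <- list(shape = inc$shape, center = inc$center, size = inc$size)
    if (!is.null(inc$blood))
      out$blood <- list(so2 = inc$blood$so2, hematocrit = inc$blood$hematocrit)
    if (!is.null(inc$optics)) out$optics <- optics_to_list(inc$optics)
    out
  })
  scene <- list(
    units = list(geometry = "mm", optics = "cm^-1"),
    extent = phantom$extent, spacing = phantom$spacing,
    medium = if (is.character(phantom$medium)) phantom$medium
             else optics_to_list(phantom$medium),
    acoustic = list(speed_of_sound = phantom$acoustic$speed_of_sound,
                    alpha_us = phantom$acoustic$alpha_us),
    skin_depth = phantom$skin_depth,
    inclusions = incs)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(scene, path, precision = 15)
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  s <- yaml::read_yaml(path)
  incs <- lapply(s$inclusions, function(l) {
    inclusion(l$shape, unlist(l$center), unlist(l$size),
              blood = if (!is.null(l$blood))
                blood_state(l$blood$so2, l$blood$hematocrit),
              optics = if (!is.null(l$optics)) optics_from_list(l$optics))
  })
  medium <- if (is.character(s$medium)) s$medium else optics_from_list(s$medium)
  digital_phantom(extent = unlist(s$extent), spacing = s$spacing,
                  medium = medium,
                  acoustic = acoustic_properties(s$acoustic$speed_of_sound,
                                                 s$acoustic$alpha_us),
                  inclusions = incs, skin_depth = s$skin_depth)
}
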