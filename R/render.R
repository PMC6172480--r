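#' Display palette specification
#'
#' Anchors of the functional RGBA palette: oxygen saturation below the
#' normally-oxygenated level (85%) renders red, grading to magenta at
#' extreme hypoxia; the band from 85% to 90% is transparent so the
#' grayscale anatomy shows through; values above 90% render green, grading
#' to cyan at the arterial extreme. Total hemoglobin uses a yellow palette
#' in which only the highest relative values are colored.
#'
#' @param red_boundary red/transparent boundary (% sO2), default 85.
#' @param green_boundary transparent/green boundary (% sO2), default 90.
#' @param magenta_below sO2 (%) below which red grades to magenta
#'   (extreme hypoxia; convention, default 40).
#' @param cyan_above sO2 (%) above which green grades to cyan (arterial;
#'   convention, default 98).
#' @param thb_percentile display threshold for the yellow tHb layer
#'   (percentile of in-image tHb), default 90.
#' @param fade_pct width (% sO2) of the piecewise-linear opacity ramps on
#'   either side of the transparent band.
#' @return An object of class `oa_palette`.
#' @export
palette_spec <- function(red_boundary = 85, green_boundary = 90,
                         magenta_below = 40, cyan_above = 98,
                         thb_percentile = 90, fade_pct = 3) {
  if (!(0 < red_boundary && red_boundary < green_boundary &&
        green_boundary < 100))
    stop_oa("need 0 < red_boundary < green_boundary < 100")
  structure(list(red_boundary = red_boundary,
                 green_boundary = green_boundary,
                 magenta_below = magenta_below, cyan_above = cyan_above,
                 thb_percentile = thb_percentile, fade_pct = fade_pct),
            class = "oa_palette")
}

#' Classify an sO2 value into its display color
#'
#' Values below the red boundary render red (magenta at extreme hypoxia);
#' the closed band from the red boundary to the green boundary is
#' transparent; values strictly above the green boundary render green
#' (cyan at the arterial extreme). The class ordering
#' magenta < red < transparent < green < cyan is monotone in sO2.
#'
#' @param value sO2 in percent, in \[0, 100\] (vectorized).
#' @param palette an [palette_spec()].
#' @return character vector of classes.
#' @export
classify_so2 <- function(value, palette = palette_spec()) {
  if (any(!is.finite(value)) || any(value < 0) || any(value > 100))
    stop_oa("sO2 values must lie in [0, 100] percent")
  out <- character(length(value))
  out[value < palette$red_boundary] <- "red"
  out[value < palette$magenta_below] <- "magenta"
  out[value >= palette$red_boundary & value <= palette$green_boundary] <-
    "transparent"
  out[value > palette$green_boundary] <- "green"
  out[value > palette$cyan_above] <- "cyan"
  out
}

so2_rgba <- function(pct, palette) {
  cls <- classify_so2(pct, palette)
  fade <- palette$fade_pct
  alpha <- numeric(length(pct))
  lo <- cls %in% c("red", "magenta")
  hi <- cls %in% c("green", "cyan")
  alpha[lo] <- pmin(1, (palette$red_boundary - pct[lo]) / fade)
  alpha[hi] <- pmin(1, (pct[hi] - palette$green_boundary) / fade)
  r <- as.numeric(lo)
  g <- as.numeric(hi)
  b <- as.numeric(cls == "magenta" | cls == "cyan")
  cbind(r = r, g = g, b = b, a = alpha)
}

#' Render the sO2 RGBA layer
#'
#' @param fmaps an [functional_maps()] (the `so2` field, a fraction, is
#'   displayed in percent); pixels with undefined sO2 are transparent.
#' @param palette an [palette_spec()].
#' @return an `nz x nx x 4` RGBA array in \[0, 1\].
#' @export
render_so2 <- function(fmaps, palette = palette_spec()) {
  so2 <- fmaps$so2
  pct <- as.vector(so2) * 100
  ok <- is.finite(pct)
  rgba <- matrix(0, length(pct), 4)
  if (any(ok)) rgba[ok, ] <- so2_rgba(pct[ok], palette)
  array(rgba, dim = c(nrow(so2), ncol(so2), 4))
}

#' Render the tHb RGBA layer
#'
#' Yellow coloring of the highest relative total-hemoglobin values: pixels
#' strictly above the display-threshold percentile get opacity ramping
#' linearly from 0 at the threshold to 1 at the in-image maximum; all other
#' pixels (including a uniform map, which has no "highest" values) are
#' fully transparent.
#'
#' @param fmaps an [functional_maps()] or a plain tHb matrix.
#' @param palette an [palette_spec()].
#' @return an `nz x nx x 4` RGBA array.
#' @export
render_thb <- function(fmaps, palette = palette_spec()) {
  thb <- if (inherits(fmaps, "oa_funcmaps")) fmaps$thb else fmaps
  thr <- quantile(thb, palette$thb_percentile / 100, names = FALSE)
  mx <- max(thb)
  alpha <- matrix(0, nrow(thb), ncol(thb))
  if (mx > thr) {
    sel <- thb > thr
    alpha[sel] <- (thb[sel] - thr) / (mx - thr)
  }
  out <- array(0, dim = c(nrow(thb), ncol(thb), 4))
  out[, , 1] <- as.numeric(alpha > 0)   # yellow = red + green
  out[, , 2] <- as.numeric(alpha > 0)
  out[, , 4] <- alpha
  out
}

#' Composite functional layers over the grayscale background
#'
#' Standard alpha-over compositing of the chosen functional layer(s) on
#' the grayscale anatomical image. In `"combined"` mode the sO2 colors are
#' shown only at pixels that are colored on the tHb layer. Wherever the
#' functional alpha is zero the background gray value is preserved
#' bit-exactly.
#'
#' @param bmode grayscale background [oa_image()].
#' @param so2_layer RGBA array from [render_so2()] (or `NULL`).
#' @param thb_layer RGBA array from [render_thb()] (or `NULL`).
#' @param mode `"so2"`, `"thb"` or `"combined"`.
#' @return An object of class `oa_overlay`: RGB array, the grayscale
#'   raster, and shared grid metadata.
#' @export
compose_overlay <- function(bmode, so2_layer = NULL, thb_layer = NULL,
                            mode = c("so2", "thb", "combined")) {
  mode <- match.arg(mode)
  gray <- bmode$data
  mx <- max(gray)
  if (mx > 0) gray <- gray / mx
  dims <- dim(gray)
  check_layer <- function(l, nm) {
    if (!is.null(l) && !all(dim(l)[1:2] == dims))
      stop_oa(sprintf("%s layer grid does not match the background", nm))
  }
  check_layer(so2_layer, "so2"); check_layer(thb_layer, "thb")
  layer <- switch(mode,
    so2 = so2_layer %||% stop_oa("so2 layer required"),
    thb = thb_layer %||% stop_oa("thb layer required"),
    combined = {
      if (is.null(so2_layer) || is.null(thb_layer))
        stop_oa("combined mode needs both layers")
      l <- so2_layer
      l[, , 4] <- l[, , 4] * as.numeric(thb_layer[, , 4] > 0)
      l
    })
  a <- layer[, , 4]
  rgb <- array(0, dim = c(dims, 3))
  for (ch in 1:3) rgb[, , ch] <- a * layer[, , ch] + (1 - a) * gray
  structure(list(rgb = rgb, alpha = a, gray = gray,
                 x = bmode$x, z = bmode$z, spacing = bmode$spacing,
                 mode = mode),
            class = "oa_overlay")
}

#' Write an overlay (or grayscale image) to PNG
#'
#' @param x an `oa_overlay` or [oa_image()].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_overlay_png <- function(x, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  img <- if (inherits(x, "oa_overlay")) {
    x$rgb
  } else {
    g <- x$data
    if (max(g) > 0) g <- g / max(g)
    pmin(pmax(g, 0), 1)
  }
  png::writePNG(img, path)
  invisible(path)
}

#' Pair alternating dual-wavelength frames
#'
#' Groups a tagged frame stream into short/long wavelength pairs: a 757 nm
#' frame followed by a 1064 nm frame within the inter-pulse delay tolerance
#' forms one functional frame pair. Unpaired frames are dropped (with a
#' message); two consecutive same-wavelength frames trigger a warning and
#' resynchronization.
#'
#' @param frames data.frame with columns `wavelength` (nm) and `t_ms`
#'   (timestamp, ms), in acquisition order; extra columns are carried
#'   through.
#' @param delay_ms nominal inter-pulse delay (ms), default 5.
#' @param tol_ms tolerance on the pair delay (ms).
#' @return data.frame of pairs with columns `t_short`, `t_long` and the row
#'   indices `i_short`, `i_long`; dropped frame indices in the `dropped`
#'   attribute.
#' @export
pair_frames <- function(frames, delay_ms = 5, tol_ms = 2.5) {
  pairs <- list()
  dropped <- integer()
  i <- 1L
  n <- nrow(frames)
  while (i <= n) {
    if (frames$wavelength[i] != 757) {
      dropped <- c(dropped, i); i <- i + 1L; next
    }
    if (i == n) { dropped <- c(dropped, i); break }
    j <- i + 1L
    if (frames$wavelength[j] == frames$wavelength[i]) {
      warning("two consecutive same-wavelength frames; resynchronizing",
              call. = FALSE)
      dropped <- c(dropped, i); i <- j; next
    }
    dt <- frames$t_ms[j] - frames$t_ms[i]
    if (frames$wavelength[j] == 1064 && abs(dt - delay_ms) <= tol_ms) {
      pairs[[length(pairs) + 1L]] <-
        data.frame(t_short = frames$t_ms[i], t_long = frames$t_ms[j],
                   i_short = i, i_long = j)
      i <- j + 1L
    } else {
      dropped <- c(dropped, i); i <- j
    }
  }
  out <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(t_short = numeric(), t_long = numeric(),
               i_short = integer(), i_long = integer())
  if (length(dropped))
    message(length(dropped), " unpaired frame(s) dropped")
  attr(out, "dropped") <- dropped
  out
}
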