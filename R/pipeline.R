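#' Run configuration defaults
#'
#' Builds a complete run configuration from a YAML file or a named list,
#' filling defaults for unspecified stages. The single `seed` propagates to
#' every stochastic stage (per-wavelength noise, speckle synthesis).
#'
#' @param config path to a YAML config or a named list. Recognized fields:
#'   `scene` (scene YAML path or an `oa_phantom`), `wavelengths`,
#'   `probe` (arguments to [probe_model()]), `sim` (arguments to
#'   [sim_config()]), `filter` (arguments to [filter_spec()]), `palette`
#'   (arguments to [palette_spec()]), `wiener_nsr`, `sir_floor`,
#'   `normalize` (`smooth`, `min_frac`), `out_dir`, `seed`.
#' @return a completed config list of class `oa_runconfig`.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_oa("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  defaults <- list(wavelengths = c(757, 1064), probe = list(), sim = list(),
                   filter = list(), palette = list(), wiener_nsr = "auto",
                   sir_floor = 0.2, subtract_background = TRUE,
                   average_frames = 1L,
                   normalize = list(smooth = 5, min_frac = 0.05),
                   out_dir = file.path(tempdir(), "oatomo-run"), seed = 1L)
  cfg <- modifyList(defaults, config)
  if (is.null(cfg$scene)) stop_oa("config must name a `scene`")
  class(cfg) <- "oa_runconfig"
  cfg
}

eroded_mask <- function(mask, r_px) {
  if (r_px < 1 || !any(mask)) return(mask)
  brush <- EBImage::makeBrush(2 * r_px + 1, "disc")
  EBImage::erode(mask * 1, brush) > 0.5
}

# ROI-mean sO2 is the saturation of the ROI-mean chromophore content
# (ratio of means): far more noise-robust than averaging per-pixel
# saturations, whose [0,1] clamping biases low-SNR ROIs toward mid-range.
roi_stats <- function(fmaps, ras, phantom, spacing) {
  out <- list()
  for (i in seq_along(phantom$inclusions)) {
    inc <- phantom$inclusions[[i]]
    r_px <- max(1L, floor(min(inc$size) / 2 / spacing / 3))
    m <- eroded_mask(ras$masks[[i]], r_px)
    if (!any(m)) m <- ras$masks[[i]]
    sel <- m & fmaps$valid
    if (!any(sel)) sel <- m
    thb_m <- mean(fmaps$thb_raw[sel])
    hbo_m <- mean(fmaps$hbo2_raw[sel])
    so2_roi <- if (is.finite(thb_m) && thb_m > 0)
      min(max(hbo_m / thb_m, 0), 1) else NA_real_
    out[[i]] <- list(
      inclusion = i, shape = inc$shape,
      center_x_mm = inc$center[1], depth_mm = inc$center[2],
      n_px = sum(sel),
      so2_true_pct = if (!is.null(inc$blood)) 100 * inc$blood$so2 else NA,
      so2_mean_pct = 100 * so2_roi,
      thb_mean = if (any(m)) mean(fmaps$thb[m]) else NA)
  }
  out
}

#' Run the full imaging pipeline
#'
#' End-to-end orchestration for one scene: per-wavelength forward
#' simulation, channel compensation, Wiener EIR deconvolution, zero-phase
#' bandpass, SIR-weighted filtered back-projection, bright-object
#' segmentation, depth normalization (rescaled by the bulk background
#' absorption so both wavelengths share a mu_a scale), spectral unmixing,
#' statistical mapping against a background reference region, B-mode
#' synthesis and overlay rendering. All intermediates and a JSON manifest
#' with per-inclusion ROI statistics are written to `out_dir`; identical
#' config and seed give a byte-identical manifest.
#'
#' @param config see [read_run_config()].
#' @return the manifest, invisibly (also written to
#'   `<out_dir>/manifest.json`).
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_oa(sprintf("[%s] %s", name, conditionMessage(e))))
  }
  phantom <- stage("phantom",
    if (inherits(cfg$scene, "oa_phantom")) cfg$scene else read_scene(cfg$scene))
  probe <- stage("probe", do.call(probe_model, cfg$probe))
  fspec <- do.call(filter_spec, cfg$filter)
  pal <- do.call(palette_spec, cfg$palette)
  cal <- channel_calibration(n_elements = probe$n_elements)
  grid <- grid_from_phantom(phantom)
  paths <- list()
  images <- list()
  raw <- list()
  bg_phantom <- NULL
  if (isTRUE(cfg$subtract_background) && length(phantom$inclusions)) {
    bg_phantom <- phantom
    bg_phantom$inclusions <- list()
  }
  navg <- max(1L, as.integer(cfg$average_frames))
  for (i in seq_along(cfg$wavelengths)) {
    wl <- cfg$wavelengths[i]
    raw[[i]] <- stage("simulate", {
      # average_frames > 1 emulates the video-rate display: consecutive
      # noisy acquisitions of the same (static) scene are averaged
      s <- NULL
      for (k in seq_len(navg)) {
        sim <- do.call(sim_config,
                       modifyList(cfg$sim,
                                  list(seed = cfg$seed + i - 1L +
                                         1000L * (k - 1L))))
        sk <- simulate_sinogram(phantom, probe, wl, sim)
        s <- if (is.null(s)) sk else { s$data <- s$data + sk$data; s }
      }
      s$data <- s$data / navg
      if (!is.null(bg_phantom)) {
        # model-based removal of the homogeneous-background response
        # (depth slope and illuminated-surface wave), the simulation-side
        # analogue of the device's background segmentation and removal
        sim_bg <- do.call(sim_config,
                          modifyList(cfg$sim, list(noise = FALSE)))
        s_bg <- simulate_sinogram(bg_phantom, probe, wl, sim_bg)
        s$data <- s$data - s_bg$data
      }
      s
    })
  }
  for (i in seq_along(cfg$wavelengths)) {
    wl <- cfg$wavelengths[i]
    sino <- stage("condition", {
      s <- compensate_channels(raw[[i]], cal)
      # one common Wiener filter for the frame pair (pooled spectrum)
      s <- wiener_deconvolve_eir(s, probe, cfg$wiener_nsr, psd_from = raw)
      s <- bandpass(s, fspec)
      deconvolve_sir(s, probe, cfg$sir_floor)
    })
    paths[[paste0("sinogram_", wl)]] <-
      oa_write(sino, file.path(cfg$out_dir, sprintf("sinogram_%d.rds", wl)))
    img <- stage("reconstruct", backproject(sino, grid, probe))
    paths[[paste0("image_", wl)]] <-
      oa_write(img, file.path(cfg$out_dir, sprintf("image_%d.rds", wl)))
    images[[as.character(wl)]] <- img
  }
  fmaps <- stage("map", {
    masks <- lapply(images, segment_bright)
    mask <- Reduce(`|`, masks)
    norm <- lapply(seq_along(images), function(i) {
      wl <- cfg$wavelengths[i]
      bg <- background_optics(phantom, wl)
      prof <- bg$mu_a * fluence_depth(images[[i]]$z, bg$mu_a, bg$mu_sp)
      normalize_depth(images[[i]], mask, scale = bg$mu_a,
                      min_frac = cfg$normalize$min_frac,
                      smooth = cfg$normalize$smooth, profile = prof)
    })
    fm <- unmix(norm[[1]], norm[[2]])
    set_reference(fm, reference_region(fm, mask))
  })
  paths$funcmaps <- oa_write(fmaps, file.path(cfg$out_dir, "funcmaps.rds"))
  overlays <- stage("render", {
    bmode <- synthesize_bmode(phantom, grid, seed = cfg$seed)
    so2_l <- render_so2(fmaps, pal)
    thb_l <- render_thb(fmaps, pal)
    list(so2 = compose_overlay(bmode, so2_l, NULL, "so2"),
         thb = compose_overlay(bmode, NULL, thb_l, "thb"),
         combined = compose_overlay(bmode, so2_l, thb_l, "combined"))
  })
  for (m in names(overlays))
    paths[[paste0("overlay_", m)]] <-
      write_overlay_png(overlays[[m]], file.path(cfg$out_dir,
                                                 sprintf("overlay_%s.png", m)))
  ras <- rasterize_phantom(phantom, cfg$wavelengths[1])
  manifest <- list(
    package = "oatomo",
    seed = cfg$seed,
    wavelengths = cfg$wavelengths,
    scene = list(medium = if (is.character(phantom$medium)) phantom$medium
                          else "explicit",
                 n_inclusions = length(phantom$inclusions),
                 extent_mm = phantom$extent, spacing_mm = phantom$spacing),
    sim = cfg$sim, filter = unclass(fspec),
    files = lapply(paths, basename),
    reference = lapply(fmaps$reference[c("thb", "so2")], as.list),
    rois = roi_stats(fmaps, ras, phantom, phantom$spacing))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  manifest$out_dir <- cfg$out_dir
  invisible(manifest)
}

fixture_suites <- c("two_tube_so2_sweep", "depth_series",
                    "hematocrit_series", "tumor_scenes")

#' Write validation scene fixtures
#'
#' Writes the YAML scenes (and a ground-truth CSV) for the phantom
#' validation suites: the flowing-blood oxygenation sweep (2.4 mm tubes at
#' 10 mm, upper tube 100->91% and lower tube 50->85% sO2), the depth
#' series (1.5 mm tubes, 13-32 mm, aqueous bath), the hematocrit series
#' (41/27/4% at 20 mm) and tumor scenes.
#'
#' @param suite one of `"two_tube_so2_sweep"`, `"depth_series"`,
#'   `"hematocrit_series"`, `"tumor_scenes"`.
#' @param dir output directory.
#' @return data.frame of scene files and ground truth (also written as
#'   `truth.csv`).
#' @export
make_fixtures <- function(suite, dir) {
  if (!suite %in% fixture_suites)
    stop_oa("unknown suite; available: ", paste(fixture_suites, collapse = ", "))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  add <- function(file, phantom, ...) {
    write_scene(phantom, file.path(dir, file))
    rows[[length(rows) + 1L]] <<- data.frame(file = file, ...)
  }
  if (suite == "two_tube_so2_sweep") {
    left <- c(1.00, 0.95, 0.91); right <- c(0.50, 0.70, 0.85)
    for (k in seq_along(left))
      add(sprintf("sweep_%02d.yaml", k),
          make_two_tube_phantom(depth = 10, diameter = 2.4,
                                so2_left = left[k], so2_right = right[k],
                                hematocrit = 0.27, medium = "breast"),
          so2_left = left[k], so2_right = right[k], depth_mm = 10,
          diameter_mm = 2.4, hematocrit = 0.27)
  } else if (suite == "depth_series") {
    for (d in c(13, 20, 26, 32))
      add(sprintf("depth_%02d.yaml", d),
          make_two_tube_phantom(depth = d, diameter = 1.5,
                                so2_left = 1.0, so2_right = 0.5,
                                hematocrit = 0.27, medium = "aqueous"),
          so2_left = 1.0, so2_right = 0.5, depth_mm = d,
          diameter_mm = 1.5, hematocrit = 0.27)
  } else if (suite == "hematocrit_series") {
    for (ht in c(0.41, 0.27, 0.04))
      add(sprintf("hematocrit_%02d.yaml", round(100 * ht)),
          make_two_tube_phantom(depth = 20, diameter = 2.4,
                                so2_left = 1.0, so2_right = 0.5,
                                hematocrit = ht, medium = "breast"),
          so2_left = 1.0, so2_right = 0.5, depth_mm = 20,
          diameter_mm = 2.4, hematocrit = ht)
  } else {
    geom <- list(c(10, 20), c(5, 15), c(15, 25))
    for (g in geom)
      add(sprintf("tumor_%02dmm_%02dmm.yaml", g[1], g[2]),
          make_tumor_phantom(size = g[1], depth = g[2]),
          so2_left = NA, so2_right = NA, depth_mm = g[2],
          diameter_mm = g[1], hematocrit = NA)
  }
  truth <- do.call(rbind, rows)
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  truth
}
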