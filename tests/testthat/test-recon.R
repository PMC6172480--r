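test_that("data function implements p - t dp/dt", {
  t <- (0:99) / 10
  expect_equal(data_function(rep(3.7, 100), t), rep(3.7, 100))
  expect_equal(data_function(t, t), rep(0, 100))
  w <- 2
  df <- data_function(sin(w * t), t)
  closed <- sin(w * t) - t * w * cos(w * t)
  expect_equal(df[3:98], closed[3:98], tolerance = 1e-2)
  expect_error(data_function(c(1, 2), c(0, 1)), "3 samples")
})

test_that("back-projection is linear and maps zero to zero", {
  probe <- small_probe()
  grid <- recon_grid(c(-5, 5), c(10, 20), 0.2)
  fs <- 40; n <- 800
  zero <- oa_sinogram(matrix(0, 8, n), fs, x_elem = probe$x)
  expect_true(all(backproject(zero, grid, probe)$data == 0))
  set.seed(5)
  a <- oa_sinogram(matrix(rnorm(8 * n), 8), fs, x_elem = probe$x)
  b <- oa_sinogram(matrix(rnorm(8 * n), 8), fs, x_elem = probe$x)
  ab <- a; ab$data <- 2 * a$data - 5 * b$data
  expect_equal(backproject(ab, grid, probe)$data,
               2 * backproject(a, grid, probe)$data -
                 5 * backproject(b, grid, probe)$data,
               tolerance = 1e-10)
})

test_that("point absorbers reconstruct at their true locations", {
  probe <- probe_model()
  set.seed(42)
  for (k in 1:20) {
    x0 <- runif(1, -12, 12); z0 <- runif(1, 5, 35)
    grid <- recon_grid(c(x0 - 2, x0 + 2), c(z0 - 2, z0 + 2), 0.15)
    sino <- simulate_points(data.frame(x = x0, y = 0, z = z0,
                                       p0 = 1, V = 1e-3),
                            probe, sim_config(pulse_ns = 15))
    img <- recon_chain(sino, probe, grid)
    idx <- arrayInd(which.max(img$data), dim(img$data))
    expect_lte(abs(img$x[idx[2]] - x0), grid$spacing)
    expect_lte(abs(img$z[idx[1]] - z0), grid$spacing)
  }
})

test_that("equal absorbers at equal depth reconstruct with equal brightness", {
  probe <- probe_model()
  peaks <- vapply(c(0, 5, 8), function(x0) {
    grid <- recon_grid(c(x0 - 2, x0 + 2), c(18, 22), 0.05)
    sino <- simulate_points(data.frame(x = x0, y = 0, z = 20,
                                       p0 = 1, V = 1e-3),
                            probe, sim_config(pulse_ns = 15))
    max(recon_chain(sino, probe, grid)$data)
  }, numeric(1))
  expect_lt((max(peaks) - min(peaks)) / mean(peaks), 0.05)
})

test_that("PSF widths order with pulse duration and depth", {
  probe <- probe_model()
  psf_at <- function(z0, pulse) {
    sino <- simulate_points(data.frame(x = 0, y = 0, z = z0,
                                       p0 = 1, V = 0.05^3),
                            probe, sim_config(pulse_ns = pulse))
    grid <- recon_grid(c(-3, 3), c(z0 - 3, z0 + 3), 0.02)
    psf_metrics(recon_chain(sino, probe, grid), peak = c(0, z0))
  }
  m15 <- psf_at(20, 15); m50 <- psf_at(20, 50)
  expect_gt(m50$axial, m15$axial)      # longer pulse, coarser axial PSF
  near <- psf_at(15, 15); far <- psf_at(30, 15)
  expect_gt(far$lateral, near$lateral) # lateral resolution degrades deep
})

test_that("FWHM of a synthetic Gaussian blob matches the closed form", {
  g <- recon_grid(c(-5, 5), c(15, 25), 0.05)
  sig <- 0.8
  blob <- outer(exp(-(g$z - 20)^2 / (2 * sig^2)),
                exp(-g$x^2 / (2 * sig^2)))
  m <- psf_metrics(oa_image(blob, g$x, g$z, g$spacing, 757), c(0, 20))
  expect_equal(m$axial, 2.355 * sig, tolerance = g$spacing)
  expect_equal(m$lateral, 2.355 * sig, tolerance = g$spacing)
  flat <- oa_image(matrix(-1, 10, 10), 1:10, 1:10, 1, 757)
  expect_error(psf_metrics(flat), "peak")
})

test_that("depth series contrast drops with attenuation, flattens after normalization", {
  probe <- probe_model()
  depths <- c(13, 20, 26, 32)
  tube_val <- function(d, att) {
    ph <- make_two_tube_phantom(d, 1.5, 1.0, 0.5, 0.27, "aqueous")
    ph$acoustic$alpha_us <- 0.32
    sino <- simulate_sinogram(ph, probe, 757,
                              sim_config(attenuation = att))
    grid <- grid_from_phantom(ph)
    img <- recon_chain(sino, probe, grid, nsr = 1e-3)
    ras <- rasterize_phantom(ph, 757)
    raw <- mean(img$data[ras$masks[[1]]])
    bg <- background_optics(ph, 757)
    prof <- fluence_depth(d, bg$mu_a, bg$mu_sp)
    c(raw = raw, norm = raw / prof)
  }
  on <- vapply(depths, tube_val, numeric(2), att = TRUE)
  expect_true(all(diff(on["raw", ]) < 0))  # monotone decay with depth
  off <- vapply(depths, tube_val, numeric(2), att = FALSE)
  spread <- diff(range(off["norm", ])) / mean(off["norm", ])
  expect_lt(spread, 0.10)                  # flat after depth normalization
})

test_that("synthetic B-mode is seeded, hypoechoic in inclusions, co-registered", {
  ph <- make_two_tube_phantom(15, 2.4)
  ph$skin_depth <- 1
  grid <- grid_from_phantom(ph)
  b1 <- synthesize_bmode(ph, grid, seed = 11)
  b2 <- synthesize_bmode(ph, grid, seed = 11)
  b3 <- synthesize_bmode(ph, grid, seed = 12)
  expect_identical(b1$data, b2$data)
  expect_false(identical(b1$data, b3$data))
  ras <- rasterize_phantom(ph, 757)
  tubes <- ras$masks[[1]] | ras$masks[[2]]
  expect_lt(mean(b1$data[tubes]), 0.6 * mean(b1$data[!tubes]))
  expect_equal(b1$x, grid$x)
  expect_equal(b1$z, grid$z)
  expect_equal(b1$spacing, grid$spacing)
})
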