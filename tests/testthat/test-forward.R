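test_that("probe EIR crosses -6 dB at the nominal band edges", {
  probe <- probe_model()
  fs <- 40; n <- 4000
  H <- eir_response(probe, fs, n)
  f <- abs((seq_len(n) - 1) * fs / n)
  at <- function(freq) H[which.min(abs(f[1:(n / 2)] - freq))]
  expect_equal(at(0.1) / max(H), 0.5, tolerance = 0.02)
  expect_equal(at(12) / max(H), 0.5, tolerance = 0.02)
  expect_equal(probe$aperture, 40)
  expect_error(probe_model(element_width = 0.5, pitch = 0.3125), "pitch")
})

test_that("probe self-signal adds a common early-time transient", {
  probe <- small_probe()
  src <- data.frame(x = 0, y = 0, z = 20, p0 = 1, V = 1e-3)
  off <- simulate_points(src, probe, sim_config())
  on <- simulate_points(src, probe, sim_config(probe_self_signal = 0.5))
  extra <- on$data - off$data
  expect_lt(max(abs(sweep(extra, 2, extra[1, ]))), 1e-12)  # common mode
  e_first <- sum(extra[1, 1:100]^2)
  expect_gt(e_first, 10 * sum(extra[1, 301:400]^2))         # early, decaying
})

test_that("planar fluence model reproduces the diffusion-theory arithmetic", {
  expect_equal(fluence_depth(0, 0.039, 9.0), 1.0)
  expect_equal(mu_eff(0.039, 9.0), sqrt(3 * 0.039 * 9.039))
  expect_equal(mu_eff(0.039, 9.0), 1.028, tolerance = 1e-3)
  expect_equal(fluence_depth(10, 0.039, 9.0), 0.357, tolerance = 2e-3)
  # average loss over the two wavelengths is about 3-fold per cm
  loss <- mean(1 / c(fluence_depth(10, 0.039, 9.0),
                     fluence_depth(10, 0.122, 4.0)))
  expect_equal(loss, 3, tolerance = 0.15)
  ph <- make_two_tube_phantom(10)
  fl <- fluence(ph, 757)
  expect_true(all(diff(fl$data[, 1]) < 0))  # strictly decreasing in depth
  expect_error(fluence(ph, 900), "757 and 1064")
})

test_that("initial pressure is the pixelwise Grueneisen x mu_a x fluence", {
  ph <- make_two_tube_phantom(10)
  fl <- fluence(ph, 757)
  p0 <- initial_pressure(ph, fl, 757)
  ras <- rasterize_phantom(ph, 757)
  expect_equal(p0$data, ras$mu_a * fl$data)
  # tumor-to-background ratio at equal depth equals the mu_a ratio
  tum <- make_tumor_phantom(10, 20)
  p0t <- initial_pressure(tum, fluence(tum, 757), 757)
  rast <- rasterize_phantom(tum, 757)
  row <- which.min(abs(p0t$z - 20))
  in_t <- rast$masks[[1]][row, ]
  expect_equal(mean(p0t$data[row, in_t]) / mean(p0t$data[row, !in_t]),
               0.130 / 0.039, tolerance = 1e-10)
  # zero absorption gives zero pressure
  empty <- digital_phantom(medium = optical_properties(757, 0, 9))
  expect_true(all(initial_pressure(empty, fluence(empty, 757), 757)$data == 0))
  bad_fl <- fluence(digital_phantom(spacing = 0.3), 757)
  expect_error(initial_pressure(ph, bad_fl, 757), "grid")
})

test_that("acoustic attenuation follows the power-law amplitude loss", {
  expect_equal(acoustic_attenuation(2, 5, 0), 2)
  expect_equal(acoustic_attenuation(2, 0, 3), 2)
  # 10 MHz across 1 cm of breast: ~3-fold amplitude loss
  expect_equal(1 / acoustic_attenuation(1, 10, 1), 3.2, tolerance = 0.1)
  set.seed(2)
  f <- sort(runif(10, 0, 12)); z <- sort(runif(10, 0, 4))
  expect_true(all(diff(acoustic_attenuation(1, f, 2)) < 0))
  expect_true(all(diff(acoustic_attenuation(1, 5, z)) < 0))
  expect_error(acoustic_attenuation(1, -1, 1), "nonnegative")
})

test_that("analytic sphere N-wave is causal, bipolar and of duration 2a/c", {
  a <- 1.2; d <- 25; c0 <- 1.54; fs <- 100
  nw <- sphere_nwave(a, d, sos = c0, fs = fs)
  t_on <- (d - a) / c0
  expect_true(all(nw$p[nw$t < t_on - 1e-9] == 0))
  support <- range(nw$t[nw$p != 0])
  expect_equal(diff(support), 2 * a / c0, tolerance = 2 / fs)
  expect_equal(sum(nw$p) / fs, 0, tolerance = a / d / fs)  # zero net area
  # exact edge amplitude (spherical spreading) at the pulse onset time
  expect_equal(sphere_nwave(a, d, sos = c0, t = (d - a) / c0)$p, a / (2 * d))
  expect_error(sphere_nwave(2, 1.5), "inside")
})

test_that("discretized forward simulation matches the N-wave oracle", {
  probe <- small_probe()
  cfg <- sim_config(n_quad = 1, directivity = FALSE, fs = 40, pulse_ns = 50)
  src <- sphere_sources(radius = 1, depth = 20, h = 0.03)
  sino <- simulate_points(src, probe, cfg, wavelength = 757)
  ec <- which.min(abs(probe$x))
  d <- sqrt(probe$x[ec]^2 + 20^2)
  ref <- nwave_reference(1, d, probe, sino$fs, ncol(sino$data), pulse_ns = 50)
  err <- sqrt(mean((sino$data[ec, ] - ref)^2)) / sqrt(mean(ref^2))
  expect_lt(err, 0.025)
})

test_that("forward model is linear and empty scenes give zero sinograms", {
  probe <- small_probe()
  bg0 <- optical_properties(757, 0, 9.0)
  mk <- function(incs) digital_phantom(medium = bg0, inclusions = incs,
                                       spacing = 0.3)
  cfg <- sim_config(n_t = 1700)
  expect_true(all(simulate_sinogram(mk(list()), probe, 757, cfg)$data == 0))
  i1 <- list(inclusion("tube", c(-5, 15), 2, blood = blood_state(1, 0.27)))
  i2 <- list(inclusion("tube", c(5, 25), 2, blood = blood_state(0.3, 0.27)))
  s1 <- simulate_sinogram(mk(i1), probe, 757, cfg)
  s2 <- simulate_sinogram(mk(i2), probe, 757, cfg)
  s12 <- simulate_sinogram(mk(c(i1, i2)), probe, 757, cfg)
  expect_equal(s12$data, s1$data + s2$data, tolerance = 1e-12)
})

test_that("first arrival of a shallow absorber is at depth over sound speed", {
  probe <- probe_model()
  z0 <- 15
  sino <- simulate_points(data.frame(x = 0, y = 0, z = z0, p0 = 1, V = 1e-3),
                          probe, sim_config(n_quad = 1, directivity = FALSE))
  ec <- which.min(abs(probe$x))
  pk <- which.max(abs(sino$data[ec, ])) / sino$fs
  expect_equal(pk, z0 / 1.54, tolerance = 0.15)
  # earliest across the array at the central elements
  onset <- apply(abs(sino$data) > 0.1 * max(abs(sino$data)), 1, which.max)
  expect_lte(abs(which.min(onset) - ec), 2)
})

test_that("peak amplitude decays with depth as fluence times spreading", {
  probe <- probe_model()
  depths <- c(13, 20, 26, 32)
  peaks <- vapply(depths, function(z0) {
    F_z <- fluence_depth(z0, 0.039, 9.0)
    s <- simulate_points(data.frame(x = 0, y = 0, z = z0, p0 = F_z, V = 1e-3),
                         probe,
                         sim_config(n_quad = 1, directivity = FALSE))
    max(abs(s$data[which.min(abs(probe$x)), ]))
  }, numeric(1))
  model <- fluence_depth(depths, 0.039, 9.0) / depths
  expect_equal(peaks / peaks[1], model / model[1], tolerance = 0.05)
})

test_that("seeded noise is reproducible and seed-sensitive", {
  probe <- small_probe()
  src <- data.frame(x = 0, y = 0, z = 20, p0 = 1, V = 1e-3)
  s1 <- simulate_points(src, probe, sim_config(noise = TRUE, seed = 7))
  s2 <- simulate_points(src, probe, sim_config(noise = TRUE, seed = 7))
  s3 <- simulate_points(src, probe, sim_config(noise = TRUE, seed = 8))
  expect_identical(s1$data, s2$data)
  expect_false(identical(s1$data, s3$data))
  expect_error(simulate_points(src, probe, sim_config(fs = 20)), "Nyquist")
})

test_that("beam-edge artifact forms a V with its apex at the centre", {
  probe <- probe_model()
  ph <- make_two_tube_phantom(10, 2.4, 1, 0.5, 0.27)
  sino <- simulate_sinogram(ph, probe, 757, sim_config(n_t = 1800))
  with_art <- inject_edge_wave(sino, probe, "sharp")
  art <- with_art$data - sino$data
  pk <- apply(art, 1, which.max)
  expect_true(all(which(pk == max(pk)) %in% 64:65))
  # apex delay equals half the aperture over the skin sound speed
  expect_equal(max(pk - 1) / sino$fs, (probe$aperture / 2) / sino$sos,
               tolerance = 0.2)
  # artifact energy decreases monotonically with the Gaussian edge width
  energy <- function(sig)
    sum((inject_edge_wave(sino, probe, "gaussian", sigma = sig)$data -
           sino$data)^2)
  e <- vapply(c(1, 3, 8, 20, 50), energy, numeric(1))
  expect_true(all(diff(e) < 0))
  expect_lt(e[5], 0.05 * sum(art^2))  # smooth-beam limit
})
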