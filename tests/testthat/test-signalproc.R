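make_sino <- function(data, fs = 40) {
  oa_sinogram(as.matrix(data), fs, 757, 0, 1.54,
              x_elem = seq_len(nrow(as.matrix(data))))
}

test_that("channel compensation divides by gains and zeroes bad elements", {
  set.seed(3)
  d <- matrix(rnorm(8 * 64), 8)
  s <- make_sino(d)
  idcal <- channel_calibration(1, n_elements = 8)
  expect_equal(compensate_channels(s, idcal)$data, d)
  cal <- channel_calibration(gains = seq(0.5, 1.9, by = 0.2), bad = 7,
                             n_elements = 8)
  out <- compensate_channels(s, cal)
  expect_true(all(out$data[7, ] == 0))
  expect_equal(out$data[2, ], d[2, ] / 0.7)
  # compensating with g then 1/g restores the live channels
  inv <- channel_calibration(1 / cal$gains, bad = 7, n_elements = 8)
  back <- compensate_channels(out, inv)
  expect_equal(back$data[-7, ], d[-7, ])
  expect_error(channel_calibration(gains = c(-1, rep(1, 7)), n_elements = 8),
               "gain")
  expect_error(compensate_channels(s, channel_calibration(n_elements = 12)),
               "element count")
})

test_that("Wiener deconvolution inverts the EIR in the noise-free limit", {
  probe <- probe_model()
  fs <- 40; n <- 1600
  nw <- sphere_nwave(1.2, 20, t = (0:(n - 1)) / fs)
  blurred <- apply_system_response(nw$p, probe, fs, 0)
  s <- make_sino(matrix(blurred, 1))
  expect_true(all(wiener_deconvolve_eir(make_sino(matrix(0, 1, n)),
                                        probe)$data == 0))
  H <- eir_response(probe, fs, n)
  inband <- function(x) Re(fft(fft(x) * as.numeric(H > 0.5),
                               inverse = TRUE)) / n
  err_at <- function(nsr) {
    dec <- wiener_deconvolve_eir(s, probe, nsr)$data[1, ]
    sqrt(mean((inband(dec) - inband(nw$p))^2)) /
      sqrt(mean(inband(nw$p)^2))
  }
  expect_lt(err_at(1e-6), 0.02)           # in-band roundtrip
  errs <- vapply(c(1e-1, 1e-2, 1e-3, 1e-5), err_at, numeric(1))
  expect_true(all(diff(errs) < 0))        # monotone as nsr shrinks
  huge <- wiener_deconvolve_eir(s, probe, 1e12)
  expect_lt(max(abs(huge$data)), 1e-9 * max(abs(s$data)))
  expect_error(wiener_deconvolve_eir(s, probe, -1), "nsr")
})

test_that("zero-phase bandpass removes DC and preserves in-band content", {
  fs <- 40; n <- 1600; tax <- (0:(n - 1)) / fs
  dc <- make_sino(matrix(2.5, 1, n))
  expect_lt(max(abs(bandpass(dc)$data)) / 2.5, 1e-3)
  tone <- make_sino(matrix(sin(2 * pi * 1 * tax), 1))
  expect_equal(max(abs(bandpass(tone)$data[1, 400:1200])), 1,
               tolerance = 0.05)
  pulse <- make_sino(matrix(exp(-(tax - 20)^2 / (2 * 0.3^2)), 1))
  expect_lte(abs(which.max(bandpass(pulse)$data[1, ]) -
                   which.max(pulse$data[1, ])), 1)
  expect_error(bandpass(tone, filter_spec(low = 0.067, high = 25)),
               "Nyquist")
  expect_error(filter_spec(low = 2, high = 1), "low < high")
})

test_that("conditioning chain is linear", {
  probe <- small_probe()
  fs <- 40; n <- 800
  set.seed(4)
  x <- matrix(rnorm(8 * n), 8); y <- matrix(rnorm(8 * n), 8)
  chain <- function(d) {
    s <- make_sino(d, fs)
    s <- compensate_channels(s, channel_calibration(1.3, n_elements = 8))
    s <- wiener_deconvolve_eir(s, probe, 1e-3)
    bandpass(s)$data
  }
  expect_equal(chain(2 * x + 3 * y), 2 * chain(x) + 3 * chain(y),
               tolerance = 1e-5)
})

test_that("inverse directivity weighting is the regularized reciprocal", {
  probe <- probe_model()
  expect_equal(inverse_directivity_weight(0, probe), 1)
  s <- 0.3
  expect_equal(inverse_directivity_weight(s, probe, 1.54, floor = 0.2),
               1 / element_directivity(s, probe, 1.54))
  # far oblique angles are capped at the floor
  d_far <- element_directivity(0.99, probe, 1.54)
  fl <- min(0.9, d_far * 2)
  expect_equal(inverse_directivity_weight(0.99, probe, 1.54, floor = fl),
               1 / fl)
  expect_error(deconvolve_sir(make_sino(matrix(0, 1, 8)), probe, floor = 0),
               "floor")
})

test_that("SIR correction inverts the forward directivity on oblique sources", {
  probe <- probe_model()
  x0 <- 8; z0 <- 18
  grid <- recon_grid(c(x0 - 2, x0 + 2), c(z0 - 2, z0 + 2), 0.05)
  src <- data.frame(x = x0, y = 0, z = z0, p0 = 1, V = 1e-3)
  sim_on <- simulate_points(src, probe,
                            sim_config(n_quad = 1, directivity = TRUE))
  sim_off <- simulate_points(src, probe,
                             sim_config(n_quad = 1, directivity = FALSE))
  img_corr <- recon_chain(sim_on, probe, grid)          # SIR-corrected
  img_ref <- backproject(wiener_deconvolve_eir(sim_off, probe, 1e-4),
                         grid, probe, sir_correct = FALSE)
  expect_equal(max(img_corr$data) / max(img_ref$data), 1, tolerance = 0.05)
})
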