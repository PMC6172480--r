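# Shared builders for the test suite. Fixtures are generated in code; the
# small probe keeps forward models cheap where the full 128-element array
# is not the point of the test.

small_probe <- function(n = 8) probe_model(n_elements = n, pitch = 0.3125)

# Discretize a uniform sphere (radius mm, centre depth mm) into a 3D voxel
# cloud for the forward simulator.
sphere_sources <- function(radius, depth, h) {
  g <- seq(-radius - h, radius + h, by = h)
  pts <- expand.grid(x = g, y = g, z = depth + g)
  keep <- pts$x^2 + pts$y^2 + (pts$z - depth)^2 <= radius^2
  data.frame(x = pts$x[keep], y = pts$y[keep], z = pts$z[keep],
             p0 = 1, V = h^3)
}

# Analytic sphere N-wave convolved with the detection response, evaluated
# on a fine grid and decimated to the simulation sampling grid, so the
# reference is free of its own sampling aliasing.
nwave_reference <- function(radius, distance, probe, fs, n_t, pulse_ns = 0,
                            up = 8) {
  tf <- (seq_len(n_t * up) - 1) / (fs * up)
  nw <- sphere_nwave(radius, distance, sos = 1.54, p0 = 1, t = tf)
  ref <- apply_system_response(nw$p, probe, fs * up, pulse_ns)
  ref[seq(1, n_t * up, by = up)]
}

# Minimal conditioning + reconstruction used by several tests.
recon_chain <- function(sino, probe, grid, nsr = 1e-4) {
  s <- wiener_deconvolve_eir(sino, probe, nsr)
  s <- deconvolve_sir(s, probe)
  backproject(s, grid, probe)
}

# Full two-tube recovery through run_pipeline; returns per-tube ROI sO2 %.
pipeline_so2 <- function(phantom, seed = 1, sim = list(), ...) {
  out <- withr::local_tempdir()
  m <- run_pipeline(list(scene = phantom, out_dir = out, seed = seed,
                         sim = sim, ...))
  vapply(m$rois, function(r) r$so2_mean_pct, numeric(1))
}
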