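# Small geometries shared across tests. Fields are tens of micrometres so
# whole-pipeline tests stay fast; physics is identical at larger grids.

test_config <- function(grid = 256L, pitch = 0.25, sensor = pitch,
                        z = 300, jitter = 0) {
  optical_config(grid_shape = c(grid, grid), grid_pitch = pitch,
                 sensor_pitch = sensor, z_nominal = z, z_jitter = jitter)
}

noiseless <- list(shot_scale = 0, read_sigma = 0)

# A band-limited random field (no evanescent content) for propagation tests.
bandlimited_field <- function(n = 128, pitch = 0.5, wavelength = 0.52,
                              seed = 1) {
  v <- local({ set.seed(seed); matrix(rnorm(n * n), n, n) })
  propagate(complex_field(v + 0i, pitch, wavelength), 1e-4)
}

# HSV hue in degrees of per-wavelength amplitudes (shortest..longest).
amps_to_hue <- function(amps) {
  v <- rev(pmin(pmax(amps, 0), 1))  # R, G, B
  mx <- max(v); mn <- min(v); d <- mx - mn
  if (d == 0) return(0)
  h <- if (mx == v[1]) 60 * ((v[2] - v[3]) / d)
       else if (mx == v[2]) 60 * (2 + (v[3] - v[1]) / d)
       else 60 * (4 + (v[1] - v[2]) / d)
  h %% 360
}
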