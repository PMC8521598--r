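# Shared synthetic fixtures, built in code.  Heavy objects are cached per
# session so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Nine unit-amplitude particles on a jittered grid, pairwise >= 30 um apart
# so 73-px fitting windows never overlap a neighbour (256 px at 0.4 um/px).
nine_particles <- function() {
  data.frame(
    x_um = c(16, 48, 80, 18, 52, 84, 20, 50, 84),
    y_um = c(16, 20, 18, 50, 50, 52, 82, 84, 84),
    amplitude = 1)
}

# Noise-free single-frame phantom (the baseline object of most PSF tests)
noise_free_stack <- function() {
  cached("noise_free_stack", {
    spec <- phantom_spec(grid_size = 256, pitch = 0.4,
                         particles = nine_particles(),
                         psf_magnitude_fwhm = 2.1)
    synthesize_stack(spec, 1)
  })
}

# Noise sigma giving a ~30 dB single-shot spatial-frequency dynamic range
# for the nine-particle phantom.
phantom_noise_sigma <- function() {
  cached("phantom_noise_sigma", {
    s <- to_spectrum(coherent_average(noise_free_stack()))
    sqrt(Mod(s$values[s$dc_row, s$dc_col])^2 / (10^3 * 256^2))
  })
}

# 100-frame noisy phantom and its paired signal-free noise stack
noisy_pair <- function() {
  cached("noisy_pair", {
    sigma <- phantom_noise_sigma()
    spec <- phantom_spec(grid_size = 256, pitch = 0.4,
                         particles = nine_particles(),
                         psf_magnitude_fwhm = 2.1,
                         noise_sigma = sigma, seed = 5L)
    list(stack = synthesize_stack(spec, 100),
         noise = synthesize_noise_stack(256, 256, pitch = 0.4,
                                        noise_sigma = sigma,
                                        n_frames = 100, seed = 6L))
  })
}

# 100 frames of unit-sigma circular complex Gaussian noise
unit_noise_stack <- function() {
  cached("unit_noise_stack",
         synthesize_noise_stack(256, 256, pitch = 0.4, noise_sigma = 1,
                                n_frames = 100, seed = 11L))
}

# Single centred particle, noise-free
centered_particle_stack <- function() {
  cached("centered_particle_stack", {
    spec <- phantom_spec(grid_size = 256, pitch = 0.4,
                         particles = data.frame(x_um = 51.2, y_um = 51.2,
                                                amplitude = 1),
                         psf_magnitude_fwhm = 2.1)
    synthesize_stack(spec, 1)
  })
}

# Measure the FWHM of the brightest particle of a field after upsampling
measure_fwhm <- function(field, upsample = 4L, window_px = 73L) {
  up <- zeropad_upsample(field, upsample)
  win <- window_px * upsample + (1L - (window_px * upsample) %% 2L)
  det <- detect_particles(Mod(up$values), window = win,
                          min_separation = window_px * upsample)
  fit_psf(up, c(det$row[1], det$col[1]), window = win)
}
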