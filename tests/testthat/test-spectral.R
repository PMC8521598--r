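test_that("spectrum transform is unitary and DC-centered", {
  # delta at the grid center: flat magnitude spectrum
  v <- matrix(0 + 0i, 32, 32); v[17, 17] <- 1
  s <- to_spectrum(enface_field(v, 0.4))
  expect_lt(diff(range(Mod(s$values))), 1e-10)
  expect_equal(s$nyquist_kr, pi / 0.4)

  # Parseval and round-trip identities on random fields
  for (seed in 1:5) {
    f <- withr::with_seed(seed, enface_field(
      matrix(complex(real = rnorm(64 * 48), imaginary = rnorm(64 * 48)), 64, 48),
      pitch_x = 0.4))
    s <- to_spectrum(f)
    e_space <- sum(Mod(f$values)^2)
    e_freq <- sum(Mod(s$values)^2) / length(s$values)
    expect_lt(abs(e_space - e_freq) / e_space, 1e-10)
    expect_lt(max(Mod(from_spectrum(s)$values - f$values)), 1e-10)
  }
})

test_that("a Gaussian spot transforms to a Gaussian spectrum with sigma_k = 1/sigma_x", {
  sigma_x <- 2  # um
  n <- 256; pitch <- 0.4
  xy <- (seq_len(n) - 1 - (n / 2)) * pitch
  g <- exp(-(outer(xy^2, xy^2, `+`)) / (2 * sigma_x^2))
  model <- fit_spectrum_model(enface_field(g + 0i, pitch))
  expect_lt(abs(model$sigma_k - 1 / sigma_x) / (1 / sigma_x), 0.01)
})

test_that("radial power profiles behave for flat, Gaussian, and mixed spectra", {
  prof_g <- radial_power_profile(
    to_spectrum(coherent_average(centered_particle_stack())), bin_width = 0.2)
  expect_true(all(diff(prof_g$power[prof_g$kr_center < 6]) < 1e-8))

  # signal + noise plateaus at the noise-only floor at high kr
  sigma <- phantom_noise_sigma()
  noisy <- noisy_pair()
  prof_sn <- radial_power_profile(
    to_spectrum(coherent_average(noisy$stack, 1)), bin_width = 0.2)
  prof_n <- radial_power_profile(
    to_spectrum(coherent_average(noisy$noise, 1)), bin_width = 0.2)
  hi <- prof_sn$kr_center > 6
  expect_lt(abs(mean(prof_sn$power[hi]) / mean(prof_n$power[hi]) - 1), 0.1)
})

test_that("dynamic range matches its closed-form scalings", {
  # flat noise spectrum with power equal to the signal's DC power: DR = 0 dB
  h <- 32
  noise <- matrix(0 + 0i, h, h); noise[5, 9] <- 2          # |N_k|^2 = 4 for all k
  signal <- matrix(2 / h^2 + 0i, h, h)                     # |S_DC|^2 = 4
  dr0 <- dynamic_range(enface_field(signal, 0.4), enface_field(noise, 0.4))
  expect_lt(abs(dr0$dr_db), 1e-10)

  # scaling the noise field by 10 lowers DR by exactly 20 dB
  f <- coherent_average(noisy_pair()$stack, 1)
  nz <- coherent_average(noisy_pair()$noise, 1)
  d1 <- dynamic_range(f, nz)
  d2 <- dynamic_range(f, enface_field(10 * nz$values, nz$pitch_x))
  expect_equal(d1$dr_db - d2$dr_db, 20)

  # invariant to a global phase rotation of either input
  d3 <- dynamic_range(enface_field(f$values * exp(1i * 1.1), f$pitch_x), nz)
  expect_equal(d3$dr_db, d1$dr_db)

  expect_error(dynamic_range(enface_field(matrix(0i, 8, 8), 0.4),
                             enface_field(matrix(1 + 0i, 8, 8), 0.4)),
               "degenerate")
})

test_that("phase-correlation limit separates flat-phase PSFs from noise", {
  cfg <- phase_corr_config(window = 243)
  f <- coherent_average(centered_particle_stack())

  # ideal noise-free PSF: correlated out to the Nyquist bin center
  expect_equal(phase_correlation_limit(f, c(129, 129), cfg), 7.85)

  # pure noise: decorrelated from the first bin on
  nz <- coherent_average(unit_noise_stack(), 1)
  expect_equal(phase_correlation_limit(nz, c(129, 129), cfg), 0.05)

  # invariant to global phase and to small integer translations of the window
  f_rot <- enface_field(f$values * exp(1i * 2.2), f$pitch_x)
  expect_equal(phase_correlation_limit(f_rot, c(129, 129), cfg), 7.85)
  expect_equal(phase_correlation_limit(f, c(126, 132), cfg), 7.85)

  expect_error(phase_correlation_limit(f, c(10, 129), cfg), "border")
  expect_error(phase_corr_config(window = 242), "odd")
})

test_that("phase-correlation limit is non-decreasing in N on noisy particles", {
  monotone <- vapply(1:3, function(s) {
    spec <- phantom_spec(grid_size = 256, pitch = 0.4,
                         particles = data.frame(x_um = 51.2, y_um = 51.2,
                                                amplitude = 1),
                         psf_magnitude_fwhm = 2.1, noise_sigma = 0.03,
                         seed = 100L + s)
    st <- synthesize_stack(spec, 100)
    lims <- vapply(c(1, 10, 100), function(N)
      phase_correlation_limit(coherent_average(st, N), c(129, 129),
                              phase_corr_config(window = 243)), numeric(1))
    all(diff(lims) >= 0)
  }, logical(1))
  expect_gte(sum(monotone), 2)  # majority vote over seed families
})
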