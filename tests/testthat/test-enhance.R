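test_that("refocus is an energy-preserving inverse pair and undoes simulated defocus", {
  f <- coherent_average(centered_particle_stack())
  same <- refocus(f, 0, wavelength_um = 0.85)
  expect_lt(max(Mod(same$values - f$values)), 1e-10)

  fwd <- refocus(f, 30, wavelength_um = 0.85)
  back <- refocus(fwd, -30, wavelength_um = 0.85)
  expect_lt(max(Mod(back$values - f$values)), 1e-10)
  expect_lt(abs(sum(Mod(fwd$values)^2) / sum(Mod(f$values)^2) - 1), 1e-12)

  # a defocused particle broadens, and refocusing restores the in-focus FWHM
  m0 <- measure_fwhm(f)
  m_def <- measure_fwhm(fwd)
  m_ref <- measure_fwhm(back)
  expect_gt(m_def$fwhm_um, m0$fwhm_um * 1.2)
  expect_lt(abs(m_ref$fwhm_um - m0$fwhm_um) / m0$fwhm_um, 0.02)

  expect_error(refocus(f, 10, wavelength_um = 0), "positive")
})

test_that("spectrum-model fit recovers the generator and scales with noise", {
  avg <- coherent_average(centered_particle_stack())
  model <- fit_spectrum_model(avg)
  sigma_true <- 2 * sqrt(2 * log(2)) / 2.1
  expect_lt(abs(model$sigma_k - sigma_true) / sigma_true, 0.01)

  nz <- coherent_average(noisy_pair()$noise, 1)
  m1 <- fit_spectrum_model(avg, nz)
  m2 <- fit_spectrum_model(avg, enface_field(2 * nz$values, nz$pitch_x))
  expect_equal(m2$noise_floor_power / m1$noise_floor_power, 4)

  expect_error(fit_spectrum_model(nz, nz), "noise floor")
})

test_that("BE mask has the Gaussian-ratio form with unit DC gain and caps", {
  model <- list(sigma_k = 1.12)
  m1 <- build_be_mask(model, 1, 64, 64, 0.4, max_gain_db = Inf)
  expect_true(all(m1$gain == 1))
  expect_error(build_be_mask(model, 0.9, 64, 64, 0.4), ">= 1")

  m <- build_be_mask(model, 2, 64, 64, 0.4, max_gain_db = Inf)
  expect_equal(m$gain[33, 33], 1)                 # DC
  expect_equal(m$gain, t(m$gain))                 # radial symmetry
  # in the b -> infinity limit the mask is the inverse of the model
  # amplitude: gain * exp(-kr^2 / (2 sigma_k^2)) = 1 wherever unclipped
  minf <- build_be_mask(model, 1e9, 64, 64, 0.4, max_gain_db = 40)
  H <- gaussian_transfer(2 * sqrt(2 * log(2)) / model$sigma_k, 64, 64, 0.4)
  un <- minf$gain < 10^(40 / 20) - 1e-6
  expect_lt(max(abs(minf$gain[un] * H[un] - 1)), 1e-8)

  # cap respected
  mc <- build_be_mask(model, 3, 64, 64, 0.4, max_gain_db = 20)
  expect_lte(max(mc$gain), 10 + 1e-12)

  # the noise-floor-aware cap limits gain to the floor-crossing value
  model2 <- list(sigma_k = 1.12, dc_amplitude = 100, noise_floor_power = 1)
  mf <- build_be_mask(model2, 2, 64, 64, 0.4, max_gain_db = 40)
  expect_lt(max(mf$gain), 10^(40 / 20))
  expect_equal(max(mf$gain), (100 / 1)^(1 - 1 / 4), tolerance = 1e-6)
})

test_that("applying the b=2 mask to a noise-free PSF halves its FWHM", {
  avg <- coherent_average(centered_particle_stack())
  model <- fit_spectrum_model(avg)
  mask <- build_be_mask(model, 2, 256, 256, 0.4, max_gain_db = Inf)
  m <- measure_fwhm(apply_be(avg, mask))
  expect_lt(abs(m$fwhm_um - 2.1 / 2) / (2.1 / 2), 0.02)

  # unit mask is the identity; the inverse mask undoes an unclipped mask
  unit <- build_be_mask(list(sigma_k = 1), 1, 256, 256, 0.4)
  expect_lt(max(Mod(apply_be(avg, unit)$values - avg$values)), 1e-10)
  inv <- mask; inv$gain <- 1 / mask$gain
  round_trip <- apply_be(apply_be(avg, mask), inv)
  expect_lt(max(Mod(round_trip$values - avg$values)), 1e-8)

  expect_error(apply_be(avg, build_be_mask(model, 2, 32, 32, 0.4)), "grid")
})

test_that("a mask raises white-noise power by mean(gain^2) in expectation", {
  model <- list(sigma_k = 1.12)
  mask <- build_be_mask(model, 1.5, 64, 64, 0.4, max_gain_db = 40)
  st <- synthesize_noise_stack(64, 64, noise_sigma = 1, n_frames = 50, seed = 33L)
  ratios <- vapply(st$frames, function(f) {
    out <- apply_be(enface_field(f, 0.4), mask)
    sum(Mod(out$values)^2) / sum(Mod(f)^2)
  }, numeric(1))
  expect_lt(abs(mean(ratios) - mean(mask$gain^2)) / mean(mask$gain^2), 0.05)
})

test_that("zero-pad upsampling interpolates exactly and converges", {
  f <- coherent_average(centered_particle_stack())
  expect_identical(zeropad_upsample(f, 1), f)

  up <- zeropad_upsample(f, 4)
  expect_equal(up$pitch_x, f$pitch_x / 4)
  orig_rows <- seq(1, nrow(up$values), by = 4)
  expect_lt(max(Mod(up$values[orig_rows, orig_rows] - f$values)), 1e-9)

  m2 <- measure_fwhm(f, upsample = 2)
  m4 <- measure_fwhm(f, upsample = 4)
  expect_lt(abs(m2$fwhm_um - m4$fwhm_um) / m4$fwhm_um, 0.01)
})
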