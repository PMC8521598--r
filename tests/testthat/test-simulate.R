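test_that("Gaussian transfer matches its space-domain FWHM specification", {
  # H(0) = 1 at the DC bin
  H <- gaussian_transfer(2.1, 256, 256, pitch = 0.4)
  expect_equal(H[129, 129], 1)
  expect_true(all(H <= 1) && all(H >= 0))

  # the realized magnitude PSF has FWHM 2.1 um (native transverse resolution)
  m <- measure_fwhm(coherent_average(centered_particle_stack()))
  expect_true(m$fit_ok)
  expect_lt(abs(m$fwhm_um - 2.1), 0.02)

  # sharp-PSF limit: a PSF much narrower than a pixel has an essentially
  # flat amplitude spectrum over the sampled band
  Hs <- suppressWarnings(gaussian_transfer(0.02, 64, 64, pitch = 0.4))
  expect_true(all(Hs > 0.99))

  # undersampled PSF warns
  expect_warning(gaussian_transfer(0.5, 32, 32, pitch = 0.4), "undersampled")
})

test_that("stack synthesis is deterministic, linear, and places particles at subpixel positions", {
  spec <- phantom_spec(grid_size = 64, pitch = 0.4,
                       particles = data.frame(x_um = 10, y_um = 12, amplitude = 1),
                       psf_magnitude_fwhm = 2.1, noise_sigma = 0.2, seed = 42L)
  s1 <- synthesize_stack(spec, 3)
  s2 <- synthesize_stack(spec, 3)
  expect_identical(s1$frames, s2$frames)

  # empty spec, no noise -> all-zero frames
  z <- synthesize_stack(phantom_spec(grid_size = 32, pitch = 0.4), 2)
  expect_true(all(vapply(z$frames, function(f) all(f == 0), logical(1))))

  # linearity in particle amplitudes (noise and background off)
  p1 <- data.frame(x_um = 10, y_um = 12, amplitude = 1)
  p2 <- data.frame(x_um = 18, y_um = 6, amplitude = 0.5)
  f_both <- synthesize_stack(phantom_spec(grid_size = 64, pitch = 0.4,
                                          particles = rbind(p1, p2),
                                          psf_magnitude_fwhm = 2.1), 1)$frames[[1]]
  f_sep <- synthesize_stack(phantom_spec(grid_size = 64, pitch = 0.4, particles = p1,
                                         psf_magnitude_fwhm = 2.1), 1)$frames[[1]] +
           synthesize_stack(phantom_spec(grid_size = 64, pitch = 0.4, particles = p2,
                                         psf_magnitude_fwhm = 2.1), 1)$frames[[1]]
  expect_lt(max(Mod(f_both - f_sep)), 1e-10)

  # subpixel placement: upsampled argmax lands within half an original pixel
  sub <- phantom_spec(grid_size = 64, pitch = 0.4,
                      particles = data.frame(x_um = 10.13, y_um = 11.77, amplitude = 1),
                      psf_magnitude_fwhm = 2.1)
  up <- zeropad_upsample(coherent_average(synthesize_stack(sub, 1)), 4)
  pk <- which(Mod(up$values) == max(Mod(up$values)), arr.ind = TRUE)[1, ]
  x_pk <- (pk[2] - 1) * up$pitch_x
  y_pk <- (pk[1] - 1) * up$pitch_y
  expect_lt(abs(x_pk - 10.13), 0.2)
  expect_lt(abs(y_pk - 11.77), 0.2)

  # particle peak magnitude equals its amplitude (unit-peak PSF convention)
  m <- measure_fwhm(coherent_average(centered_particle_stack()))
  expect_lt(abs(m$peak_magnitude - 1), 0.01)
})

test_that("noise stacks have the prescribed intensity and a flat spectrum", {
  expect_true(all(synthesize_noise_stack(16, 16, noise_sigma = 0, n_frames = 2,
                                         seed = 1)$frames[[1]] == 0))
  st <- unit_noise_stack()
  # per-pixel intensity sample mean ~ sigma^2 = 1
  expect_lt(abs(mean(Mod(st$frames[[1]])^2) - 1), 0.02)

  # flat radial power: outer-half vs inner-half mean power, averaged frames
  ratios <- vapply(st$frames, function(f) {
    prof <- radial_power_profile(to_spectrum(enface_field(f, 0.4)), bin_width = 0.5)
    half <- max(prof$kr_center) / 2
    sum(prof$power[prof$kr_center > half] * prof$n_bins[prof$kr_center > half]) /
      sum(prof$n_bins[prof$kr_center > half]) /
      (sum(prof$power[prof$kr_center <= half] * prof$n_bins[prof$kr_center <= half]) /
         sum(prof$n_bins[prof$kr_center <= half]))
  }, numeric(1))
  expect_gt(mean(ratios), 0.95)
  expect_lt(mean(ratios), 1.05)
})

test_that("background is phase-stable across frames while noise decorrelates", {
  inter_frame_corr <- function(a, b)
    Mod(sum(a * Conj(b))) / sqrt(sum(Mod(a)^2) * sum(Mod(b)^2))

  bg <- synthesize_stack(phantom_spec(grid_size = 256, pitch = 0.4,
                                      psf_magnitude_fwhm = 2.1,
                                      background_sigma = 0.3, seed = 9L), 2)
  expect_equal(inter_frame_corr(bg$frames[[1]], bg$frames[[2]]), 1)

  nz <- synthesize_noise_stack(256, 256, noise_sigma = 1, n_frames = 2, seed = 10L)
  expect_lt(inter_frame_corr(nz$frames[[1]], nz$frames[[2]]), 0.05)
})

test_that("Zernike pupil phase follows the Noll closed forms", {
  expect_true(all(zernike_phase(NULL, 32, 32, pitch = 0.4) == 0))

  # piston: constant inside the pupil
  p <- zernike_phase(c("1" = 0.7), 33, 33, pitch = 0.4, pupil_radius = pi / 0.4)
  expect_equal(p[17, 17], 0.7)
  expect_lt(max(abs(p[p != 0] - 0.7)), 1e-12)

  # defocus (Noll 4): sqrt(3) (2 rho^2 - 1), evaluated directly on the grid
  h <- 65
  z4 <- zernike_phase(c("4" = 1), h, h, pitch = 0.4)
  kx <- (2 * pi / (h * 0.4)) * seq(-32, 32)
  KX <- matrix(kx, h, h, byrow = TRUE); KY <- matrix(kx, h, h)
  rho <- sqrt(KX^2 + KY^2) / (pi / 0.4)
  direct <- sqrt(3) * (2 * rho^2 - 1) * (rho <= 1)
  expect_lt(max(abs(z4 - direct)), 1e-10)

  expect_error(zernike_phase(c("0" = 1), 16, 16, pitch = 0.4), "unknown")
  expect_error(zernike_phase(c("nope" = 1), 16, 16, pitch = 0.4), "unknown")
  expect_error(zernike_phase(c("4" = 1), 16, 16, pitch = 0.4,
                             pupil_radius = 2 * pi / 0.4), "Nyquist")
})

test_that("phantom validation rejects out-of-field particles and missing seeds", {
  expect_error(phantom_spec(grid_size = 32, pitch = 0.4,
                            particles = data.frame(x_um = 50, y_um = 2, amplitude = 1)),
               "field of view")
  expect_error(phantom_spec(grid_size = 32, pitch = 0.4, noise_sigma = 0.1),
               "seed")
  expect_error(phantom_spec(grid_size = 32, pitch = 0.4, psf_magnitude_fwhm = -1))
})
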