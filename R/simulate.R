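#' Synthetic coherent-imaging phantom specification
#'
#' Describes an en face plane of point scatterers imaged with a
#' Gaussian-magnitude coherent point spread function, together with an
#' optional phase-stable weak-scattering background, per-frame i.i.d.
#' circular complex Gaussian system noise, optional pupil-phase aberrations,
#' and optional inter-frame bulk shift / global phase drift.  This is the
#' statistical structure a beam-scanned OCT acquisition of a sparse
#' scattering phantom assumes: the particles and the background are
#' phase-stable across repeated acquisitions while the system noise
#' decorrelates from frame to frame.
#'
#' @param grid_size integer (H, W) in pixels (scalar means square).
#' @param pitch pixel pitch, micrometres per pixel (default 0.4).
#' @param particles data frame or matrix with columns `x_um`, `y_um`,
#'   `amplitude`: scatterer positions (may be subpixel) and magnitudes.
#'   Positions use the convention `x = (col - 1) * pitch`,
#'   `y = (row - 1) * pitch` and must lie inside the field of view.
#' @param psf_magnitude_fwhm full width at half maximum of the *magnitude*
#'   PSF, micrometres (default 2.1).
#' @param background_sigma per-pixel standard deviation (amplitude units,
#'   `E|z|^2 = sigma^2`) of the frozen circular Gaussian scatterer field that
#'   models single-scattering background; identical across frames.
#' @param noise_sigma per-pixel standard deviation (amplitude units) of the
#'   per-frame i.i.d. circular complex Gaussian system noise.
#' @param zernike_coeffs named numeric vector of pupil-phase aberration
#'   coefficients in radians; names are Noll indices (see [zernike_phase()]).
#' @param pupil_radius pupil normalization radius for the aberration phase,
#'   rad/um; defaults to the Nyquist radial frequency `pi / pitch`.
#' @param frame_shift optional N x 2 matrix of per-frame bulk shifts
#'   (dx_um, dy_um).
#' @param frame_phase optional length-N vector of per-frame global phases
#'   (radians).
#' @param seed integer RNG seed; required explicitly whenever
#'   `background_sigma > 0` or `noise_sigma > 0` (no hidden global RNG).
#' @return An object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(grid_size = c(256L, 256L), pitch = 0.4,
                         particles = NULL, psf_magnitude_fwhm = 2.1,
                         background_sigma = 0, noise_sigma = 0,
                         zernike_coeffs = NULL, pupil_radius = NULL,
                         frame_shift = NULL, frame_phase = NULL,
                         seed = NULL) {
  if (length(grid_size) == 1L) grid_size <- rep(grid_size, 2L)
  grid_size <- as.integer(grid_size)
  if (any(grid_size < 4L)) stop("grid_size too small")
  if (pitch <= 0) stop("pitch must be positive")
  if (psf_magnitude_fwhm <= 0) stop("psf_magnitude_fwhm must be positive")
  if (background_sigma < 0 || noise_sigma < 0) stop("sigmas must be >= 0")
  if (!is.null(particles)) {
    particles <- as.data.frame(particles)
    if (!all(c("x_um", "y_um", "amplitude") %in% names(particles)))
      stop("`particles` needs columns x_um, y_um, amplitude")
    fov_x <- (grid_size[2L] - 1L) * pitch
    fov_y <- (grid_size[1L] - 1L) * pitch
    if (any(particles$x_um < 0 | particles$x_um > fov_x |
            particles$y_um < 0 | particles$y_um > fov_y))
      stop("particle coordinates must lie inside the field of view")
  }
  if ((background_sigma > 0 || noise_sigma > 0) && is.null(seed))
    stop("`seed` must be given explicitly when the phantom is stochastic")
  if (!is.null(frame_shift)) frame_shift <- as.matrix(frame_shift)
  structure(list(grid_size = grid_size, pitch = pitch, particles = particles,
                 psf_magnitude_fwhm = psf_magnitude_fwhm,
                 background_sigma = background_sigma, noise_sigma = noise_sigma,
                 zernike_coeffs = zernike_coeffs,
                 pupil_radius = if (is.null(pupil_radius)) pi / pitch else pupil_radius,
                 frame_shift = frame_shift, frame_phase = frame_phase,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "phantom_spec")
}

#' Gaussian amplitude transfer function of a coherent Gaussian beam
#'
#' DC-centered radially symmetric Gaussian amplitude transfer `H(kr)` with
#' `H(0) = 1`, parameterized so that the magnitude of the space-domain PSF
#' has the requested FWHM.  For a magnitude PSF
#' `|h(r)| = exp(-r^2 / (2 sigma_x^2))` with
#' `sigma_x = fwhm / (2 sqrt(2 log 2))`, the amplitude spectrum is
#' `H(kr) = exp(-sigma_x^2 kr^2 / 2)`, i.e. `sigma_k = 1 / sigma_x`.
#'
#' @param psf_magnitude_fwhm magnitude-PSF FWHM, micrometres.
#' @param h,w grid dimensions in pixels.
#' @param pitch pixel pitch, micrometres per pixel.
#' @return Real H x W matrix over the DC-centered (kx, ky) grid.
#' @export
gaussian_transfer <- function(psf_magnitude_fwhm, h, w = h, pitch = 0.4) {
  if (psf_magnitude_fwhm <= 0) stop("psf_magnitude_fwhm must be positive")
  if (psf_magnitude_fwhm < 2 * pitch)
    warning("PSF magnitude FWHM below 2 pixels: PSF is undersampled")
  sigma_x <- psf_magnitude_fwhm / (2 * sqrt(2 * log(2)))
  g <- k_grid(h, w, pitch)
  exp(-(sigma_x^2 / 2) * g$KR^2)
}

# sigma_k (rad/um) of the amplitude transfer for a magnitude-PSF FWHM (um)
fwhm_to_sigma_k <- function(fwhm) (2 * sqrt(2 * log(2))) / fwhm

# ---- Zernike polynomials (Noll indexing) -----------------------------------

# Noll index -> (n, m); sign of m encodes cos (m >= 0, even j) vs sin
# (m < 0, odd j).
noll_to_nm <- function(j) {
  if (j < 1 || j != round(j)) stop(sprintf("unknown Zernike (Noll) index: %s", j))
  n <- 0L
  while ((n + 1L) * (n + 2L) / 2 < j) n <- n + 1L
  i <- j - n * (n + 1L) / 2          # 1-based rank within order n
  m_abs <- if (n %% 2L == 0L) 2L * floor(i / 2) else 2L * floor((i - 1) / 2) + 1L
  m <- if (j %% 2L == 0L) m_abs else -m_abs
  if (m_abs == 0L) m <- 0L
  c(n = n, m = as.integer(m))
}

# Radial polynomial R_n^|m|(rho)
zernike_radial <- function(n, m_abs, rho) {
  out <- 0
  for (k in 0:((n - m_abs) / 2)) {
    out <- out + (-1)^k * factorial(n - k) /
      (factorial(k) * factorial((n + m_abs) / 2 - k) * factorial((n - m_abs) / 2 - k)) *
      rho^(n - 2 * k)
  }
  out
}

#' Pupil-phase aberration from Zernike coefficients
#'
#' Sum of Noll-normalized Zernike polynomials evaluated on the normalized
#' pupil coordinate `rho = kr / pupil_radius`, zero outside `rho > 1`.
#' Normalization follows Noll: piston is 1, and
#' `Z_j = sqrt(n + 1) R_n^0` for m = 0,
#' `sqrt(2 (n + 1)) R_n^|m| cos(|m| theta)` for even j,
#' `sqrt(2 (n + 1)) R_n^|m| sin(|m| theta)` for odd j.
#'
#' @param coeffs named numeric vector; names are Noll indices, values are
#'   coefficients in radians (e.g. `c("4" = 1.5)` for defocus).
#' @param h,w grid dimensions in pixels.
#' @param pitch pixel pitch, micrometres per pixel.
#' @param pupil_radius pupil edge in rad/um; must not exceed the Nyquist
#'   radial frequency.  Default `pi / pitch`.
#' @return Real H x W phase matrix (radians) on the DC-centered grid.
#' @export
zernike_phase <- function(coeffs, h, w = h, pitch = 0.4, pupil_radius = NULL) {
  g <- k_grid(h, w, pitch)
  if (is.null(pupil_radius)) pupil_radius <- pi / pitch
  if (pupil_radius > g$nyquist_kr + 1e-9)
    stop("pupil_radius exceeds the Nyquist radial spatial frequency")
  phase <- matrix(0, h, w)
  if (is.null(coeffs) || length(coeffs) == 0L) return(phase)
  if (is.null(names(coeffs))) stop("`coeffs` must be named by Noll index")
  rho <- g$KR / pupil_radius
  theta <- atan2(g$KY, g$KX)
  inside <- rho <= 1
  for (nm in names(coeffs)) {
    j <- suppressWarnings(as.numeric(nm))
    if (is.na(j)) stop(sprintf("unknown Zernike (Noll) index: %s", nm))
    idx <- noll_to_nm(j)
    n <- idx[["n"]]; m <- idx[["m"]]; m_abs <- abs(m)
    rad <- zernike_radial(n, m_abs, rho)
    z <- if (m == 0L) sqrt(n + 1) * rad
         else if (m > 0L) sqrt(2 * (n + 1)) * rad * cos(m_abs * theta)
         else sqrt(2 * (n + 1)) * rad * sin(m_abs * theta)
    phase <- phase + coeffs[[nm]] * z * inside
  }
  phase
}

# Complex circular Gaussian matrix with E|z|^2 = sigma^2 per element.
# Caller is responsible for seeding.
circular_gaussian <- function(h, w, sigma) {
  matrix(complex(real = stats::rnorm(h * w, sd = sigma / sqrt(2)),
                 imaginary = stats::rnorm(h * w, sd = sigma / sqrt(2))), h, w)
}

# DC-centered object spectrum of the point scatterers: subpixel placement by
# spectral phase ramps, PSF normalized to unit peak magnitude.
particle_spectrum <- function(spec, g, H) {
  P <- matrix(0 + 0i, spec$grid_size[1L], spec$grid_size[2L])
  if (is.null(spec$particles) || nrow(spec$particles) == 0L) return(P)
  for (i in seq_len(nrow(spec$particles))) {
    p <- spec$particles[i, ]
    P <- P + p$amplitude * exp(-1i * (g$KX * p$x_um + g$KY * p$y_um))
  }
  P / mean(H)   # unit-peak PSF: space-domain peak magnitude == amplitude
}

#' Synthesize a stack of coherent en face field frames
#'
#' Each frame is
#' `IFFT( (P(k) + FFT(bg)) * H(k) * exp(i Phi_ab(k)) * ramp_n(k) * exp(i phi_n) ) + noise_n`,
#' where `P` is the particle spectrum (subpixel positions via phase ramps,
#' PSF normalized to unit peak magnitude so a particle of amplitude `a` has
#' space-domain peak magnitude `a`), `bg` the frozen background scatterer
#' field (identical across frames), `H` the Gaussian amplitude transfer,
#' `Phi_ab` the aberration phase, `ramp_n`/`phi_n` the optional per-frame
#' bulk shift and global phase, and `noise_n` fresh i.i.d. circular complex
#' Gaussian noise.  Deterministic given `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @param n_frames number of frames N.
#' @return A [field_stack()] with generator provenance recorded.
#' @export
synthesize_stack <- function(spec, n_frames) {
  if (!inherits(spec, "phantom_spec")) stop("`spec` must be a phantom_spec")
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L) stop("n_frames must be >= 1")
  h <- spec$grid_size[1L]; w <- spec$grid_size[2L]
  if (!is.null(spec$frame_shift) && nrow(spec$frame_shift) != n_frames)
    stop("frame_shift must have one row per frame")
  if (!is.null(spec$frame_phase) && length(spec$frame_phase) != n_frames)
    stop("frame_phase must have one entry per frame")
  g <- k_grid(h, w, spec$pitch)
  H <- gaussian_transfer(spec$psf_magnitude_fwhm, h, w, spec$pitch)
  phi_ab <- if (is.null(spec$zernike_coeffs)) 0 else
    zernike_phase(spec$zernike_coeffs, h, w, spec$pitch, spec$pupil_radius)

  gen <- function() {
    P <- particle_spectrum(spec, g, H)
    if (spec$background_sigma > 0) {
      bg <- circular_gaussian(h, w, spec$background_sigma)
      P <- P + fftshift2(fft2(bg))
    }
    S <- P * H * exp(1i * phi_ab)
    frames <- vector("list", n_frames)
    for (n in seq_len(n_frames)) {
      Sn <- S
      if (!is.null(spec$frame_shift)) {
        d <- spec$frame_shift[n, ]
        Sn <- Sn * exp(-1i * (g$KX * d[1L] + g$KY * d[2L]))
      }
      if (!is.null(spec$frame_phase)) Sn <- Sn * exp(1i * spec$frame_phase[n])
      f <- ifft2(ifftshift2(Sn))
      if (spec$noise_sigma > 0) f <- f + circular_gaussian(h, w, spec$noise_sigma)
      frames[[n]] <- f
    }
    frames
  }
  frames <- if (is.null(spec$seed)) gen() else withr::with_seed(spec$seed, gen())
  field_stack(frames, pitch_x = spec$pitch,
              provenance = list(generator = "synthesize_stack",
                                seed = spec$seed, n_frames = n_frames,
                                psf_magnitude_fwhm = spec$psf_magnitude_fwhm,
                                noise_sigma = spec$noise_sigma,
                                background_sigma = spec$background_sigma))
}

#' Synthesize a paired noise-image stack
#'
#' Frames of i.i.d. circular complex Gaussian system noise, independent
#' across frames and pixels, with uniform (flat) magnitude spectrum: the
#' computational analog of imaging an empty sample dish.
#'
#' @param h,w grid dimensions in pixels.
#' @param pitch pixel pitch, micrometres per pixel.
#' @param noise_sigma per-pixel amplitude sd (`E|z|^2 = noise_sigma^2`).
#' @param n_frames number of frames.
#' @param seed integer RNG seed.
#' @return A [field_stack()].
#' @export
synthesize_noise_stack <- function(h, w = h, pitch = 0.4, noise_sigma = 1,
                                   n_frames = 1L, seed) {
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  n_frames <- as.integer(n_frames)
  frames <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_frames), function(i) {
      if (noise_sigma == 0) matrix(0 + 0i, h, w) else circular_gaussian(h, w, noise_sigma)
    })
  })
  field_stack(frames, pitch_x = pitch,
              provenance = list(generator = "synthesize_noise_stack",
                                seed = as.integer(seed), noise_sigma = noise_sigma,
                                n_frames = n_frames))
}
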