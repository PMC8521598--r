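#' Paraxial computational refocus
#'
#' Multiplies the transverse spectrum by the conjugate paraxial defocus
#' phase `exp(-i z (kx^2 + ky^2) / (2 k0))` with `k0 = 2 pi n / lambda`:
#' the single defocus term of computational adaptive optics.  A pure phase
#' filter, so total energy is preserved.
#'
#' @param field complex [enface_field()].
#' @param defocus_um defocus distance z, micrometres (signed).
#' @param wavelength_um central wavelength, micrometres.
#' @param refractive_index medium index (default 1).
#' @return Refocused [enface_field()].
#' @export
refocus <- function(field, defocus_um, wavelength_um, refractive_index = 1) {
  if (wavelength_um <= 0) stop("wavelength must be positive")
  field <- as_enface(field, pitch_x = NULL)
  k0 <- 2 * pi * refractive_index / wavelength_um
  # paraxial validity: quadratic phase should vary slowly per spectral bin
  g <- k_grid(nrow(field$values), ncol(field$values), field$pitch_x, field$pitch_y)
  if (abs(defocus_um) * g$nyquist_kr * max(g$dk_x, g$dk_y) / k0 > pi)
    warning("large defocus: paraxial quadratic phase is undersampled at the grid edge")
  ph <- exp(-1i * defocus_um * (g$KX^2 + g$KY^2) / (2 * k0))
  enface_field(ifft2(ifftshift2(fftshift2(fft2(field$values)) * ph)),
               field$pitch_x, field$pitch_y)
}

#' Fit the Gaussian magnitude-spectrum model
#'
#' Fits the radial power profile of the coherent-average image to the
#' squared Gaussian amplitude model
#' `P(kr) = A^2 exp(-kr^2 / sigma_k^2)` by linear least squares of
#' `log(power)` against `kr^2`, restricted to radial bins whose power
#' exceeds the noise floor by a configurable margin.  The noise floor is the
#' mean noise power per spectral bin of the paired noise image.
#'
#' @param avg_field coherent-average [enface_field()] containing signal
#'   above the noise floor at DC.
#' @param noise_field paired noise field on the same grid, or `NULL` when
#'   noise-free.
#' @param bin_width radial bin width for the profile, rad/um; default one
#'   spectral bin (`dk`).
#' @param margin power factor above the noise floor a bin must reach to
#'   enter the fit (default 3).
#' @return A list of class `"spectrum_model"`: `sigma_k` (rad/um),
#'   `dc_amplitude`, `noise_floor_power`, `fit_range` (kr range used),
#'   `n_bins_used`.
#' @export
fit_spectrum_model <- function(avg_field, noise_field = NULL, bin_width = NULL,
                               margin = 3) {
  avg_field <- as_enface(avg_field, pitch_x = NULL)
  s <- to_spectrum(avg_field)
  if (is.null(bin_width)) bin_width <- max(s$dk_x, s$dk_y)
  prof <- radial_power_profile(s, bin_width)
  noise_floor <- if (is.null(noise_field)) 0 else
    mean(Mod(fft2(field_values(noise_field)))^2)
  floor_thresh <- max(noise_floor * margin, max(prof$power) * 1e-9)
  use <- prof$power > floor_thresh
  if (sum(use) < 3L)
    stop("spectrum model fit error: fewer than 3 radial bins above the noise floor")
  x <- prof$kr_center[use]^2
  y <- log(prof$power[use])
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- fit$coefficients[2L]
  if (!is.finite(slope) || slope >= 0)
    stop("spectrum model fit error: radial power profile is not decreasing")
  structure(list(sigma_k = sqrt(-1 / slope),
                 dc_amplitude = sqrt(exp(fit$coefficients[1L])),
                 noise_floor_power = noise_floor,
                 fit_range = range(prof$kr_center[use]),
                 n_bins_used = sum(use)),
            class = "spectrum_model")
}

#' Build a bandwidth-expansion mask
#'
#' The Gaussian-ratio magnitude mask: with the fitted amplitude model
#' `M_0(kr) = exp(-kr^2 / (2 sigma_k^2))` (up to scale) and the expanded
#' model `M_b` with `sigma_k * b`, the gain is
#' `M_b / M_0 = exp[(kr^2 / (2 sigma_k^2)) (1 - 1/b^2)]`, clipped at a gain
#' cap (amplitude dB).  The mask is defined on the full grid including the
#' corners (the radial law is simply continued beyond the axis Nyquist).
#' `b = 1` gives a unit mask.
#'
#' Expansion can only raise signal that sits above the noise floor, so when
#' the model carries a measured floor (`noise_floor_power > 0`) the cap is
#' additionally limited to the gain reached at the radial frequency where
#' the model amplitude meets the floor,
#' `(dc_amplitude / sqrt(noise_floor_power))^(1 - 1/b^2)`: beyond that point
#' there is no recoverable signal and further amplification would only
#' raise noise.  `max_gain_db` remains an upper bound in all cases
#' (`Inf` disables it, appropriate for noise-free data).
#'
#' @param model a `"spectrum_model"` (at minimum `sigma_k`; optionally
#'   `dc_amplitude` and `noise_floor_power` for the floor-aware cap).
#' @param b bandwidth-expansion factor, `b >= 1`.
#' @param h,w grid dimensions the mask is built for.
#' @param pitch_x,pitch_y pixel pitch of the target grid, um/pixel.
#' @param max_gain_db amplitude gain cap in dB (default 40, i.e. 100x).
#' @param floor_limited logical: apply the noise-floor-aware cap when the
#'   model provides a floor (default TRUE).
#' @return A list of class `"be_mask"`: `gain` (real H x W, DC-centered),
#'   `be_factor`, `max_gain_db` (the effective cap used), `sigma_k`.
#' @export
build_be_mask <- function(model, b, h, w = h, pitch_x = 0.4, pitch_y = pitch_x,
                          max_gain_db = 40, floor_limited = TRUE) {
  if (b < 1) stop("BE factor must be >= 1")
  sigma_k <- model$sigma_k
  if (is.null(sigma_k) || sigma_k <= 0) stop("model must provide sigma_k > 0")
  cap_db <- max_gain_db
  if (floor_limited && !is.null(model$noise_floor_power) &&
      is.finite(model$noise_floor_power) && model$noise_floor_power > 0 &&
      !is.null(model$dc_amplitude)) {
    floor_db <- (1 - 1 / b^2) *
      10 * log10(model$dc_amplitude^2 / model$noise_floor_power)
    cap_db <- max(0, min(cap_db, floor_db))
  }
  g <- k_grid(h, w, pitch_x, pitch_y)
  gain <- exp((g$KR^2 / (2 * sigma_k^2)) * (1 - 1 / b^2))
  gain <- pmin(gain, 10^(cap_db / 20))
  structure(list(gain = gain, be_factor = b, max_gain_db = cap_db,
                 sigma_k = sigma_k), class = "be_mask")
}

#' Apply a bandwidth-expansion mask to a field
#'
#' Multiplies the DC-centered spectrum by the mask gain and transforms back:
#' magnitude-based deconvolution that raises signal at higher transverse
#' spatial frequencies.
#'
#' @param field complex [enface_field()].
#' @param mask a [build_be_mask()] result (its gain must match the field
#'   grid).
#' @return Bandwidth-expanded [enface_field()].
#' @export
apply_be <- function(field, mask) {
  field <- as_enface(field, pitch_x = NULL)
  if (!identical(dim(mask$gain), dim(field$values)))
    stop("mask grid does not match field grid")
  enface_field(ifft2(ifftshift2(fftshift2(fft2(field$values)) * mask$gain)),
               field$pitch_x, field$pitch_y)
}

#' Zero-pad upsampling in the spatial-frequency domain
#'
#' Embeds the DC-centered spectrum at the center of a `factor`-times larger
#' zero array and transforms back, yielding the band-limited (sinc)
#' interpolation of the field on a grid with pitch `pitch / factor`.
#' Original samples are reproduced exactly at the original pixel locations,
#' so total energy in the physical (integral) sense — pixel area times
#' squared magnitude — is preserved.  Implemented to facilitate resolution
#' measurement by curve fitting to the PSF.
#'
#' @param field complex [enface_field()].
#' @param factor integer upsampling factor, `>= 1`.
#' @return [enface_field()] on the finer grid.
#' @export
zeropad_upsample <- function(field, factor) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be >= 1")
  field <- as_enface(field, pitch_x = NULL)
  if (factor == 1L) return(field)
  v <- field$values
  h <- nrow(v); w <- ncol(v)
  S <- fftshift2(fft2(v))
  big <- matrix(0 + 0i, factor * h, factor * w)
  r0 <- floor(factor * h / 2) - floor(h / 2)
  c0 <- floor(factor * w / 2) - floor(w / 2)
  big[r0 + seq_len(h), c0 + seq_len(w)] <- S
  up <- stats::fft(ifftshift2(big), inverse = TRUE) / (h * w)  # value-preserving
  enface_field(up, field$pitch_x / factor, field$pitch_y / factor)
}
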