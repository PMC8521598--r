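#' Transverse spatial-frequency spectrum of a field
#'
#' DC-centered 2D discrete Fourier transform of a complex en face field.
#' Under this normalization Parseval's identity reads
#' `sum(|field|^2) == sum(|spectrum|^2) / (H * W)`.
#'
#' @param field an [enface_field()] (or complex matrix plus `pitch_x`,
#'   `pitch_y`).
#' @param pitch_x,pitch_y pitch when `field` is a bare matrix.
#' @return An object of class `"spectrum2d"`: list with `values` (complex,
#'   DC at `[floor(H/2)+1, floor(W/2)+1]`), axes `kx`, `ky` (rad/um), bin
#'   widths `dk_x`, `dk_y`, `nyquist_kr`, and the originating pitch.
#' @export
to_spectrum <- function(field, pitch_x = NULL, pitch_y = pitch_x) {
  field <- as_enface(field, pitch_x = pitch_x, pitch_y = pitch_y)
  v <- field$values
  if (any(!is.finite(Re(v)) | !is.finite(Im(v)))) stop("field must be finite")
  g <- k_grid(nrow(v), ncol(v), field$pitch_x, field$pitch_y)
  structure(list(values = fftshift2(fft2(v)), kx = g$kx, ky = g$ky,
                 dk_x = g$dk_x, dk_y = g$dk_y, nyquist_kr = g$nyquist_kr,
                 pitch_x = field$pitch_x, pitch_y = field$pitch_y,
                 dc_row = g$dc_row, dc_col = g$dc_col),
            class = "spectrum2d")
}

#' Inverse of [to_spectrum()]
#' @param spec a `"spectrum2d"`.
#' @return The [enface_field()] whose spectrum is `spec`.
#' @export
from_spectrum <- function(spec) {
  enface_field(ifft2(ifftshift2(spec$values)), spec$pitch_x, spec$pitch_y)
}

#' @export
print.spectrum2d <- function(x, ...) {
  cat(sprintf("<spectrum2d> %d x %d, dk = %.4g x %.4g rad/um, Nyquist kr = %.4g rad/um\n",
              nrow(x$values), ncol(x$values), x$dk_x, x$dk_y, x$nyquist_kr))
  invisible(x)
}

# Radial |k| matrix of a spectrum2d
spectrum_kr <- function(spec) {
  h <- nrow(spec$values); w <- ncol(spec$values)
  KX <- matrix(spec$kx, h, w, byrow = TRUE)
  KY <- matrix(spec$ky, h, w)
  sqrt(KX^2 + KY^2)
}

#' Radial power profile of a 2D spectrum
#'
#' Mean power `|spectrum|^2` in annular bins of width `bin_width` from
#' `kr = 0` to the Nyquist radial frequency.  For a sparse-scatterer image
#' the profile decreases (following the squared Gaussian transfer) to a
#' plateau at the system noise floor.
#'
#' @param spec a `"spectrum2d"` (from [to_spectrum()]).
#' @param bin_width radial bin width, rad/um (default 0.1).
#' @return Data frame with `kr_center` (rad/um), `power` (mean power per
#'   spectral bin), and `n_bins` (number of spectral samples in the
#'   annulus).  Annuli with no samples are dropped.
#' @export
radial_power_profile <- function(spec, bin_width = 0.1) {
  if (bin_width <= 0) stop("bin_width must be positive")
  kr <- spectrum_kr(spec)
  pow <- Mod(spec$values)^2
  keep <- kr <= spec$nyquist_kr
  idx <- pmin(floor(kr[keep] / bin_width), ceiling(spec$nyquist_kr / bin_width) - 1L)
  agg <- tapply(pow[keep], idx, mean)
  cnt <- tapply(pow[keep], idx, length)
  centers <- (as.numeric(names(agg)) + 0.5) * bin_width
  data.frame(kr_center = centers, power = as.numeric(agg),
             n_bins = as.integer(cnt))
}

#' Spatial-frequency dynamic range
#'
#' Ratio, in dB, of the signal power at DC (`kr = 0`, the single center bin
#' of the signal spectrum) to the mean noise power across the entire
#' transverse spatial-frequency domain of the paired noise image.  Coherent
#' averaging over N frames suppresses the noise floor by a factor N and so
#' raises the DR by `10 log10(N)` (20 dB at N = 100).
#'
#' @param signal_field complex field with sample signal ([enface_field()]).
#' @param noise_field paired signal-free noise field on the same grid.
#' @return A list of class `"dr_result"`: `dr_db`, `dc_power`,
#'   `mean_noise_power`.
#' @export
dynamic_range <- function(signal_field, noise_field) {
  stopifnot_same_grid(signal_field, noise_field)
  if (!inherits(signal_field, "enface_field")) {
    if (inherits(noise_field, "enface_field"))
      signal_field <- as_enface(signal_field, like = noise_field)
    else stop("at least one input must be an enface_field carrying pitch")
  }
  s <- to_spectrum(signal_field)
  dc_power <- Mod(s$values[s$dc_row, s$dc_col])^2
  if (dc_power == 0) stop("degenerate signal: zero power at DC")
  mean_noise_power <- mean(Mod(fft2(field_values(noise_field)))^2)
  structure(list(dr_db = 10 * log10(dc_power / mean_noise_power),
                 dc_power = dc_power, mean_noise_power = mean_noise_power),
            class = "dr_result")
}

#' Phase-correlation analysis configuration
#'
#' Parameters of the phase-decorrelation spectrum: window cropped around a
#' particle, sliding kernel for the local phase standard deviation, radial
#' bin width, and the decorrelation threshold.
#'
#' @param window square crop size around the particle, pixels (odd;
#'   default 243).
#' @param kernel sliding kernel size, pixels (odd; default 3).
#' @param bin_width radial bin width, rad/um (default 0.1).
#' @param threshold phase decorrelation threshold, radians (default 0.2).
#' @return A list of class `"phase_corr_config"`.
#' @export
phase_corr_config <- function(window = 243L, kernel = 3L, bin_width = 0.1,
                              threshold = 0.2) {
  window <- as.integer(window); kernel <- as.integer(kernel)
  if (window %% 2L == 0L) stop("window must be odd")
  if (kernel %% 2L == 0L) stop("kernel must be odd")
  if (threshold <= 0) stop("threshold must be positive")
  if (bin_width <= 0) stop("bin_width must be positive")
  structure(list(window = window, kernel = kernel, bin_width = bin_width,
                 threshold = threshold), class = "phase_corr_config")
}

# Local circular standard deviation of a phase matrix over a square sliding
# kernel, truncated (not padded) at the edges: the circular mean direction of
# each neighborhood is subtracted before taking the RMS of the wrapped
# residuals, so +/- pi crossings of a smooth phase are not spuriously
# flagged as decorrelation.
local_circular_sd <- function(theta, kernel = 3L) {
  h <- nrow(theta); w <- ncol(theta)
  r <- (kernel - 1L) %/% 2L
  offs <- expand.grid(dy = -r:r, dx = -r:r)
  shift_na <- function(m, dy, dx) {
    out <- matrix(NA_real_, h, w)
    ys <- max(1L, 1L + dy):min(h, h + dy)
    xs <- max(1L, 1L + dx):min(w, w + dx)
    out[ys, xs] <- m[ys - dy, xs - dx]
    out
  }
  S <- matrix(0, h, w); C <- matrix(0, h, w); cnt <- matrix(0L, h, w)
  sin_t <- sin(theta); cos_t <- cos(theta)
  shifted <- vector("list", nrow(offs))
  for (i in seq_len(nrow(offs))) {
    th <- shift_na(theta, offs$dy[i], offs$dx[i])
    shifted[[i]] <- th
    ok <- !is.na(th)
    S[ok] <- S[ok] + sin(th[ok]); C[ok] <- C[ok] + cos(th[ok])
    cnt <- cnt + ok
  }
  mu <- atan2(S, C)
  acc <- matrix(0, h, w)
  for (i in seq_len(nrow(offs))) {
    th <- shifted[[i]]
    ok <- !is.na(th)
    d <- (th[ok] - mu[ok] + pi) %% (2 * pi) - pi
    acc[ok] <- acc[ok] + d^2
  }
  sqrt(acc / cnt)
}

#' Phase-correlation limit of a point scatterer
#'
#' The largest radial spatial frequency at which the spectral phase of the
#' signal from a point scatterer remains correlated.  A window is cropped
#' around the particle, the phase spectrum is taken as the angle of its 2D
#' transform, the local (circular) standard deviation over a small sliding
#' kernel forms the phase-decorrelation spectrum, and that spectrum is
#' averaged in radial bins from 0 to the Nyquist frequency: the limit is the
#' center of the first bin whose mean exceeds the threshold (0.2 rad by
#' default).  If no bin exceeds it, the last bin center is returned
#' (Nyquist-limited).
#'
#' @param field complex [enface_field()].
#' @param particle_center integer `(row, col)` pixel indices of the particle.
#' @param cfg a [phase_corr_config()].
#' @return The limiting `kr` (rad/um).
#' @export
phase_correlation_limit <- function(field, particle_center,
                                    cfg = phase_corr_config()) {
  field <- as_enface(field, pitch_x = NULL)
  v <- field$values
  r <- (cfg$window - 1L) %/% 2L
  pr <- as.integer(particle_center[1L]); pc <- as.integer(particle_center[2L])
  if (pr - r < 1L || pr + r > nrow(v) || pc - r < 1L || pc + r > ncol(v))
    stop("particle too close to the border: window does not fit inside the field")
  win <- v[(pr - r):(pr + r), (pc - r):(pc + r)]
  # the window center is the phase origin, so a particle at the center has a
  # flat (ramp-free) phase spectrum
  theta <- Arg(fftshift2(fft2(ifftshift2(win))))
  decorr <- local_circular_sd(theta, cfg$kernel)
  g <- k_grid(cfg$window, cfg$window, field$pitch_x, field$pitch_y)
  nb <- ceiling(g$nyquist_kr / cfg$bin_width)
  keep <- g$KR <= g$nyquist_kr
  idx <- pmin(floor(g$KR[keep] / cfg$bin_width), nb - 1L)
  bin_mean <- tapply(decorr[keep], idx, mean)
  centers <- (as.numeric(names(bin_mean)) + 0.5) * cfg$bin_width
  over <- which(bin_mean > cfg$threshold)
  if (length(over) == 0L) centers[length(centers)] else centers[over[1L]]
}
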