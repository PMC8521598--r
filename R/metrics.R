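#' Detect point-scatterer particles in a magnitude image
#'
#' Local maxima of the magnitude image (or the maximum-intensity projection
#' over a few depth planes) above a peak threshold, at least one fitting
#' window apart.  When two candidate peaks fall closer than `min_separation`
#' the brighter one wins and the pair is merged to a single detection.
#' Detections are returned in deterministic descending-peak order.
#'
#' @param x magnitude matrix, complex matrix/[enface_field()] (modulus is
#'   taken), 3D array (H, W, D; the MIP over depth is used), or a list of
#'   such planes.
#' @param peak_threshold absolute magnitude threshold; default
#'   `threshold_factor` times the median magnitude.
#' @param threshold_factor multiple of median magnitude for the default
#'   threshold (default 10).
#' @param min_separation minimum center-to-center distance in pixels
#'   (default `window`).
#' @param window fitting-window size in pixels used for the default
#'   separation (default 73).
#' @return Data frame with `row`, `col`, `peak`, ordered by decreasing peak.
#' @export
detect_particles <- function(x, peak_threshold = NULL, threshold_factor = 10,
                             min_separation = NULL, window = 73L) {
  if (is.list(x) && !inherits(x, "enface_field"))
    x <- simplify2array(lapply(x, function(p) Mod(field_values(p))))
  mag <- if (is.array(x) && length(dim(x)) == 3L) apply(Mod(x), c(1, 2), max)
         else Mod(field_values(x))
  if (is.null(min_separation)) min_separation <- window
  h <- nrow(mag); w <- ncol(mag)
  if (max(mag) == 0)
    return(data.frame(row = integer(), col = integer(), peak = numeric()))
  if (is.null(peak_threshold)) {
    # relative floor guards against numerically-zero medians of noise-free
    # synthetic images, where round-off ripples would otherwise qualify
    peak_threshold <- max(threshold_factor * stats::median(mag), 1e-3 * max(mag))
  }
  if (peak_threshold <= 0) stop("peak_threshold must be positive")
  if (max(mag) < peak_threshold)
    return(data.frame(row = integer(), col = integer(), peak = numeric()))
  # 8-neighbor local maxima above threshold
  pad <- matrix(-Inf, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mag
  is_max <- mag >= peak_threshold
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    is_max <- is_max & (mag >= pad[(2:(h + 1L)) + dy, (2:(w + 1L)) + dx])
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(data.frame(row = integer(), col = integer(), peak = numeric()))
  peaks <- mag[idx]
  ord <- order(peaks, decreasing = TRUE)
  idx <- idx[ord, , drop = FALSE]; peaks <- peaks[ord]
  keep_r <- numeric(); keep_c <- numeric(); keep_p <- numeric()
  for (i in seq_along(peaks)) {
    if (length(keep_r) == 0L ||
        all(sqrt((keep_r - idx[i, 1L])^2 + (keep_c - idx[i, 2L])^2) >= min_separation)) {
      keep_r <- c(keep_r, idx[i, 1L]); keep_c <- c(keep_c, idx[i, 2L])
      keep_p <- c(keep_p, peaks[i])
    }
  }
  data.frame(row = as.integer(keep_r), col = as.integer(keep_c), peak = keep_p)
}

# Bilinear interpolation of matrix m at fractional (row, col) positions.
bilinear <- function(m, rows, cols) {
  h <- nrow(m); w <- ncol(m)
  r0 <- pmax(1L, pmin(h - 1L, floor(rows))); c0 <- pmax(1L, pmin(w - 1L, floor(cols)))
  fr <- rows - r0; fc <- cols - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1L, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1L)] * (1 - fr) * fc +
    m[cbind(r0 + 1L, c0 + 1L)] * fr * fc
}

# Parabolic subpixel refinement of a local peak of magnitude matrix m.
refine_peak <- function(m, r, c) {
  h <- nrow(m); w <- ncol(m)
  sub <- function(ym, y0, yp) {
    den <- ym - 2 * y0 + yp
    if (den == 0) 0 else max(-0.5, min(0.5, 0.5 * (ym - yp) / den))
  }
  dr <- if (r > 1L && r < h) sub(m[r - 1L, c], m[r, c], m[r + 1L, c]) else 0
  dc <- if (c > 1L && c < w) sub(m[r, c - 1L], m[r, c], m[r, c + 1L]) else 0
  c(r + dr, c + dc)
}

#' Radial Gaussian fit of a point-spread function
#'
#' Crops a square window around the particle, extracts `n_angles`
#' equally-spaced full diameter profiles of the magnitude through the
#' (subpixel-refined) center by bilinear interpolation, and fits each
#' profile to a 1D Gaussian by linear least squares on the log magnitude
#' (a quadratic in the radial coordinate), using only samples above
#' `frac_threshold` of the profile peak to avoid log-of-noise bias.  The
#' per-angle fitted peaks and FWHMs are averaged.
#'
#' @param field [enface_field()] (typically upsampled; the pitch is taken
#'   from the field).
#' @param center `(row, col)` pixel indices of the particle (may be
#'   fractional; refined locally before profiling).
#' @param window profile window size, pixels (default 73; the profiles span
#'   the window diameter).
#' @param n_angles number of diameter profiles over `[0, pi)` (default 32).
#' @param frac_threshold fraction of the profile peak below which samples
#'   are excluded from the fit (default 0.2).
#' @param background_intensity background intensity used for the peak SBR;
#'   `NA` skips the SBR.
#' @return A list of class `"psf_measurement"`: `center_px`, `fwhm_um`,
#'   `fwhm_sd_um` (across angles), `peak_magnitude`, `peak_sbr_db`,
#'   `n_profiles`, `n_failed`, `fit_ok`.
#' @export
fit_psf <- function(field, center, window = 73L, n_angles = 32L,
                    frac_threshold = 0.2, background_intensity = NA_real_) {
  field <- as_enface(field, pitch_x = NULL)
  mag <- Mod(field$values)
  h <- nrow(mag); w <- ncol(mag)
  r <- (as.integer(window) - 1L) %/% 2L
  ci <- round(center)
  if (ci[1L] - r < 1 || ci[1L] + r > h || ci[2L] - r < 1 || ci[2L] + r > w)
    stop("fit window does not fit inside the field")
  # the peak may sit a few pixels off the nominal center (e.g. coma shifts
  # the PSF centroid as the bandwidth changes): search a small neighbourhood
  # before the subpixel refinement
  s <- max(3L, as.integer(window) %/% 16L)
  rows_s <- max(1L, ci[1L] - s):min(h, ci[1L] + s)
  cols_s <- max(1L, ci[2L] - s):min(w, ci[2L] + s)
  loc <- which(mag[rows_s, cols_s, drop = FALSE] ==
                 max(mag[rows_s, cols_s]), arr.ind = TRUE)[1L, ]
  ci <- c(rows_s[loc[1L]], cols_s[loc[2L]])
  ctr <- refine_peak(mag, as.integer(ci[1L]), as.integer(ci[2L]))
  pitch <- field$pitch_x
  if (abs(field$pitch_y - pitch) > 1e-12)
    stop("fit_psf assumes square pixels")
  t_px <- seq(-r, r, by = 1)          # radial sample offsets in pixels
  angles <- (seq_len(n_angles) - 1L) * pi / n_angles
  fwhms <- rep(NA_real_, n_angles); pks <- rep(NA_real_, n_angles)
  for (a in seq_len(n_angles)) {
    rows <- ctr[1L] + t_px * sin(angles[a])
    cols <- ctr[2L] + t_px * cos(angles[a])
    ok <- rows >= 1 & rows <= h & cols >= 1 & cols <= w
    p <- bilinear(mag, rows[ok], cols[ok])
    t_um <- t_px[ok] * pitch
    # fit only the contiguous main lobe around the center: samples above the
    # threshold elsewhere in the window (neighbours, noise speckle) must not
    # enter the Gaussian fit
    i0 <- which.min(abs(t_um))
    ref <- max(p[max(1L, i0 - 2L):min(length(p), i0 + 2L)])
    if (!is.finite(ref) || ref <= 0) next
    thr <- frac_threshold * ref
    left <- i0; while (left > 1L && is.finite(p[left - 1L]) && p[left - 1L] >= thr) left <- left - 1L
    right <- i0; while (right < length(p) && is.finite(p[right + 1L]) && p[right + 1L] >= thr) right <- right + 1L
    use <- seq.int(left, right)
    use <- use[is.finite(p[use]) & p[use] > 0]
    if (length(use) < 5L) next
    X <- cbind(1, t_um[use], t_um[use]^2)
    cf <- stats::lm.fit(X, log(p[use]))$coefficients
    if (!is.finite(cf[3L]) || cf[3L] >= 0) next
    sigma <- sqrt(-1 / (2 * cf[3L]))
    fwhms[a] <- 2 * sqrt(2 * log(2)) * sigma
    pks[a] <- exp(cf[1L] - cf[2L]^2 / (4 * cf[3L]))
  }
  n_failed <- sum(is.na(fwhms))
  fit_ok <- n_failed <= n_angles / 2
  fwhm <- mean(fwhms, na.rm = TRUE)
  peak <- mean(pks, na.rm = TRUE)
  structure(list(center_px = ctr,
                 fwhm_um = if (fit_ok) fwhm else NA_real_,
                 fwhm_sd_um = stats::sd(fwhms, na.rm = TRUE),
                 peak_magnitude = if (fit_ok) peak else NA_real_,
                 peak_sbr_db = if (fit_ok && is.finite(background_intensity))
                   10 * log10(peak^2 / background_intensity) else NA_real_,
                 n_profiles = as.integer(n_angles), n_failed = as.integer(n_failed),
                 fit_ok = fit_ok),
            class = "psf_measurement")
}

#' Aggregate PSF measurements into a resolution report
#'
#' Applies the aggregate-exclusion rule on the *baseline* (coherent-average,
#' pre-expansion) FWHM — particles whose baseline FWHM exceeds
#' `exclusion_fwhm_um` are excluded as air bubbles or particle aggregates —
#' then aggregates mean and standard deviation of FWHM and peak SBR, and
#' computes the resolution-enhancement (RE) factor
#' `mean(baseline FWHM) / mean(enhanced FWHM)` and the efficiency
#' `RE factor / BE factor`.
#'
#' @param measurements list of `"psf_measurement"` objects (post-expansion),
#'   or a numeric vector of enhanced FWHMs.
#' @param baseline_fwhm_um per-particle baseline FWHMs (recycled if scalar).
#' @param be_factor applied bandwidth-expansion factor.
#' @param exclusion_fwhm_um baseline-FWHM exclusion threshold, micrometres
#'   (default 2.4).
#' @return A list of class `"resolution_report"`: `mean_fwhm_um`,
#'   `std_fwhm_um`, `mean_sbr_db`, `std_sbr_db`, `n_particles`,
#'   `baseline_fwhm_um` (mean over survivors), `re_factor`, `efficiency`,
#'   `be_factor`.
#' @export
resolution_report <- function(measurements, baseline_fwhm_um, be_factor,
                              exclusion_fwhm_um = 2.4) {
  if (is.numeric(measurements)) {
    fwhm <- measurements; sbr <- rep(NA_real_, length(fwhm))
    ok <- is.finite(fwhm)
  } else {
    fwhm <- vapply(measurements, function(m) m$fwhm_um, numeric(1))
    sbr <- vapply(measurements, function(m) m$peak_sbr_db, numeric(1))
    ok <- vapply(measurements, function(m) isTRUE(m$fit_ok), logical(1))
  }
  baseline <- rep_len(baseline_fwhm_um, length(fwhm))
  keep <- ok & is.finite(baseline) & baseline <= exclusion_fwhm_um
  if (!any(keep))
    stop(sprintf(
      "all particles excluded by the baseline-FWHM rule (FWHM > %.2f um) or failed fits",
      exclusion_fwhm_um))
  re <- mean(baseline[keep]) / mean(fwhm[keep])
  structure(list(mean_fwhm_um = mean(fwhm[keep]),
                 std_fwhm_um = stats::sd(fwhm[keep]),
                 mean_sbr_db = if (any(is.finite(sbr[keep]))) mean(sbr[keep], na.rm = TRUE) else NA_real_,
                 std_sbr_db = if (any(is.finite(sbr[keep]))) stats::sd(sbr[keep], na.rm = TRUE) else NA_real_,
                 n_particles = sum(keep),
                 baseline_fwhm_um = mean(baseline[keep]),
                 re_factor = re, efficiency = re / be_factor,
                 be_factor = be_factor),
            class = "resolution_report")
}

#' @export
print.resolution_report <- function(x, ...) {
  cat(sprintf(
    "<resolution_report> n = %d particles | FWHM %.3f +/- %.3f um (baseline %.3f um)\n  RE factor %.3f at BE factor %.2f -> efficiency %.3f | SBR %.1f dB\n",
    x$n_particles, x$mean_fwhm_um, x$std_fwhm_um, x$baseline_fwhm_um,
    x$re_factor, x$be_factor, x$efficiency, x$mean_sbr_db))
  invisible(x)
}
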