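#' Estimate bulk shift and global phase of a frame against a reference
#'
#' Shift is estimated from the peak of the zero-mean normalized
#' cross-correlation of the magnitude images (computed via FFT, robust to
#' phase drift), refined to subpixel precision by local quadratic (parabolic)
#' interpolation of the correlation peak.  The global phase is then the
#' angle of the complex inner product `sum(Conj(reference) * shifted(frame))`
#' after undoing the shift.  Frames whose correlation peak falls below
#' `quality_threshold` are flagged low-quality (returned, not raised).
#'
#' @param frame,reference complex [enface_field()]s on the same grid.
#' @param quality_threshold minimum normalized correlation peak (default 0.3).
#' @return A list of class `"frame_correction"`: `dx_um`, `dy_um`
#'   (subpixel bulk shift of `frame` relative to `reference`), `phi`
#'   (global phase, radians, in (-pi, pi]), `quality` (normalized
#'   cross-correlation peak in [0, 1]), `low_quality` flag.
#' @export
estimate_correction <- function(frame, reference, quality_threshold = 0.3) {
  stopifnot_same_grid(frame, reference)
  frame <- as_enface(frame, pitch_x = NULL)
  reference <- as_enface(reference, like = frame)
  a <- Mod(reference$values); b <- Mod(frame$values)
  a <- a - mean(a); b <- b - mean(b)
  h <- nrow(a); w <- ncol(a)
  # c(dy, dx) = sum_x a*(x) b(x + d) peaks at the shift of frame w.r.t. ref
  cc <- Re(stats::fft(Conj(fft2(b)) * fft2(a), inverse = TRUE)) / (h * w)
  denom <- sqrt(sum(a^2) * sum(b^2))
  quality <- if (denom == 0) 0 else max(cc) / denom
  pk <- which(cc == max(cc), arr.ind = TRUE)[1L, ]
  # parabolic subpixel refinement with circular neighbors
  sub1 <- function(m, i, j, along) {
    if (along == "row") {
      ym <- m[(i - 2L) %% h + 1L, j]; y0 <- m[i, j]; yp <- m[i %% h + 1L, j]
    } else {
      ym <- m[i, (j - 2L) %% w + 1L]; y0 <- m[i, j]; yp <- m[i, j %% w + 1L]
    }
    den <- ym - 2 * y0 + yp
    if (den == 0) 0 else max(-0.5, min(0.5, 0.5 * (ym - yp) / den))
  }
  to_signed <- function(idx, n) if (idx - 1L > n / 2) idx - 1L - n else idx - 1L
  dy_px <- to_signed(unname(pk[1L]), h) + sub1(cc, pk[1L], pk[2L], "row")
  dx_px <- to_signed(unname(pk[2L]), w) + sub1(cc, pk[1L], pk[2L], "col")
  # the cross-correlation above peaks at -d when frame(x) = ref(x - d)
  dy_px <- -dy_px; dx_px <- -dx_px
  corr0 <- structure(list(dx_um = dx_px * frame$pitch_x,
                          dy_um = dy_px * frame$pitch_y,
                          phi = 0, quality = quality,
                          low_quality = quality < quality_threshold),
                     class = "frame_correction")
  shifted <- apply_correction(frame, corr0)
  phi <- Arg(sum(Conj(reference$values) * shifted$values))
  corr0$phi <- phi
  corr0
}

#' Apply (undo) a frame correction
#'
#' Shifts the frame by `(-dx, -dy)` via a spectral phase ramp (subpixel,
#' band-limited) and multiplies by `exp(-i phi)`, so that
#' `apply_correction(frame, estimate_correction(frame, ref))` is registered
#' to `ref`.
#'
#' @param frame complex [enface_field()].
#' @param corr a `"frame_correction"` (or list with `dx_um`, `dy_um`, `phi`).
#' @return Corrected [enface_field()].
#' @export
apply_correction <- function(frame, corr) {
  frame <- as_enface(frame, pitch_x = NULL)
  v <- frame$values
  g <- k_grid(nrow(v), ncol(v), frame$pitch_x, frame$pitch_y)
  S <- fftshift2(fft2(v))
  S <- S * exp(1i * (g$KX * corr$dx_um + g$KY * corr$dy_um))
  out <- ifft2(ifftshift2(S)) * exp(-1i * corr$phi)
  enface_field(out, frame$pitch_x, frame$pitch_y)
}

# Negate a correction (for inverse-pair identities)
negate_correction <- function(corr) {
  corr$dx_um <- -corr$dx_um; corr$dy_um <- -corr$dy_um; corr$phi <- -corr$phi
  corr
}

#' Register every frame of a stack to a reference frame
#'
#' Convenience wrapper: estimates and applies a [estimate_correction()] for
#' each frame against the reference (first frame by default), so that a
#' subsequent coherent average adds in phase.
#'
#' @param stack a [field_stack()].
#' @param reference reference [enface_field()]; default the first frame.
#' @param quality_threshold forwarded to [estimate_correction()].
#' @return List with `stack` (registered [field_stack()]) and `corrections`
#'   (data frame of per-frame `dx_um`, `dy_um`, `phi`, `quality`).
#' @export
register_stack <- function(stack, reference = NULL, quality_threshold = 0.3) {
  if (is.null(reference))
    reference <- enface_field(stack$frames[[1L]], stack$pitch_x, stack$pitch_y)
  frames <- vector("list", n_frames(stack))
  rows <- vector("list", n_frames(stack))
  for (i in seq_len(n_frames(stack))) {
    f <- enface_field(stack$frames[[i]], stack$pitch_x, stack$pitch_y)
    corr <- estimate_correction(f, reference, quality_threshold)
    frames[[i]] <- apply_correction(f, corr)$values
    rows[[i]] <- data.frame(frame = i, dx_um = corr$dx_um, dy_um = corr$dy_um,
                            phi = corr$phi, quality = corr$quality,
                            low_quality = corr$low_quality)
  }
  list(stack = field_stack(frames, stack$pitch_x, stack$pitch_y,
                           wavelength_um = stack$wavelength_um,
                           depth_index = stack$depth_index,
                           provenance = c(stack$provenance, list(registered = TRUE))),
       corrections = do.call(rbind, rows))
}
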