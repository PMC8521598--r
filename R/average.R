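#' Coherent average of a field stack
#'
#' Element-wise complex mean of the first `n` frames.  Phase-stable signal
#' survives; random-phase system noise cancels, with noise *power* falling
#' as 1/n (20 dB suppression at n = 100).
#'
#' @param stack a [field_stack()].
#' @param n number of leading frames to average (default all).
#' @return An [enface_field()].
#' @export
coherent_average <- function(stack, n = n_frames(stack)) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  if (n > n_frames(stack)) stop("n exceeds the number of frames in the stack")
  acc <- Reduce(`+`, stack$frames[seq_len(n)])
  enface_field(acc / n, stack$pitch_x, stack$pitch_y)
}

#' Incoherent (magnitude-only) average of a field stack
#'
#' Element-wise mean of `|frame|` over the first `n` frames.  Phase-blind:
#' it suppresses magnitude fluctuations but not the noise floor, and is a
#' factor of sqrt(n) less efficient than the coherent average at reducing
#' noise intensity.
#'
#' @inheritParams coherent_average
#' @return A real magnitude matrix (same grid as the frames).
#' @export
incoherent_average <- function(stack, n = n_frames(stack)) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  if (n > n_frames(stack)) stop("n exceeds the number of frames in the stack")
  Reduce(`+`, lapply(stack$frames[seq_len(n)], Mod)) / n
}

#' Space-domain intensity metrics of an en face image
#'
#' The three intensity summaries used to track averaging performance:
#' * `particle_intensity` — 99th percentile of the scattering intensity
#'   (squared magnitude) of the image;
#' * `background_intensity` — median intensity of the particle-removed
#'   image, where particles are removed by magnitude thresholding followed
#'   by dilation of the binary mask;
#' * `noise_intensity` — standard deviation of the intensity of the paired
#'   noise image (an image acquired or synthesized with no sample).
#'
#' @param image complex field ([enface_field()] or matrix) or real magnitude
#'   matrix.
#' @param noise_image paired noise field/magnitude on the same grid, or
#'   `NULL` to skip the noise metric.
#' @param threshold absolute magnitude threshold for the particle mask;
#'   default `threshold_factor` times the median magnitude.
#' @param threshold_factor multiple of the median magnitude used when
#'   `threshold` is `NULL` (default 5).
#' @param dilate_radius dilation radius of the particle mask, pixels
#'   (default 2; 0 disables dilation).
#' @return A list of class `"intensity_metrics"` with fields
#'   `particle_intensity`, `background_intensity`, `noise_intensity`,
#'   `n_frames_used` (carried through from the caller, `NA` here).
#' @export
intensity_metrics <- function(image, noise_image = NULL, threshold = NULL,
                              threshold_factor = 5, dilate_radius = 2) {
  mag <- Mod(field_values(image))
  if (!is.null(noise_image)) {
    if (!identical(dim(Mod(field_values(noise_image))), dim(mag)))
      stop("image and noise_image do not share a grid")
  }
  intens <- mag^2
  if (is.null(threshold)) threshold <- threshold_factor * stats::median(mag)
  mask <- mag > threshold
  if (dilate_radius > 0 && any(mask)) {
    brush <- EBImage::makeBrush(2L * as.integer(dilate_radius) + 1L, shape = "disc")
    mask <- EBImage::dilate(mask * 1, brush) > 0
  }
  if (all(mask))
    stop("particle mask covers the entire image; background intensity undefined")
  noise <- if (is.null(noise_image)) NA_real_ else
    stats::sd(as.vector(Mod(field_values(noise_image))^2))
  structure(list(particle_intensity = as.numeric(stats::quantile(intens, 0.99)),
                 background_intensity = stats::median(intens[!mask]),
                 noise_intensity = noise,
                 n_frames_used = NA_integer_),
            class = "intensity_metrics")
}

#' Noise intensity of a field or magnitude image
#'
#' Standard deviation of the pixel intensity (squared magnitude): the noise
#' metric against which all dB suppression figures are quoted.
#'
#' @param x complex field, [enface_field()], or real magnitude matrix.
#' @return Scalar standard deviation of intensity.
#' @export
noise_intensity <- function(x) stats::sd(as.vector(Mod(field_values(x))^2))
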