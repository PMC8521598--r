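#' Write a complex field stack to HDF5
#'
#' Stores the stack in one group with datasets `real` and `imag` of shape
#' (N, H, W) and attributes `pitch_x_um`, `pitch_y_um`, optionally
#' `wavelength_um` and `depth_index`, and `provenance_json`.  Complex values
#' are stored as paired real/imaginary planes so the layout is
#' language-neutral; the frame index is explicit in the first dimension, so
#' reading can never silently reorder frames.
#'
#' @param stack a [field_stack()].
#' @param path output file path (overwritten if present).
#' @param group HDF5 group name (default `"stack"`).
#' @return `path`, invisibly.
#' @seealso [read_stack()]
#' @export
write_stack <- function(stack, path, group = "stack") {
  if (!inherits(stack, "field_stack")) stop("`stack` must be a field_stack")
  dir <- dirname(path)
  if (!dir.exists(dir)) stop(sprintf("directory does not exist: %s", dir))
  if (file.exists(path)) unlink(path)
  h <- nrow(stack$frames[[1L]]); w <- ncol(stack$frames[[1L]])
  n <- length(stack$frames)
  re <- array(0, c(n, h, w)); im <- array(0, c(n, h, w))
  for (i in seq_len(n)) {
    re[i, , ] <- Re(stack$frames[[i]])
    im[i, , ] <- Im(stack$frames[[i]])
  }
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, group)
  rhdf5::h5write(re, path, paste0(group, "/real"))
  rhdf5::h5write(im, path, paste0(group, "/imag"))
  fid <- rhdf5::H5Fopen(path)
  gid <- rhdf5::H5Gopen(fid, group)
  rhdf5::h5writeAttribute(stack$pitch_x, gid, "pitch_x_um")
  rhdf5::h5writeAttribute(stack$pitch_y, gid, "pitch_y_um")
  if (!is.null(stack$wavelength_um))
    rhdf5::h5writeAttribute(stack$wavelength_um, gid, "wavelength_um")
  if (!is.null(stack$depth_index))
    rhdf5::h5writeAttribute(as.integer(stack$depth_index), gid, "depth_index")
  rhdf5::h5writeAttribute(
    as.character(jsonlite::toJSON(stack$provenance, auto_unbox = TRUE, digits = NA)),
    gid, "provenance_json")
  rhdf5::H5Gclose(gid)
  rhdf5::H5Fclose(fid)
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a complex field stack from HDF5
#'
#' Inverse of [write_stack()]: the round trip is lossless for values, shapes,
#' pitch and provenance.
#'
#' @param path HDF5 file written by [write_stack()] (or any file following
#'   the same layout).
#' @param group group name (default `"stack"`).
#' @return A [field_stack()].
#' @export
read_stack <- function(path, group = "stack") {
  if (!file.exists(path)) stop(sprintf("file does not exist: %s", path))
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  contents <- rhdf5::h5ls(path)
  have <- paste0("/", group, "/", c("real", "imag")) %in%
    paste0(contents$group, "/", contents$name)
  if (!have[1L]) stop(sprintf("format error: missing dataset '%s/real'", group))
  if (!have[2L]) stop(sprintf("format error: missing dataset '%s/imag'", group))
  re <- rhdf5::h5read(path, paste0(group, "/real"))
  im <- rhdf5::h5read(path, paste0(group, "/imag"))
  if (!identical(dim(re), dim(im)))
    stop(sprintf("format error: dataset '%s/imag' has shape %s but '%s/real' has shape %s",
                 group, paste(dim(im), collapse = "x"),
                 group, paste(dim(re), collapse = "x")))
  if (length(dim(re)) != 3L)
    stop("format error: datasets 'real'/'imag' must have shape (N, H, W)")
  at <- rhdf5::h5readAttributes(path, group)
  if (is.null(at$pitch_x_um) || is.null(at$pitch_y_um))
    stop("metadata error: missing pitch attributes 'pitch_x_um'/'pitch_y_um'")
  n <- dim(re)[1L]
  frames <- lapply(seq_len(n), function(i)
    matrix(complex(real = re[i, , ], imaginary = im[i, , ]),
           dim(re)[2L], dim(re)[3L]))
  prov <- list()
  if (!is.null(at$provenance_json))
    prov <- jsonlite::fromJSON(as.character(at$provenance_json), simplifyVector = TRUE)
  field_stack(frames,
              pitch_x = as.numeric(at$pitch_x_um),
              pitch_y = as.numeric(at$pitch_y_um),
              wavelength_um = if (!is.null(at$wavelength_um)) as.numeric(at$wavelength_um),
              depth_index = if (!is.null(at$depth_index)) as.integer(at$depth_index),
              provenance = prov)
}

#' Export a magnitude image as 16-bit grayscale TIFF
#'
#' Visualization helper (human inspection only; quantitative output goes
#' through HDF5/CSV/JSON).  In linear mode the magnitude is mapped linearly
#' from `[0, max]` to `[0, 65535]`.  In log mode values are expressed in dB
#' relative to the maximum magnitude, clipped at `db_floor`, then mapped
#' linearly to `[0, 65535]`.
#'
#' @param field complex matrix or [enface_field()].
#' @param path output TIFF path.
#' @param log_scale logical; use dB-relative-to-max scaling.
#' @param db_floor clip level in dB (negative), log mode only.
#' @return `path`, invisibly.
#' @export
export_magnitude_tiff <- function(field, path, log_scale = TRUE, db_floor = -40) {
  v <- Mod(field_values(field))
  if (any(!is.finite(v))) stop("field must be finite")
  mx <- max(v)
  if (mx == 0) {
    img <- matrix(0, nrow(v), ncol(v))
  } else if (log_scale) {
    if (db_floor >= 0) stop("`db_floor` must be negative (dB below max)")
    db <- 20 * log10(pmax(v / mx, 10^(db_floor / 20)))
    img <- (db - db_floor) / (-db_floor)
  } else {
    img <- v / mx
  }
  tiff::writeTIFF(img, path, bits.per.sample = 16L)
  invisible(path)
}
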