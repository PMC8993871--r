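# 8-bit single-channel PNG/TIFF I/O. The on-disk mask convention is
# normative: background 0, myelin 127, axon 255.

MASK_DISK_VALUES <- c(0L, 127L, 255L)

read_gray_matrix <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop_invalid("unsupported image format '%s' (use png or tiff)", ext))
  if (is.list(arr)) arr <- arr[[1]]
  if (length(dim(arr)) == 3L) arr <- arr[, , 1L]  # first channel of multi-channel files
  round(arr * 255)
}

#' Read a grayscale intensity image from PNG or TIFF
#'
#' @param path Path to an 8-bit single-channel PNG or TIFF file.
#' @param pixel_size Pixel size in micrometers per pixel; always explicit,
#'   never read from file metadata.
#' @return An [intensity_image].
#' @export
read_intensity_image <- function(path, pixel_size) {
  intensity_image(read_gray_matrix(path), pixel_size)
}

#' Write a grayscale intensity image to PNG or TIFF
#'
#' @param img An [intensity_image] (or an RGB overlay array from
#'   [render_overlay]).
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_intensity_image <- function(img, path) {
  arr <- if (inherits(img, "intensity_image")) img$pixels else img
  arr <- pmin(pmax(round(arr), 0), 255) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(arr, path),
    tif = ,
    tiff = tiff::writeTIFF(arr, path, bits.per.sample = 8L),
    stop_invalid("unsupported image format '%s' (use png or tiff)", ext))
  invisible(path)
}

#' Read a three-class semantic mask from PNG or TIFF
#'
#' Expects the 8-bit encoding background = 0, myelin = 127, axon = 255; any
#' other pixel value is an error (masks are a bit-exact interface).
#'
#' @inheritParams read_intensity_image
#' @return A [semantic_mask].
#' @export
read_mask <- function(path, pixel_size) {
  v <- read_gray_matrix(path)
  if (!all(v %in% MASK_DISK_VALUES))
    stop_invalid("mask '%s' contains values outside {0, 127, 255}", path)
  labels <- matrix(0L, nrow(v), ncol(v))
  labels[v == 127] <- MASK_MYELIN
  labels[v == 255] <- MASK_AXON
  semantic_mask(labels, pixel_size)
}

#' Write a three-class semantic mask to PNG or TIFF
#'
#' @param mask A [semantic_mask].
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  v <- matrix(MASK_DISK_VALUES[mask$labels + 1L], nrow(mask$labels),
              ncol(mask$labels))
  write_intensity_image(v, path)
}

#' Export instance labels as a 16-bit image (debug aid)
#'
#' Axon pixels carry their fiber id; assigned myelin pixels carry
#' fiber id + 32768; everything else is 0.
#'
#' @param fs A [fiber_set].
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_instance_labels <- function(fs, path) {
  v <- fs$axon_labels
  v[fs$myelin_labels > 0L] <- fs$myelin_labels[fs$myelin_labels > 0L] + 32768L
  arr <- v / 65535
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(arr, path),
    tif = ,
    tiff = tiff::writeTIFF(arr, path, bits.per.sample = 16L),
    stop_invalid("unsupported image format '%s' (use png or tiff)", ext))
  invisible(path)
}
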