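#' Class codes for three-class axon/myelin semantic masks
#'
#' Internal label codes: background 0, myelin 1, axon 2. On disk (8-bit PNG or
#' TIFF) the convention is background 0, myelin 127, axon 255.
#'
#' @name mask-codes
#' @aliases MASK_BACKGROUND MASK_MYELIN MASK_AXON
#' @export MASK_BACKGROUND MASK_MYELIN MASK_AXON
NULL

MASK_BACKGROUND <- 0L
MASK_MYELIN <- 1L
MASK_AXON <- 2L

#' Construct a grayscale intensity image
#'
#' Container for a single-channel 8-bit light-microscopy image together with
#' its physical pixel size. Pixel sizes are never inferred from file metadata;
#' they are always supplied explicitly because every downstream length and
#' area is derived from them.
#'
#' @param pixels Numeric matrix of intensities in `[0, 255]`; rows are image
#'   rows (y), columns are image columns (x).
#' @param pixel_size Pixel edge length in micrometers per pixel (> 0).
#' @return An object of class `intensity_image` with fields `pixels` and
#'   `pixel_size`.
#' @export
intensity_image <- function(pixels, pixel_size) {
  if (!is.matrix(pixels) || length(pixels) == 0L)
    stop("`pixels` must be a nonempty matrix", call. = FALSE)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      !is.finite(pixel_size) || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number (um/px)", call. = FALSE)
  rng <- range(pixels)
  if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 255)
    stop("intensities must be finite and within [0, 255]", call. = FALSE)
  structure(list(pixels = pixels, pixel_size = as.numeric(pixel_size)),
            class = "intensity_image")
}

#' Construct a three-class semantic mask
#'
#' @param labels Integer matrix with values in `{MASK_BACKGROUND, MASK_MYELIN,
#'   MASK_AXON}` (0, 1, 2).
#' @param pixel_size Pixel edge length in micrometers per pixel (> 0).
#' @return An object of class `semantic_mask` with fields `labels` and
#'   `pixel_size`.
#' @export
semantic_mask <- function(labels, pixel_size) {
  if (!is.matrix(labels) || length(labels) == 0L)
    stop("`labels` must be a nonempty matrix", call. = FALSE)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      !is.finite(pixel_size) || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number (um/px)", call. = FALSE)
  storage.mode(labels) <- "integer"
  if (!all(labels %in% c(MASK_BACKGROUND, MASK_MYELIN, MASK_AXON)))
    stop("mask labels must be 0 (background), 1 (myelin) or 2 (axon)",
         call. = FALSE)
  structure(list(labels = labels, pixel_size = as.numeric(pixel_size)),
            class = "semantic_mask")
}

#' @export
print.intensity_image <- function(x, ...) {
  cat(sprintf("<intensity_image> %d x %d px @ %g um/px, range [%g, %g]\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
print.semantic_mask <- function(x, ...) {
  n <- tabulate(x$labels + 1L, nbins = 3L)
  cat(sprintf(
    "<semantic_mask> %d x %d px @ %g um/px (background %d, myelin %d, axon %d)\n",
    nrow(x$labels), ncol(x$labels), x$pixel_size, n[1], n[2], n[3]))
  invisible(x)
}

#' @export
dim.intensity_image <- function(x) dim(x$pixels)

#' @export
dim.semantic_mask <- function(x) dim(x$labels)

# shared argument checks -------------------------------------------------

stop_invalid <- function(...) {
  cnd <- structure(class = c("nervemorph_invalid_argument", "error", "condition"),
                   list(message = sprintf(...), call = sys.call(-1)))
  stop(cnd)
}

assert_same_shape <- function(a, b, what = "inputs") {
  da <- dim(a); db <- dim(b)
  if (!identical(da, db))
    stop_invalid("%s must have the same shape (got %dx%d vs %dx%d)",
                 what, da[1], da[2], db[1], db[2])
  invisible(TRUE)
}
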