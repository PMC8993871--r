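# Patch-based tiling: split an image into overlapping fixed-size patches,
# segment each patch, and stitch per-class scores back (averaging in
# overlaps). Undersized images are reflect-padded up to the patch size.

anchors_1d <- function(dim, patch_size, overlap) {
  stride <- patch_size - overlap
  last <- max(dim, patch_size) - patch_size
  a <- seq.int(0L, last, by = stride)
  if (a[length(a)] != last) a <- c(a, last)
  as.integer(a)
}

reflect_index <- function(n, n_out) {
  # reflect without repeating the edge sample; degenerate dims repeat
  if (n == 1L) return(rep(1L, n_out))
  idx <- seq_len(n_out)
  period <- 2L * (n - 1L)
  r <- (idx - 1L) %% period
  ifelse(r < n, r + 1L, period - r + 1L)
}

#' Split an image into overlapping patches
#'
#' Anchors are laid at stride `patch_size - overlap` from 0, plus a final
#' anchor clamped to `dim - patch_size` on each axis so the last patch ends
#' exactly at the image edge. Images smaller than `patch_size` are
#' reflect-padded; the padding is recorded in the layout and cropped away at
#' stitch time.
#'
#' @param img An [intensity_image].
#' @param patch_size Patch edge length in pixels (default 512).
#' @param overlap Overlap between neighboring patches in pixels
#'   (`0 <= overlap < patch_size`).
#' @return A list with `patches` (list of `patch_size` x `patch_size`
#'   matrices, row-major anchor order) and `layout` (a `patch_layout`: fields
#'   `patch_size`, `overlap`, `anchors` 0-based `(row, col)` matrix,
#'   `padded_shape`, `original_shape`).
#' @export
split_patches <- function(img, patch_size = 512L, overlap = 10L) {
  stopifnot(inherits(img, "intensity_image"))
  patch_size <- as.integer(patch_size); overlap <- as.integer(overlap)
  if (!(patch_size > overlap && overlap >= 0L))
    stop_invalid("need patch_size > overlap >= 0 (got %d, %d)",
                 patch_size, overlap)
  shape <- dim(img$pixels)
  padded <- pmax(shape, patch_size)
  m <- img$pixels
  if (any(padded > shape))
    m <- m[reflect_index(shape[1], padded[1]),
           reflect_index(shape[2], padded[2]), drop = FALSE]
  ar <- anchors_1d(padded[1], patch_size, overlap)
  ac <- anchors_1d(padded[2], patch_size, overlap)
  anchors <- cbind(row = rep(ar, each = length(ac)),
                   col = rep(ac, times = length(ar)))
  patches <- lapply(seq_len(nrow(anchors)), function(i) {
    r <- anchors[i, 1]; c <- anchors[i, 2]
    m[(r + 1):(r + patch_size), (c + 1):(c + patch_size), drop = FALSE]
  })
  layout <- structure(list(patch_size = patch_size, overlap = overlap,
                           anchors = anchors, padded_shape = padded,
                           original_shape = shape),
                      class = "patch_layout")
  list(patches = patches, layout = layout)
}

#' Stitch per-patch class scores into a semantic mask
#'
#' Per-class scores are summed where patches overlap and divided by the
#' per-pixel cover count (i.e. averaged), padding is cropped back to the
#' original shape, and the per-pixel argmax taken with tie priority
#' axon > myelin > background.
#'
#' @param scores List with one class-score stack per layout anchor, each a
#'   `patch_size x patch_size x 3` array (planes ordered background, myelin,
#'   axon; finite, non-negative).
#' @param layout A `patch_layout` from [split_patches].
#' @param pixel_size Pixel size of the stitched mask in micrometers per pixel.
#' @return A [semantic_mask] of shape `layout$original_shape`.
#' @export
stitch_patches <- function(scores, layout, pixel_size) {
  stopifnot(inherits(layout, "patch_layout"))
  n <- nrow(layout$anchors)
  if (length(scores) != n)
    stop_invalid("got %d score stacks for %d patches", length(scores), n)
  ps <- layout$patch_size
  pad <- layout$padded_shape
  acc <- array(0, dim = c(pad[1], pad[2], 3L))
  cover <- matrix(0L, pad[1], pad[2])
  for (i in seq_len(n)) {
    s <- scores[[i]]
    if (!identical(dim(s)[1:2], c(ps, ps)) || length(dim(s)) != 3L)
      stop_invalid("score stack %d is not %d x %d x 3", i, ps, ps)
    r <- layout$anchors[i, 1]; c <- layout$anchors[i, 2]
    ri <- (r + 1):(r + ps); ci <- (c + 1):(c + ps)
    acc[ri, ci, ] <- acc[ri, ci, ] + s
    cover[ri, ci] <- cover[ri, ci] + 1L
  }
  orig <- layout$original_shape
  ri <- seq_len(orig[1]); ci <- seq_len(orig[2])
  cov <- cover[ri, ci, drop = FALSE]
  lab <- argmax_mask(acc[ri, ci, 1L] / cov, acc[ri, ci, 2L] / cov,
                     acc[ri, ci, 3L] / cov)
  semantic_mask(lab, pixel_size)
}

#' One-hot class scores for a mask region (identity segmenter helper)
#'
#' @param labels Integer label matrix (codes 0/1/2).
#' @return A `rows x cols x 3` one-hot score array.
#' @export
one_hot_scores <- function(labels) {
  out <- array(0, dim = c(nrow(labels), ncol(labels), 3L))
  out[, , 1L] <- labels == MASK_BACKGROUND
  out[, , 2L] <- labels == MASK_MYELIN
  out[, , 3L] <- labels == MASK_AXON
  out
}

#' Classical threshold-and-fill baseline segmenter
#'
#' Pixels darker than `myelin_threshold` become myelin; enclosed holes of the
#' myelin foreground with area at least `min_hole_px` become axon (in
#' osmium-stained material the dark annulus encloses the lighter axoplasm);
#' everything else is background. This is a deliberately simple classical
#' stand-in so the tiling pipeline and evaluation suite run end-to-end with
#' any segmenter.
#'
#' @param img An [intensity_image].
#' @param myelin_threshold Intensity threshold in `[0, 255]`; `NULL` (default)
#'   uses Otsu's threshold on the patch histogram.
#' @param min_hole_px Minimum enclosed-hole area in pixels to be promoted to
#'   axon (default 10).
#' @return A [semantic_mask] with the image's shape and pixel size.
#' @export
baseline_segment <- function(img, myelin_threshold = NULL, min_hole_px = 10L) {
  stopifnot(inherits(img, "intensity_image"))
  if (is.null(myelin_threshold))
    myelin_threshold <- EBImage::otsu(EBImage::Image(img$pixels / 255),
                                      range = c(0, 1)) * 255
  if (myelin_threshold < 0 || myelin_threshold > 255)
    stop_invalid("`myelin_threshold` must lie in [0, 255]")
  myelin <- img$pixels < myelin_threshold
  lab <- matrix(MASK_BACKGROUND, nrow(myelin), ncol(myelin))
  lab[myelin] <- MASK_MYELIN
  # enclosed holes: connected components of the complement not touching the
  # image border (4-connectivity, complementary to 8-connected foreground)
  comp <- label_components(!myelin, connectivity = 4L)
  if (max(comp) > 0L) {
    border_ids <- unique(c(comp[1, ], comp[nrow(comp), ],
                           comp[, 1], comp[, ncol(comp)]))
    sizes <- tabulate(comp, nbins = max(comp))
    hole_ids <- setdiff(which(sizes >= min_hole_px), border_ids)
    lab[comp %in% hole_ids] <- MASK_AXON
  }
  semantic_mask(lab, img$pixel_size)
}

#' Run a per-patch segmenter over a whole image
#'
#' Pipeline: resample the image to the working resolution `working_px / zoom`,
#' optionally auto-contrast it, split into overlapping patches, apply the
#' segmenter to every patch, stitch the per-class scores, and resample the
#' stitched labels back to the native pixel size and shape. A zoom below 1
#' coarsens the working resolution (e.g. 0.55x to avoid over-segmentation of
#' large fibers); the returned mask always has the input's native shape and
#' pixel size.
#'
#' @param img An [intensity_image].
#' @param segmenter Function mapping an [intensity_image] patch to either a
#'   `patch x patch x 3` class-score array or a [semantic_mask] (converted to
#'   one-hot scores). Defaults to [baseline_segment].
#' @param zoom Working-resolution multiplier (> 0, default 1).
#' @param overlap Patch overlap in pixels (default 10; 10-25 is typical).
#' @param working_px Working pixel size in micrometers per pixel before zoom
#'   (default 0.1).
#' @param patch_size Patch edge length in pixels (default 512).
#' @param contrast If `TRUE` (default), apply [autocontrast] before splitting.
#' @param ... Passed on to `segmenter`.
#' @return A [semantic_mask] with the input's native shape and pixel size.
#' @export
run_tiled_segmentation <- function(img, segmenter = baseline_segment,
                                   zoom = 1, overlap = 10L,
                                   working_px = 0.1, patch_size = 512L,
                                   contrast = TRUE, ...) {
  stopifnot(inherits(img, "intensity_image"))
  if (!is.numeric(zoom) || length(zoom) != 1L || !is.finite(zoom) || zoom <= 0)
    stop_invalid("`zoom` must be a single positive number")
  work_px <- working_px / zoom
  native_shape <- dim(img$pixels)
  work <- resample_intensity(img, work_px)
  if (contrast) work <- autocontrast(work)
  sp <- split_patches(work, patch_size = patch_size, overlap = overlap)
  scores <- lapply(seq_along(sp$patches), function(i) {
    res <- tryCatch(
      segmenter(intensity_image(sp$patches[[i]], work_px), ...),
      error = function(e) {
        a <- sp$layout$anchors[i, ]
        stop(sprintf("segmenter failed on patch %d at (row %d, col %d): %s",
                     i, a[1], a[2], conditionMessage(e)), call. = FALSE)
      })
    if (inherits(res, "semantic_mask")) res <- one_hot_scores(res$labels)
    res
  })
  stitched <- stitch_patches(scores, sp$layout, work_px)
  resample_labels(stitched, img$pixel_size, target_shape = native_shape)
}
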