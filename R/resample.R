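# Bilinear resampling with pixel-center alignment: output pixel i (0-based)
# samples source coordinate (i + 0.5) * in/out - 0.5, clamped to the source
# grid. At unchanged scale this is the exact identity, which the tiling
# round-trip guarantees rely on.

bilinear_core <- function(m, out_nrow, out_ncol) {
  nr <- nrow(m); nc <- ncol(m)
  rs <- pmin(pmax((seq_len(out_nrow) - 0.5) * (nr / out_nrow) - 0.5, 0), nr - 1)
  cs <- pmin(pmax((seq_len(out_ncol) - 0.5) * (nc / out_ncol) - 0.5, 0), nc - 1)
  r0 <- floor(rs); c0 <- floor(cs)
  fr <- rs - r0;   fc <- cs - c0
  r1 <- pmin(r0 + 1, nr - 1); c1 <- pmin(c0 + 1, nc - 1)
  i0 <- r0 + 1; i1 <- r1 + 1; j0 <- c0 + 1; j1 <- c1 + 1
  wr0 <- 1 - fr; wc0 <- 1 - fc
  m[i0, j0, drop = FALSE] * (wr0 %o% wc0) +
    m[i1, j0, drop = FALSE] * (fr %o% wc0) +
    m[i0, j1, drop = FALSE] * (wr0 %o% fc) +
    m[i1, j1, drop = FALSE] * (fr %o% fc)
}

resampled_shape <- function(shape, pixel_size, target_px) {
  as.integer(pmax(round(shape * pixel_size / target_px), 1))
}

#' Resample an intensity image to a new pixel size
#'
#' Bilinear interpolation; the output shape is `round(shape * pixel_size /
#' target_px)`. Resampling to the current pixel size returns the input
#' unchanged.
#'
#' @param img An [intensity_image].
#' @param target_px Target pixel size in micrometers per pixel (> 0).
#' @return An [intensity_image] at `target_px`.
#' @export
resample_intensity <- function(img, target_px) {
  stopifnot(inherits(img, "intensity_image"))
  if (!is.numeric(target_px) || length(target_px) != 1L ||
      !is.finite(target_px) || target_px <= 0)
    stop_invalid("`target_px` must be a single positive number")
  if (target_px == img$pixel_size) return(img)
  out_shape <- resampled_shape(dim(img$pixels), img$pixel_size, target_px)
  out <- bilinear_core(img$pixels, out_shape[1], out_shape[2])
  intensity_image(pmin(pmax(round(out), 0), 255), target_px)
}

# One-hot bilinear resampling of the three class planes followed by argmax;
# ties resolved axon > myelin > background so thin axons survive.
argmax_mask <- function(s_bg, s_my, s_ax) {
  lab <- matrix(MASK_BACKGROUND, nrow(s_bg), ncol(s_bg))
  lab[s_my >= s_bg] <- MASK_MYELIN
  lab[s_ax >= s_my & s_ax >= s_bg] <- MASK_AXON
  lab
}

#' Resample a semantic mask to a new pixel size
#'
#' Each class is converted to an indicator plane, bilinearly resampled with
#' the same kernel as [resample_intensity], and the per-pixel argmax taken
#' (ties broken axon > myelin > background), keeping labels categorical while
#' interpolating boundaries smoothly.
#'
#' @param mask A [semantic_mask].
#' @param target_px Target pixel size in micrometers per pixel (> 0).
#' @param target_shape Optional explicit output shape `c(rows, cols)`
#'   overriding the rounded shape (used to return tiled segmentations at the
#'   exact native size).
#' @return A [semantic_mask] at `target_px`.
#' @export
resample_labels <- function(mask, target_px, target_shape = NULL) {
  stopifnot(inherits(mask, "semantic_mask"))
  if (!is.numeric(target_px) || length(target_px) != 1L ||
      !is.finite(target_px) || target_px <= 0)
    stop_invalid("`target_px` must be a single positive number")
  out_shape <- if (is.null(target_shape))
    resampled_shape(dim(mask$labels), mask$pixel_size, target_px)
  else as.integer(target_shape)
  if (target_px == mask$pixel_size && identical(out_shape, dim(mask$labels)))
    return(mask)
  planes <- lapply(c(MASK_BACKGROUND, MASK_MYELIN, MASK_AXON), function(k) {
    bilinear_core((mask$labels == k) * 1, out_shape[1], out_shape[2])
  })
  semantic_mask(argmax_mask(planes[[1]], planes[[2]], planes[[3]]), target_px)
}

#' Percentile auto-contrast stretch
#'
#' Linearly maps the `clip_fraction` and `1 - clip_fraction` intensity
#' quantiles to 0 and 255 and clamps, emulating the auto-contrast
#' preadjustment used before segmentation. Constant images are returned
#' unchanged. The mapping is monotone: pixel ordering is preserved.
#'
#' @param img An [intensity_image].
#' @param clip_fraction Fraction of each intensity tail to clip
#'   (default 0.001, i.e. 0.1% per tail); must lie in `[0, 0.5)`.
#' @return An [intensity_image].
#' @export
autocontrast <- function(img, clip_fraction = 0.001) {
  stopifnot(inherits(img, "intensity_image"))
  if (!is.numeric(clip_fraction) || length(clip_fraction) != 1L ||
      clip_fraction < 0 || clip_fraction >= 0.5)
    stop_invalid("`clip_fraction` must lie in [0, 0.5)")
  q <- stats::quantile(img$pixels, c(clip_fraction, 1 - clip_fraction),
                       names = FALSE)
  if (q[2] <= q[1]) return(img)
  out <- (img$pixels - q[1]) / (q[2] - q[1]) * 255
  intensity_image(pmin(pmax(round(out), 0), 255), img$pixel_size)
}
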