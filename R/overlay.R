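# Enumerated overlay rendering: myelin tinted red, axons blue, fiber id
# printed at each axon centroid so records can be checked against the
# exported table. Digits come from a built-in 3x5 bitmap font; placement is
# deterministic.

DIGIT_FONT <- lapply(list(
  `0` = c("111", "101", "101", "101", "111"),
  `1` = c("010", "110", "010", "010", "111"),
  `2` = c("111", "001", "111", "100", "111"),
  `3` = c("111", "001", "111", "001", "111"),
  `4` = c("101", "101", "111", "001", "001"),
  `5` = c("111", "100", "111", "001", "111"),
  `6` = c("111", "100", "111", "101", "111"),
  `7` = c("111", "001", "010", "010", "010"),
  `8` = c("111", "101", "111", "101", "111"),
  `9` = c("111", "101", "111", "001", "111")),
  function(rows) do.call(rbind, lapply(strsplit(rows, ""),
                                       function(r) as.integer(r) == 1L)))

draw_number <- function(plane_set, id, cy, cx) {
  digits <- strsplit(as.character(id), "")[[1]]
  w <- 4L * length(digits) - 1L
  r0 <- round(cy) - 2L
  c0 <- round(cx) - (w - 1L) %/% 2L
  nr <- nrow(plane_set[[1]]); nc <- ncol(plane_set[[1]])
  for (k in seq_along(digits)) {
    glyph <- DIGIT_FONT[[digits[k]]]
    for (i in 1:5) for (j in 1:3) {
      if (!glyph[i, j]) next
      r <- r0 + i; c <- c0 + (k - 1L) * 4L + j
      if (r >= 1L && r <= nr && c >= 1L && c <= nc)
        for (p in 1:3) plane_set[[p]][r, c] <- 255
    }
  }
  plane_set
}

#' Render an enumerated fiber overlay
#'
#' Myelin is tinted red and axons blue over a white background; each fiber's
#' id from the morphometry table is printed in white at its axon centroid.
#'
#' @param mask A [semantic_mask].
#' @param tbl A [measure_fiber_set] table derived from `mask` (may be empty:
#'   then only the class tint is rendered).
#' @return A `rows x cols x 3` RGB array with values in `[0, 255]` and
#'   attribute `pixel_size`; write with [write_intensity_image].
#' @export
render_overlay <- function(mask, tbl = NULL) {
  stopifnot(inherits(mask, "semantic_mask"))
  lab <- mask$labels
  r <- matrix(255, nrow(lab), ncol(lab)); g <- r; b <- r
  my <- lab == MASK_MYELIN; ax <- lab == MASK_AXON
  r[my] <- 200; g[my] <- 30;  b[my] <- 30
  r[ax] <- 40;  g[ax] <- 60;  b[ax] <- 220
  planes <- list(r, g, b)
  if (!is.null(tbl) && nrow(tbl) > 0L) {
    for (i in seq_len(nrow(tbl))) {
      planes <- draw_number(planes, tbl$fiber_id[i],
                            tbl$y_px[i] + 1, tbl$x_px[i] + 1)
    }
  }
  out <- array(0, dim = c(nrow(lab), ncol(lab), 3L))
  out[, , 1] <- planes[[1]]; out[, , 2] <- planes[[2]]; out[, , 3] <- planes[[3]]
  attr(out, "pixel_size") <- mask$pixel_size
  out
}
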