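# Per-fiber morphometry under the equivalent-circle model: all diameters and
# thicknesses are derived from cross-sectional areas assuming an ideal
# circular shape, which standardizes measurements across irregular fibers.

#' Equivalent-circle axon diameter from cross-sectional area
#'
#' `d = 2 * sqrt(A / pi)`: the diameter of the circle with the same area.
#'
#' @param area Axon cross-sectional area(s) in square micrometers (>= 0).
#' @return Diameter(s) in micrometers.
#' @export
axon_diameter_from_area <- function(area) {
  if (any(!is.finite(area)) || any(area < 0))
    stop_invalid("`area` must be finite and non-negative")
  2 * sqrt(area / pi)
}

#' Myelin sheath thickness from axon and myelin areas
#'
#' Thickness of the annulus under the circular model: the equivalent-circle
#' outer radius of the whole fiber (axon + myelin area) minus the
#' equivalent-circle axon radius,
#' `(2 * sqrt((A_axon + A_myelin) / pi) - 2 * sqrt(A_axon / pi)) / 2`.
#'
#' @param axon_area Axon area(s) in square micrometers (>= 0).
#' @param myelin_area Myelin sheath area(s) in square micrometers (>= 0).
#' @return Thickness(es) in micrometers.
#' @export
myelin_thickness_from_areas <- function(axon_area, myelin_area) {
  if (any(!is.finite(axon_area)) || any(axon_area < 0) ||
      any(!is.finite(myelin_area)) || any(myelin_area < 0))
    stop_invalid("areas must be finite and non-negative")
  (2 * sqrt((axon_area + myelin_area) / pi) - 2 * sqrt(axon_area / pi)) / 2
}

#' g-ratio from axon and myelin areas
#'
#' Equivalent-diameter ratio `sqrt(A_axon / (A_axon + A_myelin))`: axon
#' diameter over fiber diameter under the circular model. Physiological
#' values cluster near 0.6-0.7.
#'
#' @inheritParams myelin_thickness_from_areas
#' @return g-ratio(s) in `(0, 1]`.
#' @export
g_ratio <- function(axon_area, myelin_area) {
  if (any(!is.finite(axon_area)) || any(axon_area < 0) ||
      any(!is.finite(myelin_area)) || any(myelin_area < 0))
    stop_invalid("areas must be finite and non-negative")
  if (any(axon_area + myelin_area == 0))
    stop_invalid("g-ratio undefined when both areas are zero")
  sqrt(axon_area / (axon_area + myelin_area))
}

#' Region shape descriptors from a pixel set
#'
#' Centroid (mean pixel coordinates, 0-based, x = column, y = row with y
#' increasing downward), solidity (pixel count over convex-hull-filled pixel
#' count), eccentricity (`sqrt(1 - l2/l1)` from the eigenvalues `l1 >= l2` of
#' the central second-moment matrix) and orientation
#' (`0.5 * atan2(2*mu11, mu20 - mu02)` in degrees, in `(-90, 90]`, measured
#' from the +x axis). Single-pixel and collinear sets degenerate to
#' solidity 1, eccentricity per the moment formula (0 for a single pixel).
#'
#' @param coords Two-column matrix of `(row, col)` pixel indices (1-based,
#'   as returned by `which(..., arr.ind = TRUE)`); nonempty.
#' @return List with `centroid_x`, `centroid_y` (0-based px), `solidity`,
#'   `eccentricity`, `orientation_deg`.
#' @export
shape_descriptors <- function(coords) {
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 2)
  if (nrow(coords) == 0L) stop_invalid("pixel set must be nonempty")
  x <- coords[, 2] - 1; y <- coords[, 1] - 1
  cx <- mean(x); cy <- mean(y)
  dx <- x - cx; dy <- y - cy
  mu20 <- mean(dx * dx); mu02 <- mean(dy * dy); mu11 <- mean(dx * dy)
  tr <- mu20 + mu02
  det <- mu20 * mu02 - mu11 * mu11
  disc <- sqrt(max((tr / 2)^2 - det, 0))
  l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
  ecc <- if (l1 <= 0) 0 else sqrt(max(1 - l2 / l1, 0))
  ori <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
  list(centroid_x = cx, centroid_y = cy,
       solidity = length(x) / hull_pixel_count(x, y),
       eccentricity = ecc, orientation_deg = ori)
}

# Number of lattice points inside (or on) the convex hull of a pixel set.
# Half-plane inclusion test against the hull edges, evaluated over the
# bounding box; degenerate (collinear) sets return the pixel count itself.
hull_pixel_count <- function(x, y) {
  n <- length(x)
  if (n <= 2L) return(n)
  pts <- unique(cbind(x, y))
  if (nrow(pts) <= 2L) return(n)
  h <- grDevices::chull(pts[, 1], pts[, 2])  # clockwise vertex order
  if (length(h) <= 2L) return(n)             # collinear
  hx <- pts[h, 1]; hy <- pts[h, 2]
  gx <- seq(min(x), max(x)); gy <- seq(min(y), max(y))
  px <- rep(gx, times = length(gy)); py <- rep(gy, each = length(gx))
  inside <- rep(TRUE, length(px))
  m <- length(hx)
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    # clockwise hull: interior lies at non-positive cross product
    cr <- (hx[j] - hx[i]) * (py - hy[i]) - (hy[j] - hy[i]) * (px - hx[i])
    inside <- inside & (cr <= 1e-9)
  }
  max(sum(inside), n)
}

#' Flag-threshold configuration for probable segmentation artifacts
#'
#' Misclassified myelin-split artifacts typically show tiny axon diameters
#' with very low g-ratios, while unmyelinated axons misread as thinly
#' myelinated fibers show unphysiologically high g-ratios; these thresholds
#' drive post-hoc screening flags (records are flagged, never deleted).
#'
#' @param g_low g-ratio lower threshold (default 0.35).
#' @param g_high g-ratio upper threshold (default 0.90).
#' @param d_min Minimum plausible axon diameter in micrometers (default 0.30).
#' @return A `flag_config` list.
#' @export
flag_config <- function(g_low = 0.35, g_high = 0.90, d_min = 0.30) {
  if (!(g_low > 0 && g_low < g_high && g_high <= 1))
    stop_invalid("need 0 < g_low < g_high <= 1")
  if (d_min < 0) stop_invalid("`d_min` must be >= 0")
  structure(list(g_low = g_low, g_high = g_high, d_min = d_min),
            class = "flag_config")
}

#' Measure all fibers of a fiber set
#'
#' One record per fiber: areas are pixel counts times `pixel_size^2`;
#' diameter, thickness and g-ratio follow the equivalent-circle model; shape
#' descriptors and the centroid are computed on the axon pixel set; the
#' BORDER flag is copied from `touches_border`.
#'
#' @param fs A [build_fiber_set] result.
#' @return A tibble (`morphometry_table`) with columns `fiber_id`, `x_px`,
#'   `y_px`, `x_um`, `y_um`, `axon_area_um2`, `axon_diameter_um`,
#'   `myelin_area_um2`, `myelin_thickness_um`, `g_ratio`, `solidity`,
#'   `eccentricity`, `orientation_deg`, `flags`; attributes `pixel_size` and
#'   `provenance`.
#' @export
measure_fiber_set <- function(fs) {
  stopifnot(inherits(fs, "fiber_set"))
  ps <- fs$pixel_size
  n <- nrow(fs$fibers)
  if (n == 0L) {
    tbl <- tibble::tibble(
      fiber_id = integer(), x_px = numeric(), y_px = numeric(),
      x_um = numeric(), y_um = numeric(), axon_area_um2 = numeric(),
      axon_diameter_um = numeric(), myelin_area_um2 = numeric(),
      myelin_thickness_um = numeric(), g_ratio = numeric(),
      solidity = numeric(), eccentricity = numeric(),
      orientation_deg = numeric(), flags = character())
  } else {
    axon_area <- fs$fibers$axon_px * ps^2
    myelin_area <- fs$fibers$myelin_px * ps^2
    sd_list <- lapply(fs$fibers$fiber_id, function(id) {
      shape_descriptors(which(fs$axon_labels == id, arr.ind = TRUE))
    })
    tbl <- tibble::tibble(
      fiber_id = fs$fibers$fiber_id,
      x_px = vapply(sd_list, `[[`, numeric(1), "centroid_x"),
      y_px = vapply(sd_list, `[[`, numeric(1), "centroid_y"),
      axon_area_um2 = axon_area,
      axon_diameter_um = axon_diameter_from_area(axon_area),
      myelin_area_um2 = myelin_area,
      myelin_thickness_um = myelin_thickness_from_areas(axon_area, myelin_area),
      g_ratio = g_ratio(axon_area, myelin_area),
      solidity = vapply(sd_list, `[[`, numeric(1), "solidity"),
      eccentricity = vapply(sd_list, `[[`, numeric(1), "eccentricity"),
      orientation_deg = vapply(sd_list, `[[`, numeric(1), "orientation_deg"),
      flags = ifelse(fs$fibers$touches_border, "BORDER", ""))
    tbl$x_um <- tbl$x_px * ps
    tbl$y_um <- tbl$y_px * ps
    tbl <- tbl[, c("fiber_id", "x_px", "y_px", "x_um", "y_um",
                   "axon_area_um2", "axon_diameter_um", "myelin_area_um2",
                   "myelin_thickness_um", "g_ratio", "solidity",
                   "eccentricity", "orientation_deg", "flags")]
  }
  attr(tbl, "pixel_size") <- ps
  attr(tbl, "provenance") <- list(source_shape = fs$source_shape,
                                  orphan_myelin_px = sum(fs$orphan))
  class(tbl) <- c("morphometry_table", class(tbl))
  tbl
}

add_flag <- function(flags, set, name) {
  ifelse(set, ifelse(flags == "", name, paste(flags, name, sep = ";")), flags)
}

#' Flag probable artifact records in a morphometry table
#'
#' Adds `LOW_G` where `g_ratio < g_low`, `HIGH_G` where `g_ratio > g_high`
#' and `SMALL_AXON` where `axon_diameter_um < d_min`. Flags are additive;
#' records are never deleted (screening is the user's decision).
#'
#' @param tbl A [measure_fiber_set] table.
#' @param cfg A [flag_config].
#' @return The table with its `flags` column augmented.
#' @export
flag_artifacts <- function(tbl, cfg = flag_config()) {
  stopifnot(inherits(cfg, "flag_config"))
  f <- tbl$flags
  f <- add_flag(f, tbl$g_ratio < cfg$g_low, "LOW_G")
  f <- add_flag(f, tbl$g_ratio > cfg$g_high, "HIGH_G")
  f <- add_flag(f, tbl$axon_diameter_um < cfg$d_min, "SMALL_AXON")
  tbl$flags <- f
  tbl
}

#' Write a morphometry table to CSV
#'
#' UTF-8, '.' decimal separator, one row per fiber; `flags` semicolon-joined.
#'
#' @param tbl A morphometry table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_morphometry_csv <- function(tbl, path) {
  utils::write.csv(as.data.frame(tbl), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a morphometry table from CSV
#'
#' @param path CSV path written by [write_morphometry_csv].
#' @return A tibble.
#' @export
read_morphometry_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(flags = "character"))
  tibble::as_tibble(df)
}
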