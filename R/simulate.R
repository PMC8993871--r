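# Synthetic osmium-stained nerve cross-section phantoms: bright background,
# dark annular myelin sheaths, lighter axon interiors, densely packed
# non-overlapping elliptical fibers, optional myelin-split artifacts (cut
# into image AND mask: they are real tissue artifacts a segmenter may
# transcribe) and unmyelinated dark blobs (image-only distractors). Fibers
# are parameterized by equivalent diameter so the simulated truth is
# definitionally commensurate with equivalent-circle morphometry.

#' Simulation configuration for nerve cross-section phantoms
#'
#' Defaults describe a healthy-to-regenerating rat nerve at light-microscopy
#' scale: 0.1 um/px, axon diameters lognormal with distribution mean 4 um
#' (CV 15%), g-ratio truncated-normal around 0.65, near-circular fibers,
#' bright background (230) with dark myelin (40) and intermediate axoplasm
#' (150) plus mild Gaussian noise.
#'
#' @param width,height Canvas size in pixels.
#' @param pixel_size Micrometers per pixel.
#' @param n_fibers Number of fibers to attempt to place.
#' @param diameter_meanlog,diameter_sdlog Lognormal parameters of the axon
#'   diameter (um). Vectors of length 2 with `diameter_weights` give a
#'   two-component mixture.
#' @param diameter_weights Mixture weights (default single component).
#' @param g_mean,g_sd,g_lower,g_upper Truncated-normal g-ratio distribution;
#'   bounds must lie inside (0, 1).
#' @param min_gap Minimum distance between fiber outer boundaries, px.
#' @param ellipse_ecc_max Maximum fiber eccentricity; per-fiber eccentricity
#'   is uniform on `[0, ellipse_ecc_max]`.
#' @param gray_background,gray_axon,gray_myelin Mean gray levels (0-255).
#' @param noise_sd Gaussian pixel noise standard deviation (gray levels).
#' @param p_split Per-fiber probability of a myelin-split artifact.
#' @param p_unmyelinated Number of image-only dark blobs as a fraction of the
#'   placed fiber count.
#' @param max_attempts Placement attempts per fiber before it is dropped.
#' @param seed Integer seed; the whole simulation runs off one seeded stream.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(width = 1024L, height = 1024L, pixel_size = 0.1,
                              n_fibers = 50L,
                              diameter_meanlog = log(4) - 0.15^2 / 2,
                              diameter_sdlog = 0.15,
                              diameter_weights = NULL,
                              g_mean = 0.65, g_sd = 0.05,
                              g_lower = 0.40, g_upper = 0.85,
                              min_gap = 2, ellipse_ecc_max = 0.3,
                              gray_background = 230, gray_axon = 150,
                              gray_myelin = 40, noise_sd = 8,
                              p_split = 0, p_unmyelinated = 0,
                              max_attempts = 200L, seed = 1L) {
  if (width < 1 || height < 1 || pixel_size <= 0 || n_fibers < 0)
    stop_invalid("invalid canvas or fiber count")
  if (any(diameter_sdlog < 0)) stop_invalid("`diameter_sdlog` must be >= 0")
  if (length(diameter_meanlog) != length(diameter_sdlog))
    stop_invalid("diameter mixture parameter lengths differ")
  if (is.null(diameter_weights))
    diameter_weights <- rep(1 / length(diameter_meanlog),
                            length(diameter_meanlog))
  if (length(diameter_weights) != length(diameter_meanlog) ||
      any(diameter_weights < 0) || sum(diameter_weights) <= 0)
    stop_invalid("invalid diameter mixture weights")
  if (!(g_lower > 0 && g_lower < g_upper && g_upper < 1) || g_sd < 0)
    stop_invalid("g-ratio distribution bounds must satisfy 0 < lower < upper < 1")
  if (ellipse_ecc_max < 0 || ellipse_ecc_max >= 1)
    stop_invalid("`ellipse_ecc_max` must lie in [0, 1)")
  grays <- c(gray_background, gray_axon, gray_myelin)
  if (any(grays < 0 | grays > 255)) stop_invalid("gray levels must lie in [0, 255]")
  if (p_split < 0 || p_split > 1 || p_unmyelinated < 0 || p_unmyelinated > 1)
    stop_invalid("probabilities must lie in [0, 1]")
  structure(list(
    width = as.integer(width), height = as.integer(height),
    pixel_size = pixel_size, n_fibers = as.integer(n_fibers),
    diameter_meanlog = diameter_meanlog, diameter_sdlog = diameter_sdlog,
    diameter_weights = diameter_weights / sum(diameter_weights),
    g_mean = g_mean, g_sd = g_sd, g_lower = g_lower, g_upper = g_upper,
    min_gap = min_gap, ellipse_ecc_max = ellipse_ecc_max,
    gray_background = gray_background, gray_axon = gray_axon,
    gray_myelin = gray_myelin, noise_sd = noise_sd,
    p_split = p_split, p_unmyelinated = p_unmyelinated,
    max_attempts = as.integer(max_attempts), seed = as.integer(seed)),
    class = "simulation_config")
}

rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Draw a fiber population from the configured distributions
#'
#' Uses the current RNG state; [simulate_sample] seeds it once from
#' `cfg$seed` so the whole pipeline is one deterministic stream.
#'
#' @param cfg A [simulation_config].
#' @return Tibble with `diameter_um` (axon equivalent diameter), `g`, `ecc`,
#'   `angle_deg` (uniform orientation).
#' @export
sample_fiber_population <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  n <- cfg$n_fibers
  if (n == 0L)
    return(tibble::tibble(diameter_um = numeric(), g = numeric(),
                          ecc = numeric(), angle_deg = numeric()))
  comp <- sample.int(length(cfg$diameter_weights), n, replace = TRUE,
                     prob = cfg$diameter_weights)
  d <- stats::rlnorm(n, cfg$diameter_meanlog[comp], cfg$diameter_sdlog[comp])
  tibble::tibble(
    diameter_um = d,
    g = rtruncnorm(n, cfg$g_mean, cfg$g_sd, cfg$g_lower, cfg$g_upper),
    ecc = stats::runif(n, 0, cfg$ellipse_ecc_max),
    angle_deg = stats::runif(n, -90, 90))
}

# Semi-axes (px) of an ellipse with the given equivalent diameter (um) and
# eccentricity: area pi*a*b preserved, b = a*sqrt(1-e^2).
ellipse_axes_px <- function(equiv_diameter_um, ecc, pixel_size) {
  area_px <- pi * (equiv_diameter_um / pixel_size)^2 / 4
  a <- sqrt(area_px / (pi * sqrt(1 - ecc^2)))
  c(a = a, b = a * sqrt(1 - ecc^2))
}

#' Place fibers on the canvas without overlap
#'
#' Dart-throwing, largest outer ellipse first; a candidate center is accepted
#' if the fiber's outer ellipse fits the canvas and its boundary stays at
#' least `min_gap` away from every accepted fiber (conservative
#' circumscribed-circle test on the semi-major axes). Fibers still unplaced
#' after `max_attempts` tries are dropped and the shortfall reported via the
#' `n_dropped` attribute.
#'
#' @param params A [sample_fiber_population] tibble.
#' @param cfg A [simulation_config].
#' @return Tibble of placed fibers (`row`, `col` center in 1-based px,
#'   `diameter_um`, `g`, `ecc`, `angle_deg`, `a_out`, `b_out` outer semi-axes
#'   px, `has_split`), attribute `n_dropped`.
#' @export
place_fibers <- function(params, cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  n <- nrow(params)
  if (n > 0L) {
    outer_d <- params$diameter_um / params$g
    ord <- order(-outer_d)
    params <- params[ord, , drop = FALSE]
    outer_d <- outer_d[ord]
  }
  acc_r <- numeric(0); acc_c <- numeric(0); acc_a <- numeric(0)
  keep <- logical(n); rows <- numeric(n); cols <- numeric(n)
  a_out <- numeric(n); b_out <- numeric(n)
  for (i in seq_len(n)) {
    ax <- ellipse_axes_px(outer_d[i], params$ecc[i], cfg$pixel_size)
    a_out[i] <- ax["a"]; b_out[i] <- ax["b"]
    margin <- ax["a"] + 1
    if (2 * margin >= min(cfg$height, cfg$width)) next
    for (try in seq_len(cfg$max_attempts)) {
      r <- stats::runif(1, margin, cfg$height - margin + 1)
      c_ <- stats::runif(1, margin, cfg$width - margin + 1)
      if (length(acc_r) == 0L ||
          all(sqrt((acc_r - r)^2 + (acc_c - c_)^2) >=
              acc_a + ax["a"] + cfg$min_gap)) {
        keep[i] <- TRUE; rows[i] <- r; cols[i] <- c_
        acc_r <- c(acc_r, r); acc_c <- c(acc_c, c_); acc_a <- c(acc_a, ax["a"])
        break
      }
    }
  }
  out <- tibble::tibble(
    row = rows[keep], col = cols[keep],
    diameter_um = params$diameter_um[keep], g = params$g[keep],
    ecc = params$ecc[keep], angle_deg = params$angle_deg[keep],
    a_out = a_out[keep], b_out = b_out[keep],
    has_split = rep(FALSE, sum(keep)))
  attr(out, "n_dropped") <- n - sum(keep)
  out
}

# logical matrix of pixels (in the given index window) inside the rotated
# ellipse; returns the window indices and normalized elliptical radius
ellipse_window <- function(center_r, center_c, a, b, angle_deg, nr, nc) {
  theta <- angle_deg * pi / 180
  r0 <- max(1L, floor(center_r - a)); r1 <- min(nr, ceiling(center_r + a))
  c0 <- max(1L, floor(center_c - a)); c1 <- min(nc, ceiling(center_c + a))
  ri <- r0:r1; ci <- c0:c1
  dy <- ri - center_r; dx <- ci - center_c
  # x = column axis, y = row axis; rotate into the ellipse frame
  u <- outer(dy, dx, function(y, x) x * cos(theta) + y * sin(theta))
  v <- outer(dy, dx, function(y, x) -x * sin(theta) + y * cos(theta))
  rho <- sqrt((u / a)^2 + (v / b)^2)
  list(ri = ri, ci = ci, rho = rho)
}

#' Rasterize placed fibers into image, ground-truth mask and truth table
#'
#' Each fiber's outer ellipse has equivalent diameter `diameter_um / g` and
#' its concentric inner (axon) ellipse equivalent diameter `diameter_um`.
#' The mask gets axon inside the inner ellipse and myelin in the annulus;
#' the image gets the configured mean gray levels plus Gaussian noise.
#' Myelin-split artifacts (probability `p_split` per fiber) cut a bright
#' 1-2 px circumferential band through mid-annulus in both image and mask;
#' unmyelinated blobs (`p_unmyelinated` of the fiber count) are dark disks
#' drawn in the image only.
#'
#' @param fibers A [place_fibers] tibble.
#' @param cfg A [simulation_config].
#' @return A `simulated_sample`: `image` ([intensity_image]), `truth_mask`
#'   ([semantic_mask]), `truth_table` tibble (`fiber_id`, `row`, `col`,
#'   `true_axon_diameter_um`, `true_g`, `ecc`, `angle_deg`, `has_split`),
#'   `config`.
#' @export
rasterize_sample <- function(fibers, cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  nr <- cfg$height; nc <- cfg$width
  lab <- matrix(MASK_BACKGROUND, nr, nc)
  img <- matrix(cfg$gray_background, nr, nc)
  n <- nrow(fibers)
  has_split <- if (n > 0L) stats::runif(n) < cfg$p_split else logical(0)
  for (i in seq_len(n)) {
    w <- ellipse_window(fibers$row[i], fibers$col[i],
                        fibers$a_out[i], fibers$b_out[i],
                        fibers$angle_deg[i], nr, nc)
    kappa <- fibers$g[i]          # inner/outer linear scale = g
    annulus <- w$rho <= 1 & w$rho > kappa
    inner <- w$rho <= kappa
    block_lab <- lab[w$ri, w$ci, drop = FALSE]
    block_img <- img[w$ri, w$ci, drop = FALSE]
    block_lab[annulus] <- MASK_MYELIN
    block_lab[inner] <- MASK_AXON
    block_img[annulus] <- cfg$gray_myelin
    block_img[inner] <- cfg$gray_axon
    if (has_split[i]) {
      half_rho <- stats::runif(1, 0.5, 1) / fibers$a_out[i]  # 1-2 px band
      mid <- (1 + kappa) / 2
      band <- annulus & abs(w$rho - mid) <= half_rho
      block_lab[band] <- MASK_BACKGROUND
      block_img[band] <- cfg$gray_background
    }
    lab[w$ri, w$ci] <- block_lab
    img[w$ri, w$ci] <- block_img
  }
  # image-only unmyelinated distractors: dark disks in free background
  n_blob <- round(cfg$p_unmyelinated * n)
  if (n_blob > 0L) {
    blob_d <- stats::rlnorm(n_blob,
                            cfg$diameter_meanlog[1], cfg$diameter_sdlog[1])
    for (j in seq_len(n_blob)) {
      rad <- blob_d[j] / cfg$pixel_size / 2
      for (try in seq_len(cfg$max_attempts)) {
        r <- stats::runif(1, rad + 1, nr - rad)
        c_ <- stats::runif(1, rad + 1, nc - rad)
        w <- ellipse_window(r, c_, rad, rad, 0, nr, nc)
        inside <- w$rho <= 1
        if (all(lab[w$ri, w$ci][inside] == MASK_BACKGROUND)) {
          block <- img[w$ri, w$ci, drop = FALSE]
          block[inside] <- cfg$gray_myelin + 40
          img[w$ri, w$ci] <- block
          break
        }
      }
    }
  }
  if (cfg$noise_sd > 0)
    img <- img + matrix(stats::rnorm(nr * nc, 0, cfg$noise_sd), nr, nc)
  img <- pmin(pmax(round(img), 0), 255)
  truth <- tibble::tibble(
    fiber_id = seq_len(n), row = fibers$row, col = fibers$col,
    true_axon_diameter_um = fibers$diameter_um, true_g = fibers$g,
    ecc = fibers$ecc, angle_deg = fibers$angle_deg, has_split = has_split)
  structure(list(image = intensity_image(img, cfg$pixel_size),
                 truth_mask = semantic_mask(lab, cfg$pixel_size),
                 truth_table = truth, config = cfg),
            class = "simulated_sample")
}

#' Simulate a complete nerve cross-section phantom
#'
#' Seeds one RNG stream from `cfg$seed`, then samples the fiber population,
#' places it and rasterizes it. Identical configurations give byte-identical
#' outputs.
#'
#' @param cfg A [simulation_config].
#' @return A `simulated_sample` (see [rasterize_sample]).
#' @export
simulate_sample <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)
  params <- sample_fiber_population(cfg)
  placed <- place_fibers(params, cfg)
  out <- rasterize_sample(placed, cfg)
  attr(out, "n_dropped") <- attr(placed, "n_dropped")
  out
}

#' Write a simulated sample to an output directory
#'
#' Writes `image.png`, `mask.png` (8-bit, background 0 / myelin 127 /
#' axon 255), `truth.csv` and the echoed `config.json`.
#'
#' @param sample A [simulate_sample] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulated_sample <- function(sample, dir) {
  stopifnot(inherits(sample, "simulated_sample"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_intensity_image(sample$image, file.path(dir, "image.png"))
  write_mask(sample$truth_mask, file.path(dir, "mask.png"))
  utils::write.csv(as.data.frame(sample$truth_table),
                   file.path(dir, "truth.csv"), row.names = FALSE)
  jsonlite::write_json(unclass(sample$config),
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
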