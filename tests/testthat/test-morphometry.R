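test_that("circular-model formulas are exact on closed-form cases", {
  expect_equal(axon_diameter_from_area(pi), 2)
  expect_equal(axon_diameter_from_area(0), 0)
  expect_error(axon_diameter_from_area(-1), class = "nervemorph_invalid_argument")

  expect_equal(myelin_thickness_from_areas(pi, 3 * pi), 1)
  expect_equal(myelin_thickness_from_areas(pi, 0), 0)
  expect_equal(myelin_thickness_from_areas(0, pi), 1)
  expect_error(myelin_thickness_from_areas(-1, 1),
               class = "nervemorph_invalid_argument")

  expect_equal(g_ratio(pi, 3 * pi), 0.5)
  expect_equal(g_ratio(pi, 0), 1)
  expect_equal(g_ratio(64 * pi, 36 * pi), 0.8)
  expect_error(g_ratio(0, 0), class = "nervemorph_invalid_argument")
})

test_that("diameter from a rasterized disk area is within 2% of analytic", {
  # lattice-point count as the area oracle: radius 20 px at 0.1 um/px
  area_um2 <- disk_pixels(20) * 0.1^2
  d <- axon_diameter_from_area(area_um2)
  expect_lt(abs(d - 4) / 4, 0.02)
})

test_that("shape descriptors match analytic moments and hull geometry", {
  disk <- annulus_mask(40, 40, 20, 20, r_in = 15, r_out = 0)
  sd_ <- shape_descriptors(which(disk$labels == MASK_AXON, arr.ind = TRUE))
  expect_lte(sd_$eccentricity, 0.1)
  expect_gte(sd_$solidity, 0.95)
  expect_equal(sd_$centroid_x, 19, tolerance = 1e-8)  # 0-based center
  expect_equal(sd_$centroid_y, 19, tolerance = 1e-8)

  # axis-aligned ellipse, x semi-axis 20, y semi-axis 10
  lab <- matrix(0L, 30, 50)
  for (i in 1:30) for (j in 1:50)
    if (((j - 25) / 20)^2 + ((i - 15) / 10)^2 <= 1) lab[i, j] <- MASK_AXON
  sd_ <- shape_descriptors(which(lab == MASK_AXON, arr.ind = TRUE))
  expect_equal(sd_$eccentricity, sqrt(1 - 1 / 4), tolerance = 0.02)
  expect_equal(sd_$orientation_deg, 0, tolerance = 1)

  # major axis along y (rows): orientation 90 degrees in the y-down frame
  sd_t <- shape_descriptors(which(t(lab) == MASK_AXON, arr.ind = TRUE))
  expect_equal(sd_t$orientation_deg, 90, tolerance = 1)

  # L-shaped hexomino: 6 px, hull holds 7 lattice points (hand enumeration)
  L <- rbind(c(1, 1), c(2, 1), c(3, 1), c(4, 1), c(4, 2), c(4, 3))
  expect_equal(shape_descriptors(L)$solidity, 6 / 7)

  one <- shape_descriptors(rbind(c(5, 5)))
  expect_equal(one$solidity, 1)
  expect_equal(one$eccentricity, 0)
  expect_equal(one$orientation_deg, 0)
  expect_error(shape_descriptors(matrix(numeric(), ncol = 2)),
               class = "nervemorph_invalid_argument")
})

test_that("hull fill agrees with an independent point-in-polygon oracle", {
  skip_if_not_installed("mgcv")
  set.seed(41)
  for (rep in 1:8) {
    pts <- unique(cbind(sample(0:12, 15, TRUE), sample(0:12, 15, TRUE)))
    x <- pts[, 1]; y <- pts[, 2]
    got <- nervemorph:::hull_pixel_count(x, y)
    h <- grDevices::chull(x, y)
    if (length(h) <= 2) next
    bnd <- cbind(x[h], y[h])
    grid <- expand.grid(gx = min(x):max(x), gy = min(y):max(y))
    inside <- mgcv::in.out(rbind(bnd, bnd[1, ]),
                           as.matrix(grid))
    # in.out excludes boundary points; count them explicitly
    on_hull <- rep(FALSE, nrow(grid))
    m <- nrow(bnd)
    for (i in seq_len(m)) {
      j <- if (i == m) 1L else i + 1L
      ex <- bnd[j, 1] - bnd[i, 1]; ey <- bnd[j, 2] - bnd[i, 2]
      px <- grid$gx - bnd[i, 1]; py <- grid$gy - bnd[i, 2]
      colin <- abs(ex * py - ey * px) < 1e-9
      within <- px * ex + py * ey >= -1e-9 &
        px * ex + py * ey <= ex^2 + ey^2 + 1e-9
      on_hull <- on_hull | (colin & within)
    }
    expect_equal(got, sum(inside | on_hull))
  }
})

test_that("fiber measurement reproduces annulus geometry within rasterization", {
  empty <- build_fiber_set(semantic_mask(matrix(0L, 10, 10), 0.1))
  expect_equal(nrow(measure_fiber_set(empty)), 0L)

  ann <- annulus_mask(64, 64, 32, 32, r_in = 10, r_out = 15)
  tbl <- measure_fiber_set(build_fiber_set(ann))
  expect_equal(nrow(tbl), 1L)
  expect_equal(tbl$axon_diameter_um, 2.0, tolerance = 0.05)
  expect_equal(tbl$myelin_thickness_um, 0.5, tolerance = 0.05)
  expect_equal(tbl$g_ratio, 2 / 3, tolerance = 0.05)
  expect_equal(tbl$axon_area_um2, disk_pixels(10) * 0.01)
})

test_that("derived quantities obey the circular-model identities", {
  set.seed(42)
  m <- random_mask(50, 50, probs = c(0.5, 0.3, 0.2))
  tbl <- measure_fiber_set(build_fiber_set(m, min_axon_px = 1L))
  fiber_d <- 2 * sqrt((tbl$axon_area_um2 + tbl$myelin_area_um2) / pi)
  expect_equal(tbl$g_ratio * fiber_d, tbl$axon_diameter_um)
  expect_true(all((tbl$myelin_thickness_um == 0) == (tbl$myelin_area_um2 == 0)))
  expect_true(all(diff(tbl$axon_diameter_um[order(tbl$axon_area_um2)]) >= 0))
})

test_that("scaling the pixel size scales areas and lengths but not ratios", {
  ann <- annulus_mask(64, 64, 32, 32, r_in = 10, r_out = 15, ps = 0.1)
  ann2 <- semantic_mask(ann$labels, 0.2)
  t1 <- measure_fiber_set(build_fiber_set(ann))
  t2 <- measure_fiber_set(build_fiber_set(ann2))
  expect_equal(t2$axon_area_um2, 4 * t1$axon_area_um2)
  expect_equal(t2$axon_diameter_um, 2 * t1$axon_diameter_um)
  expect_equal(t2$myelin_thickness_um, 2 * t1$myelin_thickness_um)
  expect_equal(t2$g_ratio, t1$g_ratio)
  expect_equal(t2$solidity, t1$solidity)
  expect_equal(t2$eccentricity, t1$eccentricity)
  expect_equal(t2$orientation_deg, t1$orientation_deg)
})

test_that("artifact flags follow the g-ratio and diameter thresholds", {
  tbl <- tibble::tibble(
    fiber_id = 1:3,
    axon_diameter_um = c(1.0, 4.0, 0.1),
    g_ratio = c(0.20, 0.65, 0.95),
    flags = c("", "", "BORDER"))
  out <- flag_artifacts(tbl, flag_config())
  expect_equal(out$flags[1], "LOW_G")
  expect_equal(out$flags[2], "")
  expect_equal(out$flags[3], "BORDER;HIGH_G;SMALL_AXON")
})

test_that("morphometry CSV round-trips with the documented header", {
  ann <- annulus_mask(64, 64, 32, 32, r_in = 10, r_out = 15)
  tbl <- flag_artifacts(measure_fiber_set(build_fiber_set(ann)))
  path <- tempfile(fileext = ".csv")
  write_morphometry_csv(tbl, path)
  back <- read_morphometry_csv(path)
  expect_equal(names(back),
               c("fiber_id", "x_px", "y_px", "x_um", "y_um", "axon_area_um2",
                 "axon_diameter_um", "myelin_area_um2", "myelin_thickness_um",
                 "g_ratio", "solidity", "eccentricity", "orientation_deg",
                 "flags"))
  expect_equal(back$g_ratio, tbl$g_ratio)
  unlink(path)
})

test_that("overlay tints classes and prints one numeral per fiber", {
  ann <- annulus_mask(64, 64, 32, 32, r_in = 10, r_out = 15)
  bare <- render_overlay(ann)
  # myelin tinted red, axon blue, no white text pixels inside the fiber
  my <- ann$labels == MASK_MYELIN
  expect_true(all(bare[, , 1][my] > bare[, , 3][my]))
  ax <- ann$labels == MASK_AXON
  expect_true(all(bare[, , 3][ax] > bare[, , 1][ax]))

  lab <- matrix(0L, 60, 120)
  centers <- list(c(15, 20), c(30, 60), c(45, 100))
  for (ct in centers)
    for (i in -8:8) for (j in -8:8) {
      d2 <- i^2 + j^2
      if (d2 <= 16) lab[ct[1] + i, ct[2] + j] <- MASK_AXON
      else if (d2 <= 64) lab[ct[1] + i, ct[2] + j] <- MASK_MYELIN
    }
  mask <- semantic_mask(lab, 0.1)
  tbl <- measure_fiber_set(build_fiber_set(mask))
  expect_equal(nrow(tbl), 3L)
  ov <- render_overlay(mask, tbl)
  white <- ov[, , 1] == 255 & ov[, , 2] == 255 & ov[, , 3] == 255 &
    mask$labels != MASK_BACKGROUND
  # one digit cluster at each axon centroid (ids 1-3 are single glyphs)
  cl <- nervemorph:::label_components(white, 8L)
  expect_equal(max(cl), 3L)
  for (i in seq_len(3)) {
    px <- which(cl > 0, arr.ind = TRUE)
    ct <- centers[[i]]
    expect_true(any(abs(px[, 1] - ct[1]) <= 4 & abs(px[, 2] - ct[2]) <= 8))
  }
})
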