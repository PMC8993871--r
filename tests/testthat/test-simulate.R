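test_that("fiber population sampling follows the configured distributions", {
  cfg0 <- simulation_config(n_fibers = 0)
  expect_equal(nrow(sample_fiber_population(cfg0)), 0L)

  degen <- simulation_config(n_fibers = 20, diameter_meanlog = log(3),
                             diameter_sdlog = 0)
  set.seed(71)
  p <- sample_fiber_population(degen)
  expect_equal(p$diameter_um, rep(3, 20))

  big <- simulation_config(n_fibers = 10000, diameter_meanlog = log(4),
                           diameter_sdlog = 0.3)
  set.seed(72)
  p <- sample_fiber_population(big)
  mu <- 4 * exp(0.3^2 / 2)                       # lognormal mean
  se <- sqrt((exp(0.3^2) - 1) * mu^2 / 10000)    # Monte-Carlo SE
  expect_lt(abs(mean(p$diameter_um) - mu), 3 * se)
  expect_true(all(p$g > big$g_lower & p$g < big$g_upper))
  expect_true(all(p$ecc >= 0 & p$ecc <= big$ellipse_ecc_max))
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(g_lower = 0.8, g_upper = 0.5),
               class = "nervemorph_invalid_argument")
  expect_error(simulation_config(diameter_sdlog = -1),
               class = "nervemorph_invalid_argument")
  expect_error(simulation_config(gray_background = 300),
               class = "nervemorph_invalid_argument")
  expect_error(simulation_config(p_split = 1.5),
               class = "nervemorph_invalid_argument")
})

test_that("placement keeps outer boundaries at least min_gap apart", {
  small <- simulation_config(width = 400, height = 400, n_fibers = 1, seed = 73)
  set.seed(73)
  placed <- place_fibers(sample_fiber_population(small), small)
  expect_equal(nrow(placed), 1L)

  # two 60-px fibers cannot both fit a 64x64 canvas
  crowded <- simulation_config(width = 64, height = 64, n_fibers = 2,
                               diameter_meanlog = log(6 * 0.65),
                               diameter_sdlog = 0, g_mean = 0.65, g_sd = 0,
                               ellipse_ecc_max = 0, seed = 74)
  set.seed(74)
  placed <- place_fibers(sample_fiber_population(crowded), crowded)
  expect_lte(nrow(placed), 1L)

  cfg <- simulation_config(width = 1024, height = 1024, n_fibers = 50,
                           seed = 75)
  set.seed(75)
  placed <- place_fibers(sample_fiber_population(cfg), cfg)
  expect_gte(nrow(placed), 45L)
  # exhaustive pairwise audit: center distance minus both semi-major axes
  # bounds the outer-boundary distance from below
  for (i in seq_len(nrow(placed) - 1)) for (j in (i + 1):nrow(placed)) {
    gap <- sqrt((placed$row[i] - placed$row[j])^2 +
                (placed$col[i] - placed$col[j])^2) -
      placed$a_out[i] - placed$a_out[j]
    expect_gte(gap, cfg$min_gap)
  }
})

test_that("rasterization matches lattice-point counts for circular fibers", {
  cfg <- simulation_config(width = 128, height = 128, n_fibers = 0,
                           noise_sd = 0, seed = 76)
  blank <- rasterize_sample(place_fibers(sample_fiber_population(cfg), cfg), cfg)
  expect_true(all(blank$truth_mask$labels == MASK_BACKGROUND))
  expect_true(all(blank$image$pixels == cfg$gray_background))

  one <- tibble::tibble(row = 64.5, col = 64.5, diameter_um = 4, g = 0.5,
                        ecc = 0, angle_deg = 0, a_out = 40, b_out = 40,
                        has_split = FALSE)
  cfg0 <- simulation_config(width = 128, height = 128, n_fibers = 1,
                            noise_sd = 0, seed = 77)
  set.seed(77)
  s <- rasterize_sample(one, cfg0)
  n_axon <- sum(s$truth_mask$labels == MASK_AXON)
  n_myelin <- sum(s$truth_mask$labels == MASK_MYELIN)
  expect_lt(abs(n_axon - pi * 20^2) / (pi * 20^2), 0.01)
  expect_lt(abs(n_myelin - pi * (40^2 - 20^2)) / (pi * (40^2 - 20^2)), 0.01)
})

test_that("unmyelinated blobs perturb the image but never the truth mask", {
  base <- simulation_config(width = 512, height = 512, n_fibers = 10,
                            p_unmyelinated = 0, seed = 78)
  with_blobs <- simulation_config(width = 512, height = 512, n_fibers = 10,
                                  p_unmyelinated = 0.3, seed = 78)
  a <- simulate_sample(base)
  b <- simulate_sample(with_blobs)
  expect_identical(tabulate(a$truth_mask$labels + 1L, 3L),
                   tabulate(b$truth_mask$labels + 1L, 3L))
  expect_identical(a$truth_mask$labels, b$truth_mask$labels)
})

test_that("myelin-split artifacts cut both the image and the truth mask", {
  cfg <- simulation_config(width = 512, height = 512, n_fibers = 8,
                           p_split = 1, seed = 79)
  s <- simulate_sample(cfg)
  expect_true(all(s$truth_table$has_split))
  # each split ring separates into two myelin components
  n_myelin_comp <- max(nervemorph:::label_components(
    s$truth_mask$labels == MASK_MYELIN, 8L))
  expect_gt(n_myelin_comp, nrow(s$truth_table))

  clean <- simulate_sample(simulation_config(width = 512, height = 512,
                                             n_fibers = 8, p_split = 0,
                                             seed = 79))
  expect_gt(sum(clean$truth_mask$labels == MASK_MYELIN),
            sum(s$truth_mask$labels == MASK_MYELIN))
})

test_that("simulation is deterministic in configuration and seed", {
  cfg <- simulation_config(width = 256, height = 256, n_fibers = 10,
                           p_split = 0.2, p_unmyelinated = 0.2, seed = 80)
  a <- simulate_sample(cfg)
  b <- simulate_sample(cfg)
  expect_identical(a$truth_table, b$truth_table)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth_mask$labels, b$truth_mask$labels)
})

test_that("instance extraction recovers exactly the placed fibers", {
  cfg <- simulation_config(width = 1024, height = 1024, n_fibers = 50,
                           seed = 81)
  s <- simulate_sample(cfg)
  expect_equal(nrow(s$truth_table), 50L)
  fs <- build_fiber_set(s$truth_mask)
  expect_equal(nrow(fs$fibers), 50L)
  tbl <- measure_fiber_set(fs)
  # centers match within 1 px (nearest-center pairing)
  for (i in seq_len(nrow(tbl))) {
    d <- sqrt((s$truth_table$row - (tbl$y_px[i] + 1))^2 +
              (s$truth_table$col - (tbl$x_px[i] + 1))^2)
    expect_lt(min(d), 1)
  }
})
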