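test_that("grid targets have lines exactly where the closed form predicts", {
  g <- make_grid(1000, 1000, 100, 3)
  # 11 vertical and 11 horizontal line centers at multiples of 100
  on <- function(n, spacing, line)
    (((0:(n - 1)) + line %/% 2) %% spacing) < line
  vcols <- which(apply(g == 255, 2, all)) - 1
  expect_equal(vcols, which(on(1000, 100, 3)) - 1)
  expect_equal(sum(diff(c(-10, vcols)) > 1), 11)   # 11 distinct lines
  # total white-pixel count equals the inclusion-exclusion closed form
  nv <- sum(on(1000, 100, 3)); nh <- sum(on(1000, 100, 3))
  expect_equal(sum(g == 255), nv * 1000 + nh * 1000 - nv * nh)
  expect_error(make_grid(100, 100, 3, 3), "spacing")
})

test_that("tissue scenes are deterministic with Poisson-consistent nuclei counts", {
  p <- scene_params(width_px = 300, height_px = 300, seed = 21)
  s1 <- make_tissue_scene(p)
  s2 <- make_tissue_scene(p)
  expect_identical(s1$thg, s2$thg)
  expect_identical(s1$tpef, s2$tpef)
  expect_identical(s1$nuclei, s2$nuclei)
  expect_8bit_image(s1$thg)
  expect_8bit_image(s1$tpef)

  # zero density: haze only, empty nuclei table
  s0 <- make_tissue_scene(scene_params(width_px = 200, height_px = 200,
                                       nuclei_density = 0, seed = 2))
  expect_equal(nrow(s0$nuclei), 0)
  expect_lt(max(abs(s0$thg - 20)), 10)   # haze +- smooth noise only

  # realized counts stay within 3 sigma of the Poisson mean (area = 0.09 mm^2)
  lambda <- 1500 * 0.09
  counts <- sapply(1:10, function(s)
    nrow(make_tissue_scene(scene_params(width_px = 300, height_px = 300,
                                        seed = s))$nuclei))
  expect_true(mean(abs(counts - lambda) <= 3 * sqrt(lambda)) >= 0.9)
})

test_that("the scan simulator tiles the scene with the planned geometry", {
  sc <- fixture_scene()
  scene <- list(thg = sc$thg[1:850, 1:1200], tpef = sc$tpef[1:850, 1:1200])
  sim <- simulate_scan(scene, scan_config(tile_px = 400, jitter_px = 0,
                                          noise_sd = 0, seed = 1))
  # 3 x 2 grid at stride round(0.91 * 400) = 364
  expect_equal(nrow(sim$truth), 6)
  expect_equal(max(sim$truth$nominal_x_px), 2 * 364)
  expect_equal(max(sim$truth$nominal_y_px), 364)
  # identity pipeline: tiles equal scene crops exactly
  for (i in seq_along(sim$tiles)) {
    tr <- sim$truth[i, ]
    crop <- scene$thg[tr$true_y_px + 1:400, tr$true_x_px + 1:400]
    expect_identical(sim$tiles[[i]]$channels[[1]], crop)
  }
  # stage log reports nominal positions in micrometres
  expect_equal(sim$stage_log$stage_x_um, sim$truth$nominal_x_px)  # 1000 nm pitch
})

test_that("jitter is bounded, non-trivial and hidden from the stage log", {
  sc <- fixture_scene()
  jit <- NULL
  for (seed in 1:6) {
    sim <- simulate_scan(list(thg = sc$thg, tpef = sc$tpef),
                         scan_config(tile_px = 300, jitter_px = 8,
                                     noise_sd = 0, seed = seed))
    jit <- c(jit, sim$truth$true_x_px - sim$truth$nominal_x_px,
             sim$truth$true_y_px - sim$truth$nominal_y_px)
  }
  expect_true(all(abs(jit) <= 8))
  expect_gt(length(unique(jit)), 8)      # spread across the range
  expect_gt(max(abs(jit)), 5)
  expect_error(scan_config(tile_px = 300, jitter_px = 40),
               "overlap")
})

test_that("same-seed scans are bit-identical", {
  sc <- fixture_scene()
  scene <- list(thg = sc$thg[1:330, 1:600], tpef = sc$tpef[1:330, 1:600])
  cfg <- scan_config(tile_px = 300, jitter_px = 5, noise_sd = 5, seed = 77)
  a <- simulate_scan(scene, cfg)
  b <- simulate_scan(scene, cfg)
  expect_identical(lapply(a$tiles, `[[`, "channels"),
                   lapply(b$tiles, `[[`, "channels"))
  expect_identical(a$truth, b$truth)
})

test_that("tile images round-trip through per-channel TIFFs", {
  sc <- fixture_scene()
  sim <- simulate_scan(list(thg = sc$thg[1:330, 1:600],
                            tpef = sc$tpef[1:330, 1:600]),
                       scan_config(tile_px = 300, jitter_px = 3,
                                   noise_sd = 0, seed = 5))
  dir <- withr::local_tempdir()
  write_tile_images(sim$tiles, dir)
  back <- read_tile_images(dir, pixel_pitch_nm = 1000)
  expect_length(back, length(sim$tiles))
  for (i in seq_along(back)) {
    expect_equal(back[[i]]$tile_id, sim$tiles[[i]]$tile_id)
    expect_equal(back[[i]]$channels, sim$tiles[[i]]$channels)
    expect_equal(back[[i]]$stage_x_um, sim$tiles[[i]]$stage_x_um)
  }
})
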