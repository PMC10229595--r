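test_that("stage displacement converts to the expected pixel offset", {
  m <- matrix(0, 6000, 6000)
  t0 <- tile("a", 0, 0, 0, 0, list(m), 167)
  t1 <- tile("b", 1, 0, 910, 0, list(m), 167)
  off <- initial_offset(t1, t0)
  expect_equal(off$dx_px, 5449L)           # 910 um / 167 nm
  expect_equal(off$x_ov_px, 551L)          # ~9% of 6000
  expect_equal(initial_offset(t0, t0)$dx_px, 0L)
  expect_equal(initial_offset(t0, t0)$x_ov_px, 6000L)
  t2 <- tile("c", 1, 0, 6000 * 167 / 1000, 0, list(m), 167)
  expect_equal(initial_offset(t2, t0)$x_ov_px, 0L)
})

test_that("sigma scoring is zero at the true offset and additive over neighbors", {
  sc <- fixture_scene()
  tile_img <- sc$tpef[1:200, 1:200]
  plan <- plan_mosaic(2, 2, 200, 0.1, 1000)
  canvas <- mosaic_canvas(plan, channels = 1, margin_px = 32)
  t0 <- tile("t0", 0, 0, 0, 0, list(tile_img), 1000)
  res0 <- data.frame(tile_id = "t0", placed_x_px = 0L, placed_y_px = 0L,
                     x_ov = NA, y_al = NA, sigma_min = NA, sigma_max = NA,
                     refined = FALSE, fallback = FALSE)
  canvas <- composite_tile(canvas, t0, res0)
  nb <- list(c(0, 0, 200, 200))
  # identical copy at the exact overlap: zero score
  expect_equal(score_placement(c(0, 0), tile_img, canvas, nb), 0)
  # any shift on a textured scene scores strictly higher
  for (off in list(c(2, 0), c(0, 2), c(-4, 6), c(10, 10)))
    expect_gt(score_placement(off, tile_img, canvas, nb), 0)
  # no overlap at all: Inf
  expect_identical(score_placement(c(500, 500), tile_img, canvas, nb), Inf)
  # two-neighbor score is the sum of the single-neighbor scores
  nb2 <- list(c(0, 0, 200, 200), c(50, 0, 250, 120))
  s12 <- score_placement(c(20, 10), tile_img, canvas, nb2)
  s1 <- score_placement(c(20, 10), tile_img, canvas, nb2[1])
  s2 <- score_placement(c(20, 10), tile_img, canvas, nb2[2])
  expect_equal(s12, s1 + s2)
})

test_that("featureless overlaps trip the sigma gate and fall back to the stage estimate", {
  flat <- matrix(128, 300, 300)
  tiles <- list(tile("a", 0, 0, 0, 0, list(flat), 1000),
                tile("b", 1, 0, 273, 0, list(flat), 1000))
  res <- stitch_all(tiles)
  expect_true(res$placements$fallback[2])
  expect_false(res$placements$refined[2])
  expect_equal(res$placements$placed_x_px[2], 273L)
  expect_equal(res$placements$placed_y_px[2], 0L)
})

test_that("gated coarse-to-fine search equals the exhaustive fine search", {
  sc <- fixture_scene()
  search <- alignment_search()
  set.seed(5)
  mismatches <- 0L
  for (trial in 1:5) {
    x0 <- sample(0:500, 1); y0 <- sample(0:400, 1)
    scene <- list(thg = sc$thg[y0 + 1:330, x0 + 1:600],
                  tpef = sc$tpef[y0 + 1:330, x0 + 1:600])
    sim <- simulate_scan(scene, scan_config(tile_px = 300, jitter_px = 8,
                                            noise_sd = 5, seed = trial))
    tiles <- sim$tiles
    plan <- gigamosaic:::infer_plan(tiles)
    canvas <- mosaic_canvas(plan, channels = 2, margin_px = 56)
    res0 <- data.frame(tile_id = tiles[[1]]$tile_id, placed_x_px = 0L,
                       placed_y_px = 0L, x_ov = NA, y_al = NA,
                       sigma_min = NA, sigma_max = NA,
                       refined = FALSE, fallback = FALSE)
    canvas <- composite_tile(canvas, tiles[[1]], res0)
    est <- c(273L, 0L)
    nb <- list(c(0, 0, 300, 300)); attr(nb, "orientation") <- "horizontal"
    gated <- align_tile(tiles[[2]], canvas, search, est, nb)
    expect_true(gated$refined)
    oracle <- exhaustive_align(tiles[[2]], canvas, search, est, nb)
    if (gated$placed_x_px != oracle[1] || gated$placed_y_px != oracle[2])
      mismatches <- mismatches + 1L
    expect_equal(c(gated$placed_x_px, gated$placed_y_px),
                 unname(oracle), ignore_attr = TRUE)
  }
  expect_equal(mismatches, 0L)
})

test_that("compositing copies, overwrites and feathers as specified", {
  img <- fixture_scene()$thg[1:150, 1:150]
  tl <- tile("t", 0, 0, 0, 0, list(img), 1000)
  plan <- plan_mosaic(1, 1, 150, 0, 1000)
  res <- data.frame(tile_id = "t", placed_x_px = 0L, placed_y_px = 0L,
                    x_ov = NA, y_al = NA, sigma_min = NA, sigma_max = NA,
                    refined = FALSE, fallback = FALSE)
  for (blend in c("overwrite", "feather")) {
    canvas <- mosaic_canvas(plan, 1, margin_px = 8)
    canvas <- composite_tile(canvas, tl, res, blend = blend)
    rows <- 9:158; cols <- 9:158
    expect_equal(canvas$composite[rows, cols, 1], img)
  }
  # identical content with exact overlap reproduces the source content
  plan2 <- plan_mosaic(2, 1, 150, 0.2, 1000)
  big <- fixture_scene()$thg[1:150, 1:270]
  tA <- tile("A", 0, 0, 0, 0, list(big[, 1:150]), 1000)
  tB <- tile("B", 1, 0, 120, 0, list(big[, 121:270]), 1000)
  resB <- res; resB$tile_id <- "B"; resB$placed_x_px <- 120L
  for (blend in c("overwrite", "feather")) {
    canvas <- mosaic_canvas(plan2, 1, margin_px = 8)
    canvas <- composite_tile(canvas, tA, res, blend = blend)
    canvas <- composite_tile(canvas, tB, resB, blend = blend)
    got <- canvas$composite[9:158, 9:278, 1]
    tol <- if (blend == "overwrite") 0 else 1
    expect_lte(max(abs(got - big)), tol)
  }
  bad <- tile("x", 0, 0, 0, 0, list(img, img), 1000)
  canvas <- mosaic_canvas(plan, 1, margin_px = 8)
  expect_error(composite_tile(canvas, bad, res), "channel")
})

test_that("stitching recovers simulator ground truth within the fine step", {
  sc <- fixture_scene()
  sim <- simulate_scan(list(thg = sc$thg, tpef = sc$tpef),
                       scan_config(tile_px = 400, jitter_px = 8,
                                   noise_sd = 0, seed = 11))
  res <- stitch_all(sim$tiles, sim$stage_log)
  pe <- placement_error(res$placements, sim$truth)
  expect_true(all(abs(pe$per_tile$dx) <= 2))
  expect_true(all(abs(pe$per_tile$dy) <= 2))
  # determinism: bit-identical rerun
  res2 <- stitch_all(sim$tiles, sim$stage_log)
  expect_identical(res$canvas$composite, res2$canvas$composite)
  expect_identical(res$placements, res2$placements)
  # mosaic content reconstructs the scene once the search resolves the
  # jitter exactly (1-px fine step; a 2-px step leaves parity residuals
  # that cost tens of RMSE levels on sharp nuclei edges). The mosaic
  # origin is tile 0's true (jittered) scene position.
  resf <- stitch_all(sim$tiles, sim$stage_log,
                     search = alignment_search(fine_step_px = 1),
                     blend = "feather")
  expect_equal(placement_error(resf$placements, sim$truth)$max, 0)
  plan <- resf$canvas$plan
  H <- plan$mosaic_h_px; W <- plan$mosaic_w_px
  o <- resf$canvas$origin
  t0 <- sim$truth[1, ]
  xs <- max(0, -t0$true_x_px):(min(W, ncol(sc$thg) - t0$true_x_px) - 1)
  ys <- max(0, -t0$true_y_px):(min(H, nrow(sc$thg) - t0$true_y_px) - 1)
  mos <- resf$canvas$composite[o[2] + ys + 1, o[1] + xs + 1, 1]
  ref <- sc$thg[t0$true_y_px + ys + 1, t0$true_x_px + xs + 1]
  cov <- resf$canvas$covered[o[2] + ys + 1, o[1] + xs + 1]
  mask <- matrix(FALSE, nrow(mos), ncol(mos))
  mask[30:(nrow(mos) - 30), 30:(ncol(mos) - 30)] <- TRUE
  rec <- reconstruction_error(mos, ref, mask & cov)
  expect_lt(rec$combined, 5)
})

test_that("single-tile input yields the tile itself with no search", {
  img <- fixture_scene()$thg[1:200, 1:200]
  tl <- tile("only", 0, 0, 0, 0, list(img), 1000)
  res <- stitch_all(list(tl))
  o <- res$canvas$origin
  expect_equal(res$canvas$composite[o[2] + 1:200, o[1] + 1:200, 1], img)
  expect_equal(nrow(res$placements), 1L)
  expect_false(res$placements$refined[1])
})

test_that("duplicate and unlogged tiles are rejected by name", {
  img <- matrix(1, 50, 50)
  t1 <- tile("dup", 0, 0, 0, 0, list(img), 1000)
  t2 <- tile("dup", 1, 0, 45, 0, list(img), 1000)
  expect_error(stitch_all(list(t1, t2)), "dup")
  t3 <- tile("other", 1, 0, 45, 0, list(img), 1000)
  log <- data.frame(tile_id = "dup", grid_col = 0, grid_row = 0,
                    stage_x_um = 0, stage_y_um = 0)
  expect_error(stitch_all(list(t1, t3), stage_log = log), "other")
})

test_that("placement error does not improve when noise is added", {
  sc <- fixture_scene()
  scene <- list(thg = sc$thg[1:330, 1:600], tpef = sc$tpef[1:330, 1:600])
  med <- sapply(c(0, 10, 20), function(noise) {
    errs <- sapply(1:4, function(seed) {
      sim <- simulate_scan(scene, scan_config(tile_px = 300, jitter_px = 8,
                                              noise_sd = noise, seed = seed))
      placement_error(stitch_all(sim$tiles)$placements, sim$truth)$mean
    })
    median(errs)
  })
  expect_true(all(diff(med) >= -0.5))   # non-decreasing up to sampling slack
  expect_lte(med[2], 2)                 # still accurate at sigma = 10
})
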