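# Shared fixtures, built once per test run.

# small two-channel tissue scene reused by several stitching tests
fixture_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_tissue_scene(scene_params(width_px = 1200,
                                               height_px = 850, seed = 7))
    cache
  }
})

# distorted adjacent grid-tile pair for parameter-estimation tests:
# tiles of side `tile_px` cut from a dense calibration grid with ~9%
# overlap, each warped by the forward (inducing) distortion
grid_tile_pair <- function(params, tile_px = 300, overlap_frac = 0.09,
                           spacing = 50, line = 5) {
  stride <- round((1 - overlap_frac) * tile_px)
  g <- make_grid(stride + tile_px, tile_px, spacing, line)
  list(tileA = induce(g[, 1:tile_px], params),
       tileB = induce(g[, (stride + 1):(stride + tile_px)], params),
       rois = overlap_rois(tile_px, tile_px, tile_px - stride),
       clean = g, stride = stride)
}

# distorted adjacent pair cut from a textured tissue scene (the calibration
# situation of the real instrument); wider overlap than the acquisition
# default so that (A, X_off) are separately identifiable from one strip
tissue_tile_pair <- function(params, tile_px = 300, overlap_frac = 0.2) {
  sc <- fixture_scene()
  stride <- round((1 - overlap_frac) * tile_px)
  list(tileA = induce(sc$tpef[1:tile_px, 1:tile_px], params),
       tileB = induce(sc$tpef[1:tile_px, (stride + 1):(stride + tile_px)],
                      params),
       rois = overlap_rois(tile_px, tile_px, tile_px - stride))
}

# exhaustive fine-step alignment oracle: scores every offset of the full
# window at fine_step and applies the same deterministic tie-break as the
# gated search
exhaustive_align <- function(tl, canvas, search, est, neighbors) {
  img <- Reduce(`+`, tl$channels) / length(tl$channels)
  md <- gigamosaic:::neighbor_min_depth(est, ncol(img), nrow(img),
                                        neighbors, search$downscale_factor)
  xs <- seq(-search$range_x_px, search$range_x_px, by = search$fine_step_px)
  ys <- seq(-search$range_y_px, search$range_y_px, by = search$fine_step_px)
  cand <- as.matrix(expand.grid(x = est[1] + xs, y = est[2] + ys))
  sc <- apply(cand, 1, function(off)
    score_placement(off, img, canvas, neighbors, search$downscale_factor,
                    min_depth = md))
  disp <- (cand[, 1] - est[1])^2 + (cand[, 2] - est[2])^2
  cand[order(sc, disp, cand[, 2], cand[, 1])[1], ]
}

expect_8bit_image <- function(img) {
  expect_true(is.matrix(img) || length(dim(img)) == 3)
  expect_true(min(img) >= 0 && max(img) <= 255)
}
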