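test_that("pixel maps honor the center formulas and fixed point", {
  # hand arithmetic: c1 = 0.5*C*(1 + X/S), c2 = 0.5*R*(1 + Y/S)
  par <- distortion_params(25.2, 6, 20)
  maps <- compute_pixel_maps(par, 6000, 6000)
  expect_equal(maps$c1, 3300)
  expect_equal(maps$c2, 4000)
  rm(maps)

  # integer-center case: the distortion center is a fixed point of the maps
  m <- compute_pixel_maps(par, 300, 300)   # c1 = 165, c2 = 200
  expect_equal(m$c1, 165)
  expect_equal(m$c2, 200)
  expect_equal(m$Mx[201, 166], 165, tolerance = 1e-9)
  expect_equal(m$My[201, 166], 200, tolerance = 1e-9)
  expect_true(all(is.finite(m$Mx)) && all(is.finite(m$My)))

  expect_error(distortion_params(360, 0, 0), "0, 360")
  expect_error(distortion_params(-5, 0, 0), "0, 360")
  expect_error(compute_pixel_maps(par, 1, 300), ">= 2")
})

test_that("remapping is the identity in the A -> 0 limit", {
  set.seed(42)
  img <- matrix(round(runif(200 * 150) * 255), 150, 200)
  p <- distortion_params(0.01, 6, 20)
  expect_lt(mean(abs(compensate(img, p) - img)), 0.5)
  expect_lt(mean(abs(induce(img, p) - img)), 0.5)
})

test_that("compensate exactly undoes induce up to interpolation error", {
  sc <- fixture_scene()
  img <- sc$tpef[1:400, 1:400]
  ctr <- 41:360   # central 80%
  for (par in list(distortion_params(25.2, 6, 20),
                   distortion_params(51, -49, -47),
                   distortion_params(30, 10, 5, mode = "barrel"))) {
    rt <- compensate(induce(img, par), par)
    expect_lt(mean(abs(rt - img)[ctr, ctr]), 2)
  }
  # deterministic: two runs are bit-identical
  par <- distortion_params(25.2, 6, 20)
  expect_identical(compensate(img, par), compensate(img, par))
  expect_error(compensate(img[1:100, ], par,
                          compute_pixel_maps(par, 400, 400)), "shape")
})

test_that("induced distortion displaces grid lines monotonically with radius", {
  par <- distortion_params(40, 0, 0)   # symmetric for a clean radial read
  g <- make_grid(401, 401, 50, 3)
  dst <- induce(g, par)
  # vertical line centers along the central row, relative to image center
  row <- dst[201, ]
  centers <- sapply(seq(0, 400, 50), function(x0) {
    win <- max(1, x0 - 20):min(401, x0 + 22)
    sum(win * row[win]) / sum(row[win]) - 1
  })
  disp <- abs(centers - seq(0, 400, 50))
  radius <- abs(seq(0, 400, 50) - 200)
  ord <- order(radius)
  expect_true(all(diff(disp[ord]) > -0.5))  # non-decreasing with radius
  expect_gt(max(disp), 2)                   # and genuinely displaced
})

test_that("grid lines curved by induce become straight after compensate", {
  par <- distortion_params(51, -49, -47)
  g <- make_grid(600, 600, 50, 5)
  comp <- compensate(induce(g, par), par)
  # trace one interior vertical line: centroid of white pixels per row
  x0 <- 300
  centers <- sapply(seq(30, 570, 10), function(y) {
    win <- (x0 - 15):(x0 + 15)
    v <- comp[y, win]
    if (sum(v) == 0) return(NA_real_)
    sum(win * v) / sum(v)
  })
  centers <- centers[!is.na(centers)]
  fit <- lm(centers ~ seq_along(centers))
  expect_lt(max(abs(residuals(fit))), 1)
})

test_that("d_k is minimized at the inducing parameters", {
  par <- distortion_params(30, 10, 15)
  pair <- tissue_tile_pair(par, tile_px = 300, overlap_frac = 0.09)
  a <- gigamosaic:::preprocess_for_dk(pair$tileA)
  b <- gigamosaic:::preprocess_for_dk(pair$tileB)
  dk <- function(A, xo, yo)
    gigamosaic:::cpp_dk(a, b, pair$rois$a[1], pair$rois$a[2],
                        pair$rois$b[1], pair$rois$b[2],
                        pair$rois$w, pair$rois$h,
                        A, xo, yo, 60, 60, FALSE, FALSE, TRUE, 0.25)
  d_true <- dk(30, 10, 15)
  # exhaustive coarse sweep: no candidate beats the truth
  for (A in seq(10, 60, 10)) for (xo in seq(0, 60, 15))
    for (yo in seq(0, 60, 15))
      if (!(A == 30 && xo == 10 && yo == 15))
        expect_gte(dk(A, xo, yo), d_true)
})

test_that("the grid search recovers randomly drawn parameters within one step", {
  set.seed(123)
  for (trial in 1:6) {
    A <- sample(28:45, 1)
    xo <- sample(5:30, 1)
    yo <- sample(5:30, 1)
    par <- distortion_params(A, xo, yo)
    pair <- grid_tile_pair(par, tile_px = 300, overlap_frac = 0.2,
                           spacing = 40, line = 3)
    grid <- search_grid(A_range = c(A - 6, A + 6, 2),
                        off_range = c(max(0, min(xo, yo) - 6),
                                      max(xo, yo) + 6, 2),
                        flips = "none")
    fit <- estimate_params(pair$tileA, pair$tileB, pair$rois, grid,
                           coarse_step = 1, preprocess = FALSE)
    expect_lte(abs(fit$params$A_deg - A), 2)
    expect_lte(abs(fit$params$x_off - xo), 2)
    expect_lte(abs(fit$params$y_off - yo), 2)
  }
})

test_that("undistorted identical tiles score d_k = 0 at the near-identity candidate", {
  g <- make_grid(300, 300, 50, 5)
  rois <- list(a = c(0L, 0L), b = c(0L, 0L), w = 300L, h = 300L)
  grid <- search_grid(A_range = c(0.001, 0.001, 1), off_range = c(0, 0, 1),
                      flips = "none")
  fit <- estimate_params(g, g, rois, grid, coarse_step = 1)
  expect_equal(fit$d_min, 0)
  expect_error(estimate_params(g, g[1:100, ], rois, grid), "shape")
})

test_that("resonant resampling corrects the cosinusoidal pixel spacing", {
  # constant image is invariant
  cst <- matrix(77, 8, 500)
  expect_equal(correct_resonant(cst, 1), cst)
  expect_equal(correct_resonant(cst, 0.9), cst)

  # beta = 1, width 6000: impulse at the sweep center stays put
  imp <- matrix(0, 3, 6000); imp[, 3001] <- 255
  out <- correct_resonant(imp, 1)
  expect_true(any(out[1, 3000:3002] > 100))

  # impulse at theta = pi/3 (x = 0.25) lands at column 1500 +- 1
  imp2 <- matrix(0, 3, 6000); imp2[, 2001] <- 255
  out2 <- correct_resonant(imp2, 1)
  peak <- which.max(out2[1, ]) - 1
  expect_lte(abs(peak - 1500), 1)

  # row sums approximately conserved on a smooth edge-quiet image at
  # beta = 1 (mass near the sweep turnarounds is compressed, so the claim
  # needs the signal near the edges to stay close to its mean)
  W <- 600
  sm <- round(outer(seq(80, 170, length.out = 20), rep(1, W)) +
              outer(rep(1, 20), 40 * sin(2 * pi * (0:(W - 1)) / W)))
  rs0 <- rowSums(sm); rs1 <- rowSums(correct_resonant(sm, 1))
  expect_true(all(abs(rs1 - rs0) / rs0 < 0.01))

  # simulator inverse is undone by the correction
  ts <- fixture_scene()$tpef[1:50, 1:600]
  rt <- correct_resonant(induce_resonant(ts, 0.9), 0.9)
  expect_lt(mean(abs(rt[, 30:570] - ts[, 30:570])), 2)

  expect_error(correct_resonant(cst, 0), "beta")
  expect_error(correct_resonant(cst, 1.5), "beta")
})
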