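#' Radial FOV-distortion parameters
#'
#' The model is controlled by an angle `A_deg` governing the strength of the
#' radial distortion and two spatial offsets shifting the distortion center
#' away from the image center. A negative offset encodes a flip of the image
#' along that axis before remapping (undone afterwards); the offset magnitude
#' enters the center formulas. The scaling parameters `s_x`, `s_y` are fixed
#' at 60 throughout.
#'
#' @param A_deg distortion angle in degrees, 0 < A < 360.
#' @param x_off,y_off signed spatial offsets in pixels.
#' @param s_x,s_y spatial scaling parameters (default 60).
#' @param mode `"pincushion"` or `"barrel"`.
#' @return A `distortion_params` object.
#' @export
distortion_params <- function(A_deg, x_off = 0, y_off = 0,
                              s_x = 60, s_y = 60, mode = "pincushion") {
  if (!is.numeric(A_deg) || A_deg <= 0 || A_deg >= 360)
    stop("`A_deg` must lie in (0, 360)", call. = FALSE)
  if (s_x <= 0 || s_y <= 0)
    stop("`s_x` and `s_y` must be positive", call. = FALSE)
  mode <- match.arg(mode, c("pincushion", "barrel"))
  structure(list(A_deg = as.numeric(A_deg),
                 x_off = as.numeric(x_off), y_off = as.numeric(y_off),
                 s_x = as.numeric(s_x), s_y = as.numeric(s_y),
                 mode = mode),
            class = "distortion_params")
}

#' @export
print.distortion_params <- function(x, ...) {
  cat(sprintf("distortion: A = %g deg, X_off = %g, Y_off = %g, S = (%g, %g), %s\n",
              x$A_deg, x$x_off, x$y_off, x$s_x, x$s_y, x$mode))
  invisible(x)
}

#' Precompute distortion coordinate maps
#'
#' For an output image of `C` columns and `R` rows, builds the maps
#' `M_x`, `M_y` giving the source coordinate sampled for each output pixel.
#' With center `c1 = 0.5 C (1 + |X_off|/S_x)`, `c2 = 0.5 R (1 + |Y_off|/S_y)`
#' and normalized radius `r_u`, the distorted radius is
#' `r_d = (360/(A pi)) atan(2 r_u tan(A pi/720))` and the centered
#' coordinates are scaled by `f = r_u/r_d` (pincushion) or `r_d/r_u`
#' (barrel), with `f = 1` at the center (removable singularity). The maps
#' use the offset magnitudes; the sign (flip) is handled by [compensate()].
#'
#' When `inverse = TRUE` the returned maps are the exact inverse of the
#' compensation remap (the forward, inducing distortion): the radial gather
#' map `g(r) = r f(r)` is inverted numerically, so that compensating an
#' induced image recovers it up to interpolation error.
#'
#' @param params a [distortion_params()] object.
#' @param C,R output width and height in pixels (>= 2).
#' @param mode mode of the compensation map (defaults to `params$mode`).
#' @param inverse compute the inverse (forward-distortion) maps instead.
#' @return A `pixel_maps` object with matrices `Mx`, `My` (shape R x C) and
#'   the center `c1`, `c2`.
#' @export
compute_pixel_maps <- function(params, C, R, mode = params$mode,
                               inverse = FALSE) {
  stopifnot(inherits(params, "distortion_params"))
  if (!is_count(C) || !is_count(R) || C < 2 || R < 2)
    stop("`C` and `R` must be integers >= 2", call. = FALSE)
  fn <- if (inverse) cpp_pixel_maps_inv else cpp_pixel_maps
  m <- fn(params$A_deg, abs(params$x_off), abs(params$y_off),
          params$s_x, params$s_y, as.integer(C), as.integer(R),
          mode == "pincushion")
  structure(list(Mx = m$Mx, My = m$My, inverse = inverse,
                 c1 = 0.5 * C * (1 + abs(params$x_off) / params$s_x),
                 c2 = 0.5 * R * (1 + abs(params$y_off) / params$s_y),
                 C = as.integer(C), R = as.integer(R), mode = mode),
            class = "pixel_maps")
}

remap_one <- function(img, maps, flip_x, flip_y) {
  img <- as_image_matrix(img)
  if (nrow(img) != maps$R || ncol(img) != maps$C)
    stop("image shape does not match the pixel maps", call. = FALSE)
  out <- cpp_remap(img, maps$Mx, maps$My, flip_x, flip_y)
  clip8(round_half_up(out))
}

#' Apply or induce the radial distortion model
#'
#' `compensate()` remaps an image through the model in its stored mode;
#' applied to a tile distorted by the instrument (or by [induce()]) it
#' removes the distortion up to interpolation error. `induce()` applies the
#' forward distortion — the exact inverse of the compensation remap, a
#' distortion of the opposite character (pincushion vs. barrel) — so that
#' `compensate()` undoes it.
#' Negative offsets flip the image along that axis before remapping and
#' flip back afterwards. Sampling is bilinear with zero fill outside the
#' source; multi-channel arrays are remapped per channel.
#'
#' @param image numeric matrix or `[R, C, channels]` array in \[0, 255\].
#' @param params a [distortion_params()] object.
#' @param maps optional precomputed [compute_pixel_maps()] result (must match
#'   the image shape and the intended mode).
#' @return Remapped image of the same shape, 8-bit range.
#' @export
compensate <- function(image, params, maps = NULL) {
  stopifnot(inherits(params, "distortion_params"))
  apply_model(image, params, maps, mode = params$mode)
}

#' @rdname compensate
#' @export
induce <- function(image, params, maps = NULL) {
  stopifnot(inherits(params, "distortion_params"))
  apply_model(image, params, maps, mode = params$mode, inverse = TRUE)
}

apply_model <- function(image, params, maps, mode, inverse = FALSE) {
  stack <- as_channel_stack(image)
  d <- dim(stack)
  if (is.null(maps))
    maps <- compute_pixel_maps(params, d[2], d[1], mode = mode,
                               inverse = inverse)
  if (maps$mode != mode || !identical(maps$inverse, inverse))
    stop("supplied maps do not match the requested operation", call. = FALSE)
  fx <- params$x_off < 0
  fy <- params$y_off < 0
  out <- stack
  for (k in seq_len(d[3])) out[, , k] <- remap_one(stack[, , k], maps, fx, fy)
  if (is.matrix(image)) out[, , 1] else out
}

#' Search grid for distortion-parameter estimation
#'
#' @param A_range `c(min, max, step)` in degrees.
#' @param off_range `c(min, max, step)` in pixels, applied to both offsets
#'   (magnitudes; signs are explored via `flips`).
#' @param flips subset of `c("none", "flip_x", "flip_y", "flip_xy")`.
#' @return A `search_grid` object.
#' @export
search_grid <- function(A_range = c(5, 60, 1), off_range = c(0, 60, 1),
                        flips = c("none", "flip_x", "flip_y", "flip_xy")) {
  chk <- function(r, nm) {
    if (length(r) != 3 || r[3] <= 0 || r[1] > r[2])
      stop("`", nm, "` must be c(min, max, step) with step > 0 and min <= max",
           call. = FALSE)
  }
  chk(A_range, "A_range"); chk(off_range, "off_range")
  flips <- match.arg(flips, c("none", "flip_x", "flip_y", "flip_xy"),
                     several.ok = TRUE)
  structure(list(A_range = A_range, off_range = off_range, flips = flips),
            class = "search_grid")
}

#' Overlap ROI pair for two adjacent tiles
#'
#' Convenience constructor for the overlap region-of-interest pair consumed
#' by [estimate_params()]: for horizontally adjacent tiles the rightmost
#' `ov_px` columns of tile A face the leftmost `ov_px` columns of tile B
#' (vertically: bottom rows of A face top rows of B).
#'
#' @param C,R tile width and height in pixels.
#' @param ov_px overlap extent in pixels (> 0).
#' @param orientation `"horizontal"` or `"vertical"` adjacency.
#' @return List with 0-based top-left corners `a = c(x, y)`, `b = c(x, y)`
#'   and size `w`, `h`.
#' @export
overlap_rois <- function(C, R, ov_px, orientation = "horizontal") {
  orientation <- match.arg(orientation, c("horizontal", "vertical"))
  if (!is_count(ov_px) || ov_px < 1 || ov_px > min(C, R))
    stop("`ov_px` must be a positive integer within the tile", call. = FALSE)
  if (orientation == "horizontal")
    list(a = c(C - ov_px, 0L), b = c(0L, 0L), w = as.integer(ov_px),
         h = as.integer(R))
  else
    list(a = c(0L, R - ov_px), b = c(0L, 0L), w = as.integer(C),
         h = as.integer(ov_px))
}

# opening with a square structuring element followed by Otsu binarization;
# used on copies of the tiles that feed the d_k score only
preprocess_for_dk <- function(img, open_px = 5) {
  x <- as_image_matrix(img) / 255
  x <- EBImage::opening(x, EBImage::makeBrush(open_px, shape = "box"))
  x <- as.matrix(x)
  th <- EBImage::otsu(x, range = c(0, 1))
  (x > th) * 255
}

#' Estimate distortion parameters from a tile overlap
#'
#' Grid search over `(A, X_off, Y_off, flip)` minimizing the mean absolute
#' difference `d_k` between the remapped tiles over the overlap ROI: for each
#' candidate both tiles are remapped under the compensation model and
#' `d_k = sum(|T1U - T2U|) / Area(R12)` is evaluated over the ROI. To make the
#' score robust to high-frequency noise, each input tile is first opened with
#' a small square structuring element and binarized at the Otsu threshold;
#' the preprocessed copies are used only for scoring.
#'
#' The search is coarse-to-fine: the grid is first scanned at `coarse_step`
#' times the requested step, then the `refine_top` best coarse candidates are
#' refined at the full grid resolution within one coarse step. Ties keep the
#' first candidate in enumeration order (Y_off varying fastest, then X_off,
#' then A, then flips in their given order).
#'
#' @param tileA,tileB single-channel 8-bit images of identical shape
#'   (adjacent tiles carrying the same instrument distortion).
#' @param overlap ROI pair from [overlap_rois()] (or a compatible list).
#' @param grid a [search_grid()].
#' @param mode compensation mode searched, default `"pincushion"`.
#' @param preprocess apply opening + Otsu binarization before scoring.
#' @param open_px structuring-element side for the opening (default 5).
#' @param coarse_step coarse-stage multiplier of the grid steps (default 5);
#'   set to 1 for an exhaustive single-stage search.
#' @param refine_top number of coarse candidates refined (default 5).
#' @return List with `params` (a [distortion_params()], offsets signed by the
#'   winning flip variant) and `d_min`.
#' @export
estimate_params <- function(tileA, tileB, overlap, grid = search_grid(),
                            mode = "pincushion", preprocess = TRUE,
                            open_px = 5, coarse_step = 5, refine_top = 5) {
  stopifnot(inherits(grid, "search_grid"))
  mode <- match.arg(mode, c("pincushion", "barrel"))
  tileA <- as_image_matrix(tileA, "tileA")
  tileB <- as_image_matrix(tileB, "tileB")
  if (!all(dim(tileA) == dim(tileB)))
    stop("tiles must have identical shape", call. = FALSE)
  if (overlap$w < 1 || overlap$h < 1)
    stop("overlap ROI is empty", call. = FALSE)
  if (preprocess) {
    tileA <- preprocess_for_dk(tileA, open_px)
    tileB <- preprocess_for_dk(tileB, open_px)
  }
  seq_rng <- function(r, step) {
    v <- seq(r[1], r[2], by = step)
    if (v[length(v)] < r[2]) v <- c(v, r[2])
    v
  }
  eval_cand <- function(A, xo, yo, fx, fy) {
    cpp_dk(tileA, tileB,
           as.integer(overlap$a[1]), as.integer(overlap$a[2]),
           as.integer(overlap$b[1]), as.integer(overlap$b[2]),
           overlap$w, overlap$h,
           A, xo, yo, 60, 60, fx, fy, mode == "pincushion")
  }
  flip_tab <- list(none = c(FALSE, FALSE), flip_x = c(TRUE, FALSE),
                   flip_y = c(FALSE, TRUE), flip_xy = c(TRUE, TRUE))
  scan <- function(As, Xs, Ys, flips) {
    cand <- expand.grid(yo = Ys, xo = Xs, A = As, flip = flips,
                        stringsAsFactors = FALSE)
    d <- numeric(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      f <- flip_tab[[cand$flip[i]]]
      d[i] <- eval_cand(cand$A[i], cand$xo[i], cand$yo[i], f[1], f[2])
    }
    cand$d <- d
    cand
  }
  cs <- max(1, as.integer(coarse_step))
  coarse <- scan(seq_rng(grid$A_range, grid$A_range[3] * cs),
                 seq_rng(grid$off_range, grid$off_range[3] * cs),
                 seq_rng(grid$off_range, grid$off_range[3] * cs),
                 grid$flips)
  if (cs == 1L) {
    best <- coarse[which.min(coarse$d), ]
  } else {
    top <- coarse[order(coarse$d)[seq_len(min(refine_top, nrow(coarse)))], ]
    best <- NULL
    for (i in seq_len(nrow(top))) {
      win <- function(center, r) {
        v <- seq(max(r[1], center - r[3] * cs), min(r[2], center + r[3] * cs),
                 by = r[3])
        v
      }
      fine <- scan(win(top$A[i], grid$A_range),
                   win(top$xo[i], grid$off_range),
                   win(top$yo[i], grid$off_range),
                   top$flip[i])
      b <- fine[which.min(fine$d), ]
      if (is.null(best) || b$d < best$d) best <- b
    }
  }
  f <- flip_tab[[best$flip]]
  par <- distortion_params(max(best$A, 1e-6),
                           x_off = if (f[1]) -best$xo else best$xo,
                           y_off = if (f[2]) -best$yo else best$yo,
                           mode = mode)
  list(params = par, d_min = best$d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resonant-scanner cosinusoidal resampling
#'
#' A resonant scanning mirror sweeps the fast axis cosinusoidally, so pixels
#' clocked uniformly in time are non-uniform in position. `correct_resonant`
#' treats the input columns as uniform in scan phase over the central `beta`
#' fraction of the half period \[0, pi\] (position `x(theta) = (1 - cos
#' theta)/2`) and resamples each row to columns uniform in position, by
#' linear interpolation; the output has the same width.
#' `induce_resonant` is the inverse resampling (position-uniform to
#' phase-uniform), used by the scan simulator so the pair is self-consistent.
#'
#' @param image numeric matrix or 3D array in \[0, 255\].
#' @param beta usable fraction of the sweep, in (0, 1\]; the default 0.9
#'   excludes the mirror turnarounds.
#' @return Resampled image of the same shape.
#' @export
correct_resonant <- function(image, beta = 0.9) {
  resonant_resample(image, beta, forward = TRUE)
}

#' @rdname correct_resonant
#' @export
induce_resonant <- function(image, beta = 0.9) {
  resonant_resample(image, beta, forward = FALSE)
}

resonant_resample <- function(image, beta, forward) {
  if (!is.numeric(beta) || beta <= 0 || beta > 1)
    stop("`beta` must lie in (0, 1]", call. = FALSE)
  stack <- as_channel_stack(image)
  W <- dim(stack)[2]
  if (W < 2) return(image)
  theta <- pi * (1 - beta) / 2 + beta * pi * (seq_len(W) - 1) / (W - 1)
  xpos <- (1 - cos(theta)) / 2                     # position of input col j
  xr <- range(xpos)
  xout <- seq(xr[1], xr[2], length.out = W)        # uniform positions
  if (forward) {
    # output uniform in position: invert theta at each target position
    th <- acos(pmin(pmax(1 - 2 * xout, -1), 1))
    src <- (th - theta[1]) / (beta * pi) * (W - 1) # fractional input column
  } else {
    # output uniform in phase: sample the position-uniform input at x(theta)
    src <- (xpos - xr[1]) / (xr[2] - xr[1]) * (W - 1)
  }
  src <- pmin(pmax(src, 0), W - 1)
  j0 <- floor(src); j1 <- pmin(j0 + 1, W - 1); wgt <- src - j0
  out <- stack
  for (k in seq_len(dim(stack)[3])) {
    ch <- stack[, , k]
    res <- ch[, j0 + 1, drop = FALSE] * rep(1 - wgt, each = nrow(ch)) +
           ch[, j1 + 1, drop = FALSE] * rep(wgt, each = nrow(ch))
    out[, , k] <- clip8(round_half_up(res))
  }
  if (is.matrix(image)) out[, , 1] else out
}
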