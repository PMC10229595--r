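# Synthetic fixtures: calibration grids, two-channel tissue-like scenes
# with ground truth, and a scan simulator producing distorted, jittered,
# noisy tiles plus the truth placements the stitcher must recover.

#' Synthetic grid calibration target
#'
#' White lines (255) on black (0), both axes, centered at integer multiples
#' of `spacing_px`.
#'
#' @param width_px,height_px image dimensions.
#' @param spacing_px line spacing (> `line_px`).
#' @param line_px line width in pixels (>= 1).
#' @return 8-bit matrix.
#' @export
make_grid <- function(width_px, height_px, spacing_px, line_px = 3) {
  if (!is_count(spacing_px) || !is_count(line_px) || line_px < 1 ||
      spacing_px <= line_px)
    stop("need integer `spacing_px` > `line_px` >= 1", call. = FALSE)
  on_axis <- function(n) (((0:(n - 1)) + line_px %/% 2) %% spacing_px) < line_px
  img <- matrix(0, height_px, width_px)
  img[, on_axis(width_px)] <- 255
  img[on_axis(height_px), ] <- 255
  img
}

#' Synthetic tissue-scene parameters
#'
#' Defaults describe an H&E-stained soft-tissue field at micron-scale
#' sampling: channel 1 (THG-like, hematoxylin) carries nuclei as filled
#' anti-aliased ellipses; channel 2 (TPEF-like, eosin) carries vessel/stroma
#' ribbons plus band-limited texture. Densities are physical (per mm^2) so
#' scenes scale with `pixel_pitch_nm`.
#'
#' @param width_px,height_px scene dimensions.
#' @param pixel_pitch_nm pixel size (default 1000 nm for compact test
#'   scenes).
#' @param nuclei_density nuclei per mm^2 (default 1500).
#' @param nuclei_radius_px semi-major axis range in pixels.
#' @param nuclei_ecc eccentricity range in \[0, 1).
#' @param nuclei_intensity intensity range, channel 1.
#' @param vessel_count number of vessel ribbons.
#' @param vessel_width_px ribbon full-width range in pixels.
#' @param vessel_intensity peak ribbon intensity, channel 2.
#' @param haze per-channel constant background level `c(ch1, ch2)`.
#' @param texture_amp amplitude of the band-limited channel-2 texture.
#' @param seed integer RNG seed.
#' @return A `scene_params` object.
#' @export
scene_params <- function(width_px = 1200, height_px = 900,
                         pixel_pitch_nm = 1000,
                         nuclei_density = 1500,
                         nuclei_radius_px = c(4, 9),
                         nuclei_ecc = c(0, 0.6),
                         nuclei_intensity = c(120, 220),
                         vessel_count = 8,
                         vessel_width_px = c(8, 24),
                         vessel_intensity = 170,
                         haze = c(20, 28),
                         texture_amp = 25,
                         seed = 1L) {
  stopifnot(width_px >= 16, height_px >= 16, nuclei_density >= 0,
            diff(nuclei_radius_px) >= 0, nuclei_radius_px[1] > 0,
            all(nuclei_ecc >= 0), all(nuclei_ecc < 1),
            all(nuclei_intensity >= 0), all(nuclei_intensity <= 255),
            all(haze >= 0), all(haze <= 255))
  structure(as.list(environment()), class = "scene_params")
}

#' Generate a two-channel synthetic tissue scene
#'
#' Channel 1: anti-aliased filled ellipses ("nuclei") at seeded uniform
#' random positions over a constant haze plus low-amplitude smooth noise.
#' Channel 2: smooth sinusoidal ribbons ("vessels") and band-limited
#' texture over haze. The realized nuclei count is Poisson with mean
#' `density * area_mm2`. Fully deterministic for a fixed seed.
#'
#' @param params a [scene_params()].
#' @return List with `thg` and `tpef` (8-bit matrices) and `nuclei`
#'   (data.frame of centers, axes, angle, intensity).
#' @export
make_tissue_scene <- function(params = scene_params()) {
  stopifnot(inherits(params, "scene_params"))
  p <- params
  set.seed(p$seed)
  H <- p$height_px; W <- p$width_px
  area_mm2 <- (W * p$pixel_pitch_nm / 1e6) * (H * p$pixel_pitch_nm / 1e6)

  smooth_noise <- function(amp, sigma) {
    n <- matrix(rnorm(H * W), H, W)
    n <- as.matrix(EBImage::gblur(n, sigma = sigma))
    amp * n / max(abs(range(n)), 1e-9)
  }

  ## channel 1: nuclei
  ch1 <- matrix(p$haze[1], H, W) + smooth_noise(6, 6)
  n_nuc <- rpois(1, p$nuclei_density * area_mm2)
  nuclei <- data.frame(x = numeric(0), y = numeric(0), a = numeric(0),
                       b = numeric(0), angle = numeric(0),
                       intensity = numeric(0))
  if (n_nuc > 0) {
    nuclei <- data.frame(
      x = runif(n_nuc, 0, W - 1), y = runif(n_nuc, 0, H - 1),
      a = runif(n_nuc, p$nuclei_radius_px[1], p$nuclei_radius_px[2]),
      angle = runif(n_nuc, 0, pi),
      intensity = runif(n_nuc, p$nuclei_intensity[1], p$nuclei_intensity[2]))
    ecc <- runif(n_nuc, p$nuclei_ecc[1], p$nuclei_ecc[2])
    nuclei$b <- nuclei$a * sqrt(1 - ecc^2)
    nuclei <- nuclei[, c("x", "y", "a", "b", "angle", "intensity")]
    for (i in seq_len(n_nuc)) {
      nc <- nuclei[i, ]
      r <- ceiling(nc$a) + 2
      xs <- max(0, floor(nc$x - r)):min(W - 1, ceiling(nc$x + r))
      ys <- max(0, floor(nc$y - r)):min(H - 1, ceiling(nc$y + r))
      if (length(xs) == 0 || length(ys) == 0) next
      dx <- outer(rep(1, length(ys)), xs - nc$x)
      dy <- outer(ys - nc$y, rep(1, length(xs)))
      u <- (dx * cos(nc$angle) + dy * sin(nc$angle)) / nc$a
      v <- (-dx * sin(nc$angle) + dy * cos(nc$angle)) / nc$b
      # soft 1-px anti-aliased edge on the implicit ellipse
      alpha <- pmin(1, pmax(0, (1 - sqrt(u^2 + v^2)) * nc$a + 0.5))
      patch <- ch1[ys + 1, xs + 1, drop = FALSE]
      ch1[ys + 1, xs + 1] <- pmax(patch,
                                  p$haze[1] + alpha * (nc$intensity - p$haze[1]))
    }
  }

  ## channel 2: vessels + texture
  ch2 <- matrix(p$haze[2], H, W) + smooth_noise(p$texture_amp, 3)
  for (i in seq_len(p$vessel_count)) {
    horiz <- runif(1) < 0.5
    span <- if (horiz) W else H
    depth <- if (horiz) H else W
    base <- runif(1, 0.1, 0.9) * depth
    amp <- runif(1, 0.02, 0.12) * depth
    lambda <- runif(1, 0.5, 1.5) * span
    phase <- runif(1, 0, 2 * pi)
    width <- runif(1, p$vessel_width_px[1], p$vessel_width_px[2])
    center <- base + amp * sin(2 * pi * (0:(span - 1)) / lambda + phase)
    sig <- width / 2.355   # full width at half maximum
    prof <- exp(-0.5 * (outer(0:(depth - 1), center, `-`) / sig)^2)
    contrib <- p$vessel_intensity * prof
    if (horiz) ch2 <- pmax(ch2, p$haze[2] + contrib)
    else ch2 <- pmax(ch2, p$haze[2] + t(contrib))
  }

  list(thg = clip8(round_half_up(ch1)), tpef = clip8(round_half_up(ch2)),
       nuclei = nuclei)
}

#' Scan-simulation settings
#'
#' @param tile_px tile side in pixels.
#' @param overlap_frac nominal tile overlap (default 0.09, the acquisition
#'   convention).
#' @param jitter_px maximum absolute uniform stage-repeatability error in
#'   pixels (the truth the stitcher must recover; the stage log reports
#'   the jitter-free nominal positions). Must stay below the overlap.
#' @param distortion optional [distortion_params()] applied to each tile
#'   via [induce()].
#' @param resonant_beta optional usable-fraction; tiles are resampled with
#'   [induce_resonant()] so [correct_resonant()] undoes it.
#' @param noise_sd Gaussian noise standard deviation in intensity levels
#'   (default 5), clipped to \[0, 255\].
#' @param poisson also apply Poisson (shot) noise.
#' @param pixel_pitch_nm pixel size for the stage log.
#' @param seed integer RNG seed.
#' @return A `scan_config` object.
#' @export
scan_config <- function(tile_px = 400, overlap_frac = 0.09, jitter_px = 0,
                        distortion = NULL, resonant_beta = NULL,
                        noise_sd = 5, poisson = FALSE,
                        pixel_pitch_nm = 1000, seed = 1L) {
  ov_px <- tile_px - round_half_up((1 - overlap_frac) * tile_px)
  if (jitter_px > 0 && jitter_px >= ov_px)
    stop("`jitter_px` must stay below the overlap extent (", ov_px,
         " px); alignment is unidentifiable otherwise", call. = FALSE)
  structure(list(tile_px = as.integer(tile_px), overlap_frac = overlap_frac,
                 jitter_px = as.integer(jitter_px), distortion = distortion,
                 resonant_beta = resonant_beta, noise_sd = noise_sd,
                 poisson = poisson, pixel_pitch_nm = pixel_pitch_nm,
                 seed = as.integer(seed)),
            class = "scan_config")
}

# crop with zero fill outside the scene
crop_scene <- function(img, x0, y0, w, h) {
  out <- matrix(0, h, w)
  xs <- max(0, x0):min(ncol(img) - 1, x0 + w - 1)
  ys <- max(0, y0):min(nrow(img) - 1, y0 + h - 1)
  if (length(xs) > 0 && length(ys) > 0)
    out[ys - y0 + 1, xs - x0 + 1] <- img[ys + 1, xs + 1]
  out
}

#' Simulate a tiled scan of a scene
#'
#' Tiles the scene on a regular grid with the configured overlap. Each tile
#' is cropped at its nominal grid position plus an unknown per-tile uniform
#' integer jitter in `[-jitter_px, jitter_px]^2` (stage repeatability
#' error), then optionally distorted ([induce()]), resampled to the
#' resonant-scan geometry ([induce_resonant()]), and corrupted with noise.
#' The stage log reports the jitter-free nominal positions; the returned
#' truth table records the actual crop positions.
#'
#' @param scene output of [make_tissue_scene()], or a named list of 8-bit
#'   channel matrices, or a single matrix.
#' @param config a [scan_config()].
#' @return List with `tiles` (list of [tile()]), `stage_log` (data.frame)
#'   and `truth` (data.frame with nominal and true positions).
#' @export
simulate_scan <- function(scene, config = scan_config()) {
  stopifnot(inherits(config, "scan_config"))
  if (is.matrix(scene)) scene <- list(ch1 = scene)
  chans <- Filter(is.matrix, scene)
  if (length(chans) < 1) stop("scene holds no channel matrices", call. = FALSE)
  H <- nrow(chans[[1]]); W <- ncol(chans[[1]])
  tp <- config$tile_px
  if (W < tp || H < tp) stop("scene smaller than one tile", call. = FALSE)
  stride <- round_half_up((1 - config$overlap_frac) * tp)
  nx <- (W - tp) %/% stride + 1L
  ny <- (H - tp) %/% stride + 1L
  set.seed(config$seed)
  pitch <- config$pixel_pitch_nm
  tiles <- list(); truth <- NULL; stage <- NULL
  for (r in 0:(ny - 1)) for (c in 0:(nx - 1)) {
    nom <- c(c * stride, r * stride)
    jit <- if (config$jitter_px > 0)
      sample(seq(-config$jitter_px, config$jitter_px), 2, replace = TRUE)
    else c(0L, 0L)
    pos <- nom + jit
    id <- sprintf("r%d_c%d", r, c)
    ch <- lapply(chans, crop_scene, x0 = pos[1], y0 = pos[2], w = tp, h = tp)
    if (!is.null(config$distortion))
      ch <- lapply(ch, induce, params = config$distortion)
    if (!is.null(config$resonant_beta))
      ch <- lapply(ch, induce_resonant, beta = config$resonant_beta)
    if (config$poisson)
      ch <- lapply(ch, function(m)
        matrix(clip8(rpois(length(m), lambda = pmax(m, 0.01))), nrow(m)))
    if (config$noise_sd > 0)
      ch <- lapply(ch, function(m)
        clip8(round_half_up(m + rnorm(length(m), 0, config$noise_sd))))
    tiles[[length(tiles) + 1L]] <-
      tile(id, c, r, nom[1] * pitch / 1000, nom[2] * pitch / 1000,
           ch, pitch)
    truth <- rbind(truth, data.frame(
      tile_id = id, grid_col = c, grid_row = r,
      nominal_x_px = nom[1], nominal_y_px = nom[2],
      true_x_px = pos[1], true_y_px = pos[2], stringsAsFactors = FALSE))
    stage <- rbind(stage, data.frame(
      tile_id = id, grid_col = c, grid_row = r,
      stage_x_um = nom[1] * pitch / 1000, stage_y_um = nom[2] * pitch / 1000,
      stringsAsFactors = FALSE))
  }
  list(tiles = tiles, stage_log = stage, truth = truth)
}
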