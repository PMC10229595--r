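#' Virtual-H&E color parameters
#'
#' Target blue/green/red compositions of the hematoxylin and eosin dyes and
#' the contrast parameter `k` of the Beer-Lambert lookup tables. Defaults
#' are the tuned values `(B, G, R) = (180, 0, 90)` for hematoxylin,
#' `(210, 165, 250)` for eosin, and `k = 2.5`.
#'
#' @param h_color,e_color numeric triplets `(B, G, R)` in \[0, 255\].
#' @param k contrast parameter, > 0.
#' @return An `he_color_params` object.
#' @export
he_color_params <- function(h_color = c(180, 0, 90),
                            e_color = c(210, 165, 250), k = 2.5) {
  for (col in list(h_color, e_color))
    if (length(col) != 3 || any(col < 0) || any(col > 255))
      stop("colors must be (B, G, R) triplets in [0, 255]", call. = FALSE)
  if (!is.numeric(k) || k <= 0) stop("`k` must be positive", call. = FALSE)
  structure(list(h_color = as.numeric(h_color),
                 e_color = as.numeric(e_color), k = as.numeric(k)),
            class = "he_color_params")
}

#' Build the H and E color lookup tables
#'
#' Beer-Lambert transmission LUTs: for intensity `i` in 0..255 and color
#' component `c` of the dye, the entry is
#' `round(255 * exp(-(255 - c) * i * k / 255))`. Zero signal maps to 255
#' (white, bright-field background); each column is non-increasing in `i`
#' whenever its color component is below 255.
#'
#' @param params an [he_color_params()].
#' @return A `lut_pair`: list of two 256 x 3 integer matrices `LUT_H`,
#'   `LUT_E` with columns `blue`, `green`, `red` (row `i + 1` holds
#'   intensity `i`).
#' @export
build_luts <- function(params = he_color_params()) {
  stopifnot(inherits(params, "he_color_params"))
  mk <- function(col) {
    i <- 0:255
    m <- sapply(col, function(comp)
      round_half_up(255 * exp(-(255 - comp) * i * params$k / 255)))
    storage.mode(m) <- "integer"
    colnames(m) <- c("blue", "green", "red")
    m
  }
  structure(list(LUT_H = mk(params$h_color), LUT_E = mk(params$e_color)),
            class = "lut_pair")
}

#' Remap two-channel signal to a virtual H&E image
#'
#' The THG channel (nuclei, hematoxylin-like) is passed through `LUT_H` and
#' the TPEF channel (stroma, eosin-like) through `LUT_E`; the two remapped
#' colors are combined multiplicatively per component,
#' `HE = round(H_remap * E_remap / 255)`, which is commutative in the two
#' dyes. Zero signal in both channels renders pure white.
#'
#' @param thg,tpef single-channel 8-bit images of identical shape.
#' @param luts a [build_luts()] result.
#' @return `[rows, cols, 3]` integer array in R, G, B channel order (the
#'   on-disk bitmap order B, G, R is applied by [write_bitmap()]).
#' @export
remap_to_he <- function(thg, tpef, luts = build_luts()) {
  stopifnot(inherits(luts, "lut_pair"))
  thg <- as_image_matrix(thg, "thg")
  tpef <- as_image_matrix(tpef, "tpef")
  if (!all(dim(thg) == dim(tpef)))
    stop("`thg` and `tpef` must have identical shape", call. = FALSE)
  it <- as.integer(round_half_up(thg)) + 1L
  ie <- as.integer(round_half_up(tpef)) + 1L
  out <- array(0L, c(dim(thg), 3L))
  # LUT columns are blue, green, red; output planes are R, G, B
  for (p in 1:3) {
    lc <- c(3L, 2L, 1L)[p]
    v <- round_half_up(luts$LUT_H[it, lc] * luts$LUT_E[ie, lc] / 255)
    out[, , p] <- matrix(as.integer(v), nrow(thg), ncol(thg))
  }
  out
}

#' Contrast-enhancement parameters
#'
#' @param alpha_max gain cap (>= 1); the recommended values are 8.0 for the
#'   THG channel and 5.0 for TPEF.
#' @param bg_radius_px radius of the disk structuring element used for
#'   background estimation (default 31).
#' @param gamma exponent for optional gamma correction (1 = off).
#' @param bilateral `c(spatial sigma, range sigma)` for optional bilateral
#'   filtering, or `NULL` (off).
#' @return An `enhance_params` object.
#' @export
enhance_params <- function(alpha_max = 8, bg_radius_px = 31, gamma = 1,
                           bilateral = NULL) {
  if (alpha_max < 1) stop("`alpha_max` must be >= 1", call. = FALSE)
  if (bg_radius_px < 1) stop("`bg_radius_px` must be >= 1", call. = FALSE)
  if (gamma <= 0) stop("`gamma` must be positive", call. = FALSE)
  structure(list(alpha_max = alpha_max, bg_radius_px = as.integer(bg_radius_px),
                 gamma = gamma, bilateral = bilateral),
            class = "enhance_params")
}

#' Denoised contrast enhancement (background suppression + capped gain)
#'
#' Estimates the background by grayscale morphological opening with a disk
#' of radius `bg_radius_px`, subtracts it, and rescales the foreground with
#' gain `min(alpha_max, 255 / p99)` where `p99` is the 99th percentile of
#' the positive foreground values. A pure-background (constant) input maps
#' to all zeros. This is a compact single-parameter
#' background-suppress-then-gain enhancer exposing the conventional
#' `alpha_max` control.
#'
#' @param image single-channel 8-bit image.
#' @param params an [enhance_params()] (only `alpha_max` and `bg_radius_px`
#'   are used here; apply [gamma_correct()] / [bilateral_filter()]
#'   separately if desired).
#' @return Enhanced 8-bit image.
#' @export
dce <- function(image, params = enhance_params()) {
  stopifnot(inherits(params, "enhance_params"))
  img <- as_image_matrix(image)
  brush_size <- 2L * params$bg_radius_px + 1L
  bg <- EBImage::opening(img / 255,
                         EBImage::makeBrush(brush_size, shape = "disc")) * 255
  fg <- pmax(img - as.matrix(bg), 0)
  pos <- fg[fg > 0]
  if (length(pos) == 0) return(matrix(0, nrow(img), ncol(img)))
  g <- min(params$alpha_max, 255 / quantile(pos, 0.99, names = FALSE))
  clip8(round_half_up(g * fg))
}

#' Gamma correction
#'
#' Standard power-law mapping via a 256-entry LUT:
#' `round(255 * (i / 255)^gamma)`; identity at `gamma = 1`.
#'
#' @param image single-channel 8-bit image.
#' @param gamma exponent, > 0.
#' @return Corrected image.
#' @export
gamma_correct <- function(image, gamma) {
  if (!is.numeric(gamma) || gamma <= 0)
    stop("`gamma` must be positive", call. = FALSE)
  img <- as_image_matrix(image)
  lut <- round_half_up(255 * ((0:255) / 255)^gamma)
  matrix(lut[as.integer(round_half_up(img)) + 1L], nrow(img), ncol(img))
}

#' Edge-preserving bilateral filter
#'
#' Gaussian-weighted smoothing in both space (`sigma_s`, pixels) and
#' intensity (`sigma_r`, 8-bit levels); identity on constant images.
#'
#' @param image single-channel 8-bit image.
#' @param sigma_s,sigma_r spatial and range standard deviations (> 0).
#' @return Filtered 8-bit image.
#' @export
bilateral_filter <- function(image, sigma_s = 2, sigma_r = 25) {
  if (sigma_s <= 0 || sigma_r <= 0)
    stop("sigmas must be positive", call. = FALSE)
  img <- as_image_matrix(image)
  clip8(round_half_up(cpp_bilateral(img, sigma_s, sigma_r)))
}
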