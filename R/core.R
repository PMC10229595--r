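#' Acquired image tile
#'
#' Bundles one acquired frame with its grid index, stage position and pixel
#' pitch. `channels` holds one to three single-channel 8-bit images of
#' identical shape (e.g. THG and TPEF), as a list of matrices or a
#' `[rows, cols, channels]` array.
#'
#' @param tile_id character scalar, unique within a scan.
#' @param grid_col,grid_row 0-based tile indices in the scan grid.
#' @param stage_x_um,stage_y_um stage position in micrometres.
#' @param channels list of numeric matrices (or a 3D array) with values in
#'   \[0, 255\], all of identical shape; 1 to 3 channels.
#' @param pixel_pitch_nm physical pixel size in nanometres.
#' @return An object of class `tile`.
#' @export
tile <- function(tile_id, grid_col, grid_row, stage_x_um, stage_y_um,
                 channels, pixel_pitch_nm) {
  if (is.array(channels) && length(dim(channels)) == 3L)
    channels <- lapply(seq_len(dim(channels)[3]), function(k) channels[, , k])
  if (is.matrix(channels)) channels <- list(channels)
  if (!is.list(channels) || length(channels) < 1L || length(channels) > 3L)
    stop("`channels` must hold 1 to 3 single-channel images", call. = FALSE)
  channels <- unname(lapply(channels, as_image_matrix, arg = "channels"))
  dims <- vapply(channels, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all channel images must share the same shape", call. = FALSE)
  rng <- range(unlist(lapply(channels, range)))
  if (rng[1] < 0 || rng[2] > 255)
    stop("pixel values must lie in [0, 255]", call. = FALSE)
  structure(list(tile_id = as.character(tile_id),
                 grid_col = as.integer(grid_col),
                 grid_row = as.integer(grid_row),
                 stage_x_um = as.numeric(stage_x_um),
                 stage_y_um = as.numeric(stage_y_um),
                 channels = channels,
                 pixel_pitch_nm = as.numeric(pixel_pitch_nm)),
            class = "tile")
}

#' @export
print.tile <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("tile %s  grid (%d, %d)  %d x %d px  %d channel(s)  pitch %g nm\n",
              x$tile_id, x$grid_col, x$grid_row, d[2], d[1],
              length(x$channels), x$pixel_pitch_nm))
  invisible(x)
}

# mean of channels, the single scoring image used by the alignment search
tile_score_image <- function(tl) {
  Reduce(`+`, tl$channels) / length(tl$channels)
}

#' Plan a tile mosaic
#'
#' Computes the pixel geometry of a regular tile grid with fractional
#' overlap between adjacent fields of view. The stride between tile origins
#' is `round((1 - overlap_frac) * tile_px)` (half-up), so the mosaic spans
#' `tile_px + (n - 1) * stride` pixels per axis.
#'
#' @param tiles_x,tiles_y number of tiles per axis (>= 1).
#' @param tile_px tile side length in pixels (>= 2); tiles are square.
#' @param overlap_frac fraction of the tile width/height shared by adjacent
#'   tiles, in \[0, 1); the acquisition convention is about 0.09.
#' @param pixel_pitch_nm physical pixel size in nanometres.
#' @return A `mosaic_plan` with fields `tiles_x`, `tiles_y`, `tile_px`,
#'   `overlap_frac`, `stride_px`, `mosaic_w_px`, `mosaic_h_px`,
#'   `total_px`, `extent_x_mm`, `extent_y_mm`, `pixel_pitch_nm`.
#' @examples
#' plan_mosaic(8, 4, 6000, 0.09, 183)  # ~1 Gpx over ~8.1 x 4.1 mm
#' @export
plan_mosaic <- function(tiles_x, tiles_y, tile_px, overlap_frac = 0.09,
                        pixel_pitch_nm = 167) {
  if (!is_count(tiles_x) || !is_count(tiles_y) || tiles_x < 1 || tiles_y < 1)
    stop("tile counts must be positive integers", call. = FALSE)
  if (!is_count(tile_px) || tile_px < 2)
    stop("`tile_px` must be an integer >= 2", call. = FALSE)
  if (!is.numeric(overlap_frac) || overlap_frac < 0 || overlap_frac >= 1)
    stop("`overlap_frac` must lie in [0, 1)", call. = FALSE)
  if (!is.numeric(pixel_pitch_nm) || pixel_pitch_nm <= 0)
    stop("`pixel_pitch_nm` must be positive", call. = FALSE)
  stride <- round_half_up((1 - overlap_frac) * tile_px)
  w <- tile_px + (tiles_x - 1L) * stride
  h <- tile_px + (tiles_y - 1L) * stride
  structure(list(tiles_x = as.integer(tiles_x), tiles_y = as.integer(tiles_y),
                 tile_px = as.integer(tile_px),
                 overlap_frac = overlap_frac,
                 stride_px = as.integer(stride),
                 mosaic_w_px = as.integer(w), mosaic_h_px = as.integer(h),
                 total_px = w * h,
                 extent_x_mm = w * pixel_pitch_nm / 1e6,
                 extent_y_mm = h * pixel_pitch_nm / 1e6,
                 pixel_pitch_nm = pixel_pitch_nm),
            class = "mosaic_plan")
}

#' @export
print.mosaic_plan <- function(x, ...) {
  cat(sprintf("mosaic plan: %d x %d tiles of %d px, overlap %.1f%% (stride %d px)\n",
              x$tiles_x, x$tiles_y, x$tile_px, 100 * x$overlap_frac,
              x$stride_px))
  cat(sprintf("  %d x %d px = %s px, extent %.2g x %.2g mm\n",
              x$mosaic_w_px, x$mosaic_h_px,
              format(x$total_px, big.mark = ","),
              x$extent_x_mm, x$extent_y_mm))
  invisible(x)
}

#' Pixel count of a physical area
#'
#' Number of pixels needed to cover `width_mm` x `height_mm` at a given
#' pixel pitch: `floor(width_mm * 1e6 / pitch) * floor(height_mm * 1e6 / pitch)`.
#' At 6000 px per mm (pitch 1000/6 nm), 1 cm^2 comes to 3.6 gigapixels.
#'
#' @param width_mm,height_mm physical extent in millimetres (> 0).
#' @param pixel_pitch_nm pixel size in nanometres (> 0).
#' @return Pixel count (numeric, may exceed .Machine$integer.max).
#' @export
area_pixel_count <- function(width_mm, height_mm, pixel_pitch_nm) {
  if (!is.numeric(width_mm) || !is.numeric(height_mm) ||
      !is.numeric(pixel_pitch_nm) ||
      width_mm <= 0 || height_mm <= 0 || pixel_pitch_nm <= 0)
    stop("all arguments must be positive numbers", call. = FALSE)
  floor(width_mm * 1e6 / pixel_pitch_nm) * floor(height_mm * 1e6 / pixel_pitch_nm)
}

#' Uncompressed data volume of an image
#'
#' @param pixel_count number of pixels (>= 0; vectorized).
#' @param bit_depth bits per pixel: 8 (single channel) or 24 (three channels).
#' @return Data volume in bits.
#' @export
data_volume <- function(pixel_count, bit_depth = 24) {
  if (!is.numeric(pixel_count) || any(pixel_count < 0))
    stop("`pixel_count` must be >= 0", call. = FALSE)
  if (!bit_depth %in% c(8, 24))
    stop("`bit_depth` must be 8 or 24", call. = FALSE)
  pixel_count * bit_depth
}

#' Confusion matrix of binary diagnostic calls
#'
#' @param TP,FP,TN,FN non-negative integer counts; at least one must be > 0.
#' @return A `confusion_matrix` object.
#' @export
confusion_matrix <- function(TP, FP, TN, FN) {
  counts <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(!vapply(counts, is_count, logical(1))) || any(counts < 0))
    stop("counts must be non-negative integers", call. = FALSE)
  if (sum(counts) < 1)
    stop("confusion matrix must contain at least one case", call. = FALSE)
  storage.mode(counts) <- "integer"
  structure(as.list(counts), class = "confusion_matrix")
}

#' Read or write a stage log
#'
#' The stage log is a UTF-8 TSV with header
#' `tile_id grid_col grid_row stage_x_um stage_y_um`, one row per tile,
#' '.' decimal separator.
#'
#' @param path file path.
#' @return `read_stage_log` returns a data.frame with the five columns.
#' @export
read_stage_log <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = c(tile_id = "character"))
  need <- c("tile_id", "grid_col", "grid_row", "stage_x_um", "stage_y_um")
  if (!all(need %in% names(df)))
    stop("stage log must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df[need]
}

#' @rdname read_stage_log
#' @param log data.frame with the stage-log columns.
#' @export
write_stage_log <- function(log, path) {
  write.table(log, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
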