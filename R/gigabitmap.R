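# Custom uncompressed bitmap container (.rfpb) for gigapixel mosaics:
# a fixed 4096-byte little-endian header, a 10x block-mean downscaled
# preview, then the full payload, both stored row-major with the three
# 8-bit values of each pixel interleaved in B, G, R order.
#
# Header layout (offsets in bytes):
#   0  magic "RFPB" (4 bytes)      4  version  int32
#   8  width_px int32             12  height_px int32
#  16  channels int32             20  bit_depth_per_channel int32
#  24  tiles_x int32              28  tiles_y int32
#  32  pixel_pitch_nm double
#  40  preview_w int32            44  preview_h int32
#  48  preview_offset int32       52  payload_offset int32
#  56.. zero padding to 4096

RFPB_MAGIC <- charToRaw("RFPB")
RFPB_HEADER_BYTES <- 4096L
RFPB_PREVIEW_FACTOR <- 10L

#' Write a large-image bitmap (.rfpb)
#'
#' Stores an uncompressed RGB image with a fixed-size header, a 10x
#' block-mean downscaled preview (ceiling dimensions, partial edge blocks
#' averaged over the pixels they contain), and the row-major payload with
#' each pixel's three 8-bit values interleaved in B, G, R order.
#' Single-channel input is promoted to RGB by replication.
#'
#' @param image `[rows, cols, 3]` array in R, G, B plane order (as returned
#'   by [remap_to_he()]), or a single-channel matrix; values in \[0, 255\].
#' @param path output file path (conventional extension `.rfpb`).
#' @param tiles_x,tiles_y tile-grid provenance recorded in the header.
#' @param pixel_pitch_nm pixel size recorded in the header.
#' @return Invisibly, the total number of bytes written:
#'   `4096 + 3 * preview_w * preview_h + 3 * width * height`.
#' @export
write_bitmap <- function(image, path, tiles_x = 1, tiles_y = 1,
                         pixel_pitch_nm = 167) {
  if (is.matrix(image)) image <- array(rep(image, 3), c(dim(image), 3L))
  stopifnot(is.array(image), length(dim(image)) == 3L, dim(image)[3] == 3L)
  H <- dim(image)[1]; W <- dim(image)[2]
  pw <- as.integer(ceiling(W / RFPB_PREVIEW_FACTOR))
  ph <- as.integer(ceiling(H / RFPB_PREVIEW_FACTOR))
  preview_offset <- RFPB_HEADER_BYTES
  payload_offset <- RFPB_HEADER_BYTES + 3L * pw * ph

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(RFPB_MAGIC, con)
  writeBin(as.integer(c(1L, W, H, 3L, 8L, tiles_x, tiles_y)), con,
           size = 4, endian = "little")
  writeBin(as.numeric(pixel_pitch_nm), con, size = 8, endian = "little")
  writeBin(as.integer(c(pw, ph, preview_offset, payload_offset)), con,
           size = 4, endian = "little")
  writeBin(raw(RFPB_HEADER_BYTES - 56L), con)

  prev <- array(0, c(ph, pw, 3L))
  for (k in 1:3) {
    ch <- matrix(image[, , k], H, W)
    prev[, , k] <- clip8(round_half_up(block_mean(ch, RFPB_PREVIEW_FACTOR)))
  }
  writeBin(interleave_bgr(prev), con)
  writeBin(interleave_bgr(image), con)
  invisible(payload_offset + 3 * as.numeric(W) * H)
}

# [H, W, 3] RGB array -> raw vector, pixel-interleaved B, G, R, row-major
interleave_bgr <- function(img) {
  as.raw(as.integer(aperm(img[, , c(3L, 2L, 1L), drop = FALSE],
                          c(3L, 2L, 1L))))
}

deinterleave_bgr <- function(bytes, w, h) {
  v <- array(as.integer(bytes), c(3L, w, h))
  aperm(v, c(3L, 2L, 1L))[, , c(3L, 2L, 1L), drop = FALSE]
}

#' Read the header of a .rfpb bitmap
#'
#' Parses the fixed-size header without touching the preview or payload.
#'
#' @param path file path.
#' @return A `bitmap_header` list: `version`, `width_px`, `height_px`,
#'   `channels`, `bit_depth_per_channel`, `tiles_x`, `tiles_y`,
#'   `pixel_pitch_nm`, `preview_w`, `preview_h`, `preview_offset`,
#'   `payload_offset`.
#' @export
read_header <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (!identical(readBin(con, "raw", 4), RFPB_MAGIC))
    stop("not a .rfpb bitmap (bad magic)", call. = FALSE)
  ints <- readBin(con, "integer", 7, size = 4, endian = "little")
  if (ints[1] != 1L)
    stop("unsupported .rfpb version: ", ints[1], call. = FALSE)
  pitch <- readBin(con, "numeric", 1, size = 8, endian = "little")
  tail <- readBin(con, "integer", 4, size = 4, endian = "little")
  structure(list(version = ints[1], width_px = ints[2], height_px = ints[3],
                 channels = ints[4], bit_depth_per_channel = ints[5],
                 tiles_x = ints[6], tiles_y = ints[7],
                 pixel_pitch_nm = pitch,
                 preview_w = tail[1], preview_h = tail[2],
                 preview_offset = tail[3], payload_offset = tail[4]),
            class = "bitmap_header")
}

#' Read the embedded low-resolution preview
#'
#' @param path file path.
#' @return `[preview_h, preview_w, 3]` integer array, R, G, B plane order.
#' @export
read_preview <- function(path) {
  hd <- read_header(path)
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, hd$preview_offset)
  bytes <- readBin(con, "raw", 3 * hd$preview_w * hd$preview_h)
  deinterleave_bgr(bytes, hd$preview_w, hd$preview_h)
}

#' Read a region of interest from a .rfpb bitmap
#'
#' Returns exactly the requested pixels using row-wise seeks; the full
#' payload is never loaded.
#'
#' @param path file path.
#' @param rect `c(x0, y0, x1, y1)`, half-open 0-based pixel rectangle.
#' @return `[y1 - y0, x1 - x0, 3]` integer array, R, G, B plane order.
#' @export
read_roi <- function(path, rect) {
  hd <- read_header(path)
  if (length(rect) != 4 || rect[1] < 0 || rect[2] < 0 ||
      rect[3] <= rect[1] || rect[4] <= rect[2] ||
      rect[3] > hd$width_px || rect[4] > hd$height_px)
    stop("`rect` must be a non-empty half-open rectangle inside the image",
         call. = FALSE)
  w <- rect[3] - rect[1]; h <- rect[4] - rect[2]
  con <- file(path, "rb")
  on.exit(close(con))
  bytes <- raw(3 * w * h)
  for (j in seq_len(h)) {
    y <- rect[2] + j - 1
    seek(con, hd$payload_offset + 3 * (as.numeric(y) * hd$width_px + rect[1]))
    bytes[(3 * w * (j - 1) + 1):(3 * w * j)] <- readBin(con, "raw", 3 * w)
  }
  deinterleave_bgr(bytes, w, h)
}

#' Export to a standard image format
#'
#' Lossless export to PNG (images up to 100 megapixels) or TIFF. Input can
#' be an in-memory image or the path of a `.rfpb` bitmap.
#'
#' @param image `[H, W, 3]` array (R, G, B), a matrix, or a `.rfpb` path.
#' @param out output file path.
#' @param format `"png"` or `"tiff"`.
#' @return Invisibly, `out`.
#' @export
export_standard <- function(image, out, format = c("png", "tiff")) {
  format <- match.arg(format)
  from_path <- is.character(image) && length(image) == 1L
  npx <- if (from_path) {
    hd <- read_header(image)
    as.numeric(hd$width_px) * hd$height_px
  } else prod(dim(image)[1:2])
  if (format == "png" && npx > 1e8)
    stop("image exceeds the 100 MP PNG cap; export as TIFF instead",
         call. = FALSE)
  if (from_path) {
    hd <- read_header(image)
    image <- read_roi(image, c(0, 0, hd$width_px, hd$height_px))
  }
  if (is.matrix(image)) image <- array(rep(image, 3), c(dim(image), 3L))
  if (format == "png") {
    png::writePNG(image / 255, out)
  } else {
    tiff::writeTIFF(image / 255, out, bits.per.sample = 8L,
                    compression = "none")
  }
  invisible(out)
}

#' Predicted byte size of a .rfpb bitmap
#'
#' `4096 + 3 * ceil(W/10) * ceil(H/10) + 3 * W * H` bytes; a 1-gigapixel
#' mosaic comes to about 2.8 GiB.
#'
#' @param width_px,height_px image dimensions in pixels.
#' @return Size in bytes (numeric).
#' @export
bitmap_size_bytes <- function(width_px, height_px) {
  RFPB_HEADER_BYTES +
    3 * ceiling(width_px / RFPB_PREVIEW_FACTOR) *
        ceiling(height_px / RFPB_PREVIEW_FACTOR) +
    3 * as.numeric(width_px) * height_px
}
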