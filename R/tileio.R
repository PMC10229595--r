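#' Write and read per-channel tile images
#'
#' Tiles are stored as one 8-bit grayscale TIFF per channel per tile,
#' named `{tile_id}_c{channel}.tif`, alongside a stage log
#' (`stage_log.tsv`, see [read_stage_log()]).
#'
#' @param tiles list of [tile()] objects.
#' @param dir output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
write_tile_images <- function(tiles, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stage <- NULL
  for (tl in tiles) {
    for (k in seq_along(tl$channels))
      tiff::writeTIFF(tl$channels[[k]] / 255,
                      file.path(dir, sprintf("%s_c%d.tif", tl$tile_id, k)),
                      bits.per.sample = 8L, compression = "none")
    stage <- rbind(stage, data.frame(
      tile_id = tl$tile_id, grid_col = tl$grid_col, grid_row = tl$grid_row,
      stage_x_um = tl$stage_x_um, stage_y_um = tl$stage_y_um,
      stringsAsFactors = FALSE))
  }
  write_stage_log(stage, file.path(dir, "stage_log.tsv"))
  invisible(dir)
}

#' @rdname write_tile_images
#' @param stage_log path to the stage log TSV; defaults to
#'   `stage_log.tsv` inside `dir`.
#' @param pixel_pitch_nm pixel size assigned to the tiles.
#' @return `read_tile_images` returns a list of [tile()] objects.
#' @export
read_tile_images <- function(dir, stage_log = file.path(dir, "stage_log.tsv"),
                             pixel_pitch_nm = 167) {
  log <- read_stage_log(stage_log)
  lapply(seq_len(nrow(log)), function(i) {
    row <- log[i, ]
    paths <- Sys.glob(file.path(dir, paste0(row$tile_id, "_c*.tif")))
    if (length(paths) == 0)
      stop("no channel images found for tile '", row$tile_id, "'",
           call. = FALSE)
    paths <- paths[order(paths)]
    ch <- lapply(paths, function(p) {
      m <- tiff::readTIFF(p)
      if (length(dim(m)) == 3L) m <- m[, , 1]
      round_half_up(m * 255)
    })
    tile(row$tile_id, row$grid_col, row$grid_row,
         row$stage_x_um, row$stage_y_um, ch, pixel_pitch_nm)
  })
}
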