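#' Alignment search settings
#'
#' The tile aligner scans candidate placements around the stage-estimated
#' offset: a coarse pass at `coarse_step_px` over the window
#' `[-range_x_px, range_x_px] x [-range_y_px, range_y_px]`, followed — when
#' the spread of overlap scores `sigma_max - sigma_min` reaches
#' `sigma_spread_threshold` — by a fine pass at `fine_step_px` within one
#' coarse step of the coarse minimum. Scores are computed on overlap ROIs
#' downsampled by `downscale_factor` (block mean).
#'
#' @param range_x_px,range_y_px search half-widths in pixels (default 30;
#'   must exceed the stage repeatability error).
#' @param coarse_step_px coarse stepping (default 10).
#' @param fine_step_px fine stepping (default 2, <= coarse).
#' @param sigma_spread_threshold gate for fine-tuning, in 8-bit intensity
#'   units (default 1.5).
#' @param downscale_factor integer downsampling of the overlap ROIs
#'   (default 2).
#' @return An `alignment_search` object.
#' @export
alignment_search <- function(range_x_px = 30, range_y_px = 30,
                             coarse_step_px = 10, fine_step_px = 2,
                             sigma_spread_threshold = 1.5,
                             downscale_factor = 2) {
  if (fine_step_px > coarse_step_px)
    stop("`fine_step_px` must not exceed `coarse_step_px`", call. = FALSE)
  if (any(c(range_x_px, range_y_px, coarse_step_px, fine_step_px,
            downscale_factor) <= 0))
    stop("all search settings must be positive", call. = FALSE)
  structure(list(range_x_px = as.integer(range_x_px),
                 range_y_px = as.integer(range_y_px),
                 coarse_step_px = as.integer(coarse_step_px),
                 fine_step_px = as.integer(fine_step_px),
                 sigma_spread_threshold = sigma_spread_threshold,
                 downscale_factor = as.integer(downscale_factor)),
            class = "alignment_search")
}

# block-mean downsample by integer factor f; partial edge blocks averaged
# over the pixels they contain
block_mean <- function(m, f) {
  if (f == 1L) return(m)
  ri <- ceiling(seq_len(nrow(m)) / f)
  ci <- ceiling(seq_len(ncol(m)) / f)
  s <- t(rowsum(t(rowsum(m, ri, reorder = TRUE)), ci, reorder = TRUE))
  s / outer(tabulate(ri), tabulate(ci))
}

# population (N-normalized) standard deviation
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Stage-informed initial tile offset
#'
#' Converts the stage displacement between a tile and its already-placed
#' neighbor into an expected pixel offset, and estimates the overlap extent
#' `X_OV = tile_width - |dx|` (clamped at 0).
#'
#' @param tl,prev_tile [tile()] objects carrying stage positions and pixel
#'   pitch.
#' @return List with `dx_px`, `dy_px`, `x_ov_px`.
#' @export
initial_offset <- function(tl, prev_tile) {
  for (t in list(tl, prev_tile))
    if (!inherits(t, "tile") || is.na(t$stage_x_um) || is.na(t$stage_y_um))
      stop("both tiles must carry stage positions", call. = FALSE)
  pitch <- tl$pixel_pitch_nm
  dx <- round_half_up((tl$stage_x_um - prev_tile$stage_x_um) * 1000 / pitch)
  dy <- round_half_up((tl$stage_y_um - prev_tile$stage_y_um) * 1000 / pitch)
  w <- ncol(tl$channels[[1]])
  list(dx_px = as.integer(dx), dy_px = as.integer(dy),
       x_ov_px = as.integer(max(0, w - abs(dx))))
}

#' Create an empty mosaic canvas
#'
#' @param plan a [plan_mosaic()] result.
#' @param channels number of channels of the composite.
#' @param margin_px padding on every side so that alignment shifts (and
#'   stage error) stay inside the allocated array.
#' @return A `mosaic_canvas`; placements are recorded in mosaic coordinates
#'   with the first tile's top-left at (0, 0).
#' @export
mosaic_canvas <- function(plan, channels = 1, margin_px = 64) {
  H <- plan$mosaic_h_px + 2L * margin_px
  W <- plan$mosaic_w_px + 2L * margin_px
  structure(list(composite = array(0, c(H, W, channels)),
                 score = matrix(0, H, W),
                 covered = matrix(FALSE, H, W),
                 origin = c(margin_px, margin_px),  # (x, y) of mosaic (0,0)
                 plan = plan,
                 placements = empty_placements()),
            class = "mosaic_canvas")
}

empty_placements <- function() {
  data.frame(tile_id = character(), placed_x_px = integer(),
             placed_y_px = integer(), x_ov = integer(), y_al = integer(),
             sigma_min = numeric(), sigma_max = numeric(),
             refined = logical(), fallback = logical(),
             stringsAsFactors = FALSE)
}

#' @export
print.mosaic_canvas <- function(x, ...) {
  d <- dim(x$composite)
  cat(sprintf("mosaic canvas %d x %d px, %d channel(s), %d tile(s) placed\n",
              d[2], d[1], d[3], nrow(x$placements)))
  invisible(x)
}

# grow the canvas arrays so the half-open mosaic-coordinate rect fits
grow_canvas <- function(canvas, x0, y0, x1, y1) {
  d <- dim(canvas$composite)
  ax0 <- x0 + canvas$origin[1]; ay0 <- y0 + canvas$origin[2]
  ax1 <- x1 + canvas$origin[1]; ay1 <- y1 + canvas$origin[2]
  padl <- max(0, -ax0); padt <- max(0, -ay0)
  padr <- max(0, ax1 - d[2]); padb <- max(0, ay1 - d[1])
  if (padl + padt + padr + padb == 0) return(canvas)
  H <- d[1] + padt + padb; W <- d[2] + padl + padr
  comp <- array(0, c(H, W, d[3]))
  comp[padt + seq_len(d[1]), padl + seq_len(d[2]), ] <- canvas$composite
  score <- matrix(0, H, W)
  score[padt + seq_len(d[1]), padl + seq_len(d[2])] <- canvas$score
  cov <- matrix(FALSE, H, W)
  cov[padt + seq_len(d[1]), padl + seq_len(d[2])] <- canvas$covered
  canvas$composite <- comp; canvas$score <- score; canvas$covered <- cov
  canvas$origin <- canvas$origin + c(padl, padt)
  canvas
}

rect_intersect <- function(a, b) {
  x0 <- max(a[1], b[1]); y0 <- max(a[2], b[2])
  x1 <- min(a[3], b[3]); y1 <- min(a[4], b[4])
  if (x1 <= x0 || y1 <= y0) NULL else c(x0, y0, x1, y1)
}

#' Score a candidate tile placement
#'
#' For each neighbor overlap (right/left and top/bottom adjacency), the ROI
#' is extracted from the candidate tile and from the canvas, both are
#' block-mean downsampled, and the standard deviation (population) of their
#' per-pixel absolute difference is taken; `sigma_k` is the sum over the
#' neighbor overlaps. A candidate that loses the overlap with any listed
#' neighbor (or retains less than one downsampled pixel of it) scores
#' `Inf` and is excluded from the argmin: scores are only comparable when
#' every candidate is penalized over the same set of overlaps.
#'
#' @param offset `c(x, y)` candidate mosaic position of the tile's top-left.
#' @param tile_img single-channel scoring image of the tile.
#' @param canvas a [mosaic_canvas()] with the neighbors already composited.
#' @param neighbors list of neighbor rects `c(x0, y0, x1, y1)` (half-open,
#'   mosaic coordinates).
#' @param downscale block-mean downsampling factor (default 2).
#' @param min_depth minimum overlap depth (narrowest intersection dimension)
#'   a candidate must retain with each neighbor, recycled over neighbors;
#'   the standard deviation of a very thin strip is downward-biased, so
#'   [align_tile()] requires half the overlap depth seen at the stage
#'   estimate.
#' @return `sigma_k` in 8-bit intensity units.
#' @export
score_placement <- function(offset, tile_img, canvas, neighbors,
                            downscale = 2, min_depth = downscale) {
  R <- nrow(tile_img); C <- ncol(tile_img)
  trect <- c(offset[1], offset[2], offset[1] + C, offset[2] + R)
  min_depth <- rep_len(pmax(min_depth, downscale), length(neighbors))
  sigma <- 0; n_ov <- 0L
  for (i in seq_along(neighbors)) {
    nb <- neighbors[[i]]
    inter <- rect_intersect(trect, nb)
    if (is.null(inter) || min(inter[3] - inter[1],
                              inter[4] - inter[2]) < min_depth[i])
      return(Inf)
    rows <- (inter[2] - offset[2] + 1):(inter[4] - offset[2])
    cols <- (inter[1] - offset[1] + 1):(inter[3] - offset[1])
    roi_t <- tile_img[rows, cols, drop = FALSE]
    arow <- (inter[2] + canvas$origin[2] + 1):(inter[4] + canvas$origin[2])
    acol <- (inter[1] + canvas$origin[1] + 1):(inter[3] + canvas$origin[1])
    roi_c <- canvas$score[arow, acol, drop = FALSE]
    d <- abs(block_mean(roi_t, downscale) - block_mean(roi_c, downscale))
    sigma <- sigma + sd_pop(d)
    n_ov <- n_ov + 1L
  }
  if (n_ov == 0L) Inf else sigma
}

# per-neighbor minimum overlap depth enforced during the scan: half the
# depth seen at the stage-estimated offset (never below the downscale)
neighbor_min_depth <- function(est, C, R, neighbors, downscale) {
  vapply(neighbors, function(nb) {
    inter <- rect_intersect(c(est[1], est[2], est[1] + C, est[2] + R), nb)
    if (is.null(inter)) return(as.numeric(downscale))
    max(downscale, floor(min(inter[3] - inter[1], inter[4] - inter[2]) / 2))
  }, numeric(1))
}

# deterministic argmin with ties broken by smallest displacement from the
# initial estimate, then row-major (y, then x)
argmin_candidate <- function(cand, scores, est) {
  disp <- (cand[, 1] - est[1])^2 + (cand[, 2] - est[2])^2
  ord <- order(scores, disp, cand[, 2], cand[, 1])
  ord[1]
}

#' Align one tile against the growing mosaic
#'
#' Runs the coarse scan at `coarse_step_px` over the search window centered
#' on the stage-estimated offset, scoring each candidate with
#' [score_placement()]. If the score spread `sigma_max - sigma_min` reaches
#' the threshold, a fine scan at `fine_step_px` within one coarse step of
#' the coarse minimum refines the placement (`refined = TRUE`); otherwise
#' the stage estimate is kept (`fallback = TRUE`, e.g. featureless overlap).
#'
#' @param tl the [tile()] to place.
#' @param canvas a [mosaic_canvas()] holding the tiles placed so far.
#' @param search an [alignment_search()].
#' @param est_offset `c(x, y)` stage-estimated mosaic position.
#' @param neighbors list of placed neighbor rects (see [score_placement()]).
#' @return One-row data.frame: `tile_id`, `placed_x_px`, `placed_y_px`,
#'   `x_ov`, `y_al`, `sigma_min`, `sigma_max`, `refined`, `fallback`.
#' @export
align_tile <- function(tl, canvas, search, est_offset, neighbors) {
  img <- tile_score_image(tl)
  md <- neighbor_min_depth(est_offset, ncol(img), nrow(img), neighbors,
                           search$downscale_factor)
  steps_x <- seq(-search$range_x_px, search$range_x_px,
                 by = search$coarse_step_px)
  steps_y <- seq(-search$range_y_px, search$range_y_px,
                 by = search$coarse_step_px)
  cand <- as.matrix(expand.grid(x = est_offset[1] + steps_x,
                                y = est_offset[2] + steps_y))
  sc <- apply(cand, 1, function(off)
    score_placement(off, img, canvas, neighbors, search$downscale_factor,
                    min_depth = md))
  if (all(!is.finite(sc)))
    stop("tile '", tl$tile_id, "' has no canvas overlap anywhere in the ",
         "search window", call. = FALSE)
  s_min <- min(sc[is.finite(sc)]); s_max <- max(sc[is.finite(sc)])
  refined <- (s_max - s_min) >= search$sigma_spread_threshold
  if (refined) {
    best <- cand[argmin_candidate(cand, sc, est_offset), ]
    fsteps <- seq(-search$coarse_step_px, search$coarse_step_px,
                  by = search$fine_step_px)
    fcand <- as.matrix(expand.grid(x = best[1] + fsteps,
                                   y = best[2] + fsteps))
    fsc <- apply(fcand, 1, function(off)
      score_placement(off, img, canvas, neighbors, search$downscale_factor,
                      min_depth = md))
    placed <- fcand[argmin_candidate(fcand, fsc, est_offset), ]
    fallback <- FALSE
  } else {
    placed <- est_offset
    fallback <- TRUE
  }
  # realized overlap / off-axis shift relative to the primary neighbor
  x_ov <- NA_integer_; y_al <- NA_integer_
  if (length(neighbors) > 0) {
    nb <- neighbors[[1]]
    horiz <- attr(neighbors, "orientation")[1] == "horizontal"
    if (horiz) {
      x_ov <- as.integer(max(0, nb[3] - placed[1]))
      y_al <- as.integer(placed[2] - nb[2])
    } else {
      x_ov <- as.integer(max(0, nb[4] - placed[2]))
      y_al <- as.integer(placed[1] - nb[1])
    }
  }
  data.frame(tile_id = tl$tile_id,
             placed_x_px = as.integer(placed[1]),
             placed_y_px = as.integer(placed[2]),
             x_ov = x_ov, y_al = y_al,
             sigma_min = s_min, sigma_max = s_max,
             refined = refined, fallback = fallback,
             stringsAsFactors = FALSE)
}

#' Composite a placed tile into the canvas
#'
#' `blend = "overwrite"` replaces overlap pixels with the new tile;
#' `blend = "feather"` applies a linear ramp across the overlap depth along
#' each axis (ramp width = the plan's overlap extent), blending the new tile
#' with the existing canvas only where the canvas is already covered.
#'
#' @param canvas a [mosaic_canvas()].
#' @param tl the [tile()] to composite.
#' @param result its placement row from [align_tile()].
#' @param blend `"overwrite"` or `"feather"`.
#' @return The updated canvas.
#' @export
composite_tile <- function(canvas, tl, result, blend = "overwrite") {
  blend <- match.arg(blend, c("overwrite", "feather"))
  if (length(tl$channels) != dim(canvas$composite)[3])
    stop("tile channel count does not match the canvas", call. = FALSE)
  R <- nrow(tl$channels[[1]]); C <- ncol(tl$channels[[1]])
  x0 <- result$placed_x_px; y0 <- result$placed_y_px
  canvas <- grow_canvas(canvas, x0, y0, x0 + C, y0 + R)
  rows <- (y0 + canvas$origin[2] + 1):(y0 + canvas$origin[2] + R)
  cols <- (x0 + canvas$origin[1] + 1):(x0 + canvas$origin[1] + C)
  if (blend == "overwrite") {
    for (k in seq_along(tl$channels))
      canvas$composite[rows, cols, k] <- tl$channels[[k]]
  } else {
    ramp <- max(1L, canvas$plan$tile_px - canvas$plan$stride_px)
    wx <- pmin(1, (seq_len(C) - 1) / ramp, (C - seq_len(C)) / ramp)
    wy <- pmin(1, (seq_len(R) - 1) / ramp, (R - seq_len(R)) / ramp)
    w <- outer(wy, wx, pmin)
    cov <- canvas$covered[rows, cols]
    w[!cov] <- 1          # nothing beneath: copy verbatim
    for (k in seq_along(tl$channels)) {
      old <- canvas$composite[rows, cols, k]
      canvas$composite[rows, cols, k] <-
        clip8(round_half_up(w * tl$channels[[k]] + (1 - w) * old))
    }
  }
  canvas$score[rows, cols] <-
    Reduce(`+`, lapply(seq_along(tl$channels),
                       function(k) canvas$composite[rows, cols, k])) /
    length(tl$channels)
  canvas$covered[rows, cols] <- TRUE
  canvas$placements <- rbind(canvas$placements, result)
  canvas
}

#' Stitch a full tile set into a mosaic
#'
#' Sequentially processes tiles in row-major grid order: optional
#' resonant-scan correction, optional radial distortion compensation, then
#' stage-informed alignment ([align_tile()]) against the tiles already
#' composited, and compositing. The first tile is placed at the origin; all
#' placements are relative to it. The run is deterministic for fixed inputs.
#'
#' @param tiles list of [tile()] objects covering a full grid.
#' @param stage_log optional data.frame (see [read_stage_log()]) overriding
#'   the tiles' stage positions; every tile_id must have a row.
#' @param search an [alignment_search()].
#' @param distortion optional [distortion_params()]; when given, every tile
#'   is distortion-compensated before alignment.
#' @param resonant_beta optional usable-fraction for [correct_resonant()].
#' @param blend compositing rule, `"overwrite"` (default) or `"feather"`.
#' @return List with `canvas` (the [mosaic_canvas()]) and `placements`
#'   (data.frame, one row per tile).
#' @export
stitch_all <- function(tiles, stage_log = NULL, search = alignment_search(),
                       distortion = NULL, resonant_beta = NULL,
                       blend = "overwrite") {
  if (length(tiles) < 1) stop("no tiles given", call. = FALSE)
  ids <- vapply(tiles, function(t) t$tile_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate tile_id: ", ids[duplicated(ids)][1], call. = FALSE)
  if (!is.null(stage_log)) {
    for (i in seq_along(tiles)) {
      j <- match(tiles[[i]]$tile_id, stage_log$tile_id)
      if (is.na(j))
        stop("tile '", tiles[[i]]$tile_id, "' missing from the stage log",
             call. = FALSE)
      tiles[[i]]$stage_x_um <- stage_log$stage_x_um[j]
      tiles[[i]]$stage_y_um <- stage_log$stage_y_um[j]
    }
  }
  gc_ <- vapply(tiles, function(t) t$grid_col, integer(1))
  gr_ <- vapply(tiles, function(t) t$grid_row, integer(1))
  tiles <- tiles[order(gr_, gc_)]

  # per-tile preprocessing; compensated tiles are cropped by the common
  # invalid border band (where the remap samples outside the FOV) so the
  # zero fill cannot bias the alignment score — the crop is identical for
  # every tile, leaving all relative placements unchanged
  maps <- NULL; marg <- c(0L, 0L, 0L, 0L)
  if (!is.null(distortion)) {
    d <- dim(tiles[[1]]$channels[[1]])
    maps <- compute_pixel_maps(distortion, d[2], d[1])
    marg <- valid_margins(maps, distortion$x_off < 0, distortion$y_off < 0)
  }
  for (i in seq_along(tiles)) {
    ch <- tiles[[i]]$channels
    if (!is.null(resonant_beta))
      ch <- lapply(ch, correct_resonant, beta = resonant_beta)
    if (!is.null(distortion)) {
      ch <- lapply(ch, compensate, params = distortion, maps = maps)
      d <- dim(ch[[1]])
      ch <- lapply(ch, function(m)
        m[(marg[3] + 1):(d[1] - marg[4]), (marg[1] + 1):(d[2] - marg[2]),
          drop = FALSE])
    }
    tiles[[i]]$channels <- ch
  }

  plan <- infer_plan(tiles)
  margin <- search$range_x_px + search$coarse_step_px + 16L
  canvas <- mosaic_canvas(plan, channels = length(tiles[[1]]$channels),
                          margin_px = max(margin, search$range_y_px +
                                          search$coarse_step_px + 16L))
  ref <- tiles[[1]]
  pitch <- ref$pixel_pitch_nm
  lookup <- stats::setNames(seq_along(tiles),
                            paste(vapply(tiles, `[[`, integer(1), "grid_col"),
                                  vapply(tiles, `[[`, integer(1), "grid_row")))
  placed_rect <- list()
  for (i in seq_along(tiles)) {
    tl <- tiles[[i]]
    d <- dim(tl$channels[[1]])
    if (i == 1L) {
      res <- data.frame(tile_id = tl$tile_id, placed_x_px = 0L,
                        placed_y_px = 0L, x_ov = NA_integer_,
                        y_al = NA_integer_, sigma_min = NA_real_,
                        sigma_max = NA_real_, refined = FALSE,
                        fallback = FALSE, stringsAsFactors = FALSE)
    } else {
      est <- c(round_half_up((tl$stage_x_um - ref$stage_x_um) * 1000 / pitch),
               round_half_up((tl$stage_y_um - ref$stage_y_um) * 1000 / pitch))
      nbs <- list(); ori <- character()
      left <- lookup[paste(tl$grid_col - 1L, tl$grid_row)]
      top <- lookup[paste(tl$grid_col, tl$grid_row - 1L)]
      if (!is.na(left) && !is.null(placed_rect[[left]])) {
        nbs <- c(nbs, list(placed_rect[[left]])); ori <- c(ori, "horizontal")
      }
      if (!is.na(top) && !is.null(placed_rect[[top]])) {
        nbs <- c(nbs, list(placed_rect[[top]])); ori <- c(ori, "vertical")
      }
      attr(nbs, "orientation") <- ori
      res <- align_tile(tl, canvas, search, est, nbs)
    }
    canvas <- composite_tile(canvas, tl, res, blend = blend)
    placed_rect[[i]] <- c(res$placed_x_px, res$placed_y_px,
                          res$placed_x_px + d[2], res$placed_y_px + d[1])
  }
  list(canvas = canvas, placements = canvas$placements)
}

# margins (left, right, top, bottom) of the border band where the
# compensation remap samples outside the source tile; edges are trimmed
# greedily (worst edge first) until the remaining rectangle is fully valid
valid_margins <- function(maps, flip_x, flip_y) {
  V <- maps$Mx >= -1e-3 & maps$Mx <= maps$C - 1 + 1e-3 &
       maps$My >= -1e-3 & maps$My <= maps$R - 1 + 1e-3
  if (flip_x) V <- V[, rev(seq_len(ncol(V))), drop = FALSE]
  if (flip_y) V <- V[rev(seq_len(nrow(V))), , drop = FALSE]
  l <- 0L; r <- 0L; t <- 0L; b <- 0L
  repeat {
    rows <- (t + 1):(nrow(V) - b); cols <- (l + 1):(ncol(V) - r)
    if (length(rows) < 2 || length(cols) < 2)
      stop("distortion leaves no valid tile interior", call. = FALSE)
    sub <- V[rows, cols, drop = FALSE]
    if (all(sub)) break
    bad <- c(left = sum(!sub[, 1]), right = sum(!sub[, ncol(sub)]),
             top = sum(!sub[1, ]), bottom = sum(!sub[nrow(sub), ]))
    side <- which.max(bad)
    if (side == 1L) l <- l + 1L else if (side == 2L) r <- r + 1L
    else if (side == 3L) t <- t + 1L else b <- b + 1L
  }
  c(l, r, t, b)
}

# derive a mosaic plan from the tiles' grid indices, shape and stage steps
infer_plan <- function(tiles) {
  d <- dim(tiles[[1]]$channels[[1]])
  tile_px <- max(d)
  gc_ <- vapply(tiles, function(t) t$grid_col, integer(1))
  gr_ <- vapply(tiles, function(t) t$grid_row, integer(1))
  nx <- max(gc_) - min(gc_) + 1L
  ny <- max(gr_) - min(gr_) + 1L
  pitch <- tiles[[1]]$pixel_pitch_nm
  ov <- 0
  if (nx > 1L) {
    sx <- vapply(tiles, function(t) t$stage_x_um, numeric(1))
    step_px <- stats::median(diff(sort(unique(sx)))) * 1000 / pitch
    ov <- max(0, min(0.99, 1 - step_px / d[2]))
  } else if (ny > 1L) {
    sy <- vapply(tiles, function(t) t$stage_y_um, numeric(1))
    step_px <- stats::median(diff(sort(unique(sy)))) * 1000 / pitch
    ov <- max(0, min(0.99, 1 - step_px / d[1]))
  }
  plan_mosaic(nx, ny, tile_px, ov, pitch)
}

#' Write a placement table
#'
#' TSV with columns `tile_id placed_x_px placed_y_px x_ov y_al sigma_min
#' sigma_max refined fallback`.
#'
#' @param placements data.frame from [stitch_all()].
#' @param path output file.
#' @export
write_placements <- function(placements, path) {
  write.table(placements, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
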