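#' Diagnostic metrics from a confusion matrix
#'
#' Exact rational evaluation of
#' `accuracy = (TP + TN) / (TP + TN + FP + FN)`,
#' `sensitivity = TP / (TP + FN)` and `specificity = TN / (TN + FP)`.
#' A metric whose margin is empty (e.g. sensitivity with `TP + FN = 0`) is
#' flagged undefined and carries `NA` rather than a numeric sentinel.
#'
#' @param cm a [confusion_matrix()].
#' @return A `diagnostic_metrics` list: `accuracy`, `sensitivity`,
#'   `specificity` (fractions in \[0, 1\] or `NA`) and a logical `defined`
#'   vector.
#' @export
confusion_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  P <- cm$TP + cm$FN
  N <- cm$TN + cm$FP
  out <- list(
    accuracy = (cm$TP + cm$TN) / (P + N),
    sensitivity = if (P >= 1) cm$TP / P else NA_real_,
    specificity = if (N >= 1) cm$TN / N else NA_real_)
  out$defined <- c(accuracy = TRUE, sensitivity = P >= 1, specificity = N >= 1)
  structure(out, class = "diagnostic_metrics")
}

#' @export
print.diagnostic_metrics <- function(x, ...) {
  fmt <- function(v, ok) if (ok) sprintf("%.1f%%", 100 * v) else "n/a"
  cat(sprintf("accuracy %s  sensitivity %s  specificity %s\n",
              fmt(x$accuracy, x$defined["accuracy"]),
              fmt(x$sensitivity, x$defined["sensitivity"]),
              fmt(x$specificity, x$defined["specificity"])))
  invisible(x)
}

#' Flat JSON report of diagnostic metrics
#'
#' @param metrics a [confusion_metrics()] result.
#' @return JSON string; undefined metrics appear as `null`.
#' @export
metrics_json <- function(metrics) {
  stopifnot(inherits(metrics, "diagnostic_metrics"))
  jsonlite::toJSON(metrics[c("accuracy", "sensitivity", "specificity")],
                   auto_unbox = TRUE, digits = NA, na = "null")
}

#' Per-tile placement error against ground truth
#'
#' Euclidean distance between estimated and true tile offsets, matched by
#' `tile_id`. Because the stitcher anchors the first tile at the origin
#' while simulator truth is absolute, `align = "first"` (translate both
#' tables so their first common tile coincides) or `align = "mean"` is
#' usually appropriate; the measure is translation-equivariant.
#'
#' @param est data.frame with `tile_id`, `placed_x_px`, `placed_y_px` (a
#'   [stitch_all()] placement table).
#' @param truth data.frame with `tile_id`, `true_x_px`, `true_y_px` (a
#'   [simulate_scan()] truth table).
#' @param align `"none"`, `"first"` or `"mean"`.
#' @return List with `per_tile` (data.frame: tile_id, dx, dy, error) and
#'   `mean`, `max`, `rmse` in pixels.
#' @export
placement_error <- function(est, truth, align = c("first", "none", "mean")) {
  align <- match.arg(align)
  j <- match(est$tile_id, truth$tile_id)
  if (anyNA(j) || length(est$tile_id) != length(truth$tile_id))
    stop("unmatched tile ids: ",
         paste(unique(c(est$tile_id[is.na(j)],
                        setdiff(truth$tile_id, est$tile_id))),
               collapse = ", "), call. = FALSE)
  tx <- truth$true_x_px[j]; ty <- truth$true_y_px[j]
  dx <- est$placed_x_px - tx
  dy <- est$placed_y_px - ty
  if (align == "first") { dx <- dx - dx[1]; dy <- dy - dy[1] }
  if (align == "mean") { dx <- dx - mean(dx); dy <- dy - mean(dy) }
  err <- sqrt(dx^2 + dy^2)
  list(per_tile = data.frame(tile_id = est$tile_id, dx = dx, dy = dy,
                             error = err, stringsAsFactors = FALSE),
       mean = mean(err), max = max(err), rmse = sqrt(mean(err^2)))
}

#' Mosaic reconstruction error against the true scene
#'
#' Root-mean-square intensity difference over a validity mask, per channel
#' and combined, after cropping both images to their common extent.
#'
#' @param mosaic matrix or `[H, W, ch]` array.
#' @param truth_scene matrix or array with matching channel count.
#' @param mask optional logical matrix (TRUE = include); defaults to the
#'   full common extent.
#' @return List with `per_channel` and `combined` RMSE in intensity levels.
#' @export
reconstruction_error <- function(mosaic, truth_scene, mask = NULL) {
  m <- as_channel_stack(mosaic)
  t <- as_channel_stack(truth_scene)
  if (dim(m)[3] != dim(t)[3])
    stop("channel counts differ", call. = FALSE)
  H <- min(dim(m)[1], dim(t)[1]); W <- min(dim(m)[2], dim(t)[2])
  m <- m[seq_len(H), seq_len(W), , drop = FALSE]
  t <- t[seq_len(H), seq_len(W), , drop = FALSE]
  if (is.null(mask)) mask <- matrix(TRUE, H, W)
  else mask <- mask[seq_len(H), seq_len(W)]
  if (!any(mask)) stop("empty validity mask", call. = FALSE)
  per <- vapply(seq_len(dim(m)[3]), function(k) {
    d <- (m[, , k] - t[, , k])[mask]
    sqrt(mean(d^2))
  }, numeric(1))
  d_all <- unlist(lapply(seq_len(dim(m)[3]),
                         function(k) (m[, , k] - t[, , k])[mask]))
  list(per_channel = per, combined = sqrt(mean(d_all^2)))
}
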