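# TOML configuration. Run settings travel as a small TOML subset: [section]
# headers, `key = value` pairs with numeric, boolean, string and flat-array
# values, and `#` comments. That subset covers every parameter the pipeline
# exposes; no installed package parses TOML, so the reader lives here.

#' Read or write a pipeline configuration (TOML subset)
#'
#' Supported syntax: `[section]` headers; `key = value` with numbers,
#' `true`/`false`, double-quoted strings, and flat arrays of those;
#' `#` comments. Unknown syntax is an error.
#'
#' @param path file path.
#' @return `read_toml` returns a named list of sections (named lists).
#' @export
read_toml <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  out <- list()
  section <- NULL
  parse_scalar <- function(tok) {
    tok <- trimws(tok)
    if (tok %in% c("true", "false")) return(tok == "true")
    if (grepl('^".*"$', tok)) return(gsub('^"|"$', "", tok))
    val <- suppressWarnings(as.numeric(tok))
    if (is.na(val)) stop("cannot parse TOML value: ", tok, call. = FALSE)
    val
  }
  for (raw in lines) {
    line <- sub("#.*$", "", raw)
    line <- trimws(line)
    if (line == "") next
    if (grepl("^\\[[^]]+\\]$", line)) {
      section <- gsub("^\\[|\\]$", "", line)
      if (is.null(out[[section]])) out[[section]] <- list()
      next
    }
    m <- regmatches(line, regexec("^([A-Za-z0-9_.-]+)\\s*=\\s*(.+)$", line))[[1]]
    if (length(m) != 3) stop("cannot parse TOML line: ", raw, call. = FALSE)
    key <- m[2]; rhs <- m[3]
    value <- if (grepl("^\\[.*\\]$", rhs)) {
      toks <- strsplit(gsub("^\\[|\\]$", "", rhs), ",")[[1]]
      unlist(lapply(toks, parse_scalar))
    } else parse_scalar(rhs)
    if (is.null(section)) out[[key]] <- value
    else out[[section]][[key]] <- value
  }
  out
}

#' @rdname read_toml
#' @param config named list of sections (named lists of scalars/vectors).
#' @export
write_toml <- function(config, path) {
  fmt <- function(v) {
    one <- function(x) {
      if (is.character(x)) sprintf('"%s"', x)
      else if (is.logical(x)) tolower(as.character(x))
      else format(x, scientific = FALSE)
    }
    if (length(v) > 1) paste0("[", paste(vapply(v, one, character(1)),
                                         collapse = ", "), "]")
    else one(v)
  }
  lines <- character()
  for (sec in names(config)) {
    if (is.list(config[[sec]])) {
      lines <- c(lines, sprintf("[%s]", sec))
      for (key in names(config[[sec]]))
        lines <- c(lines, sprintf("%s = %s", key, fmt(config[[sec]][[key]])))
      lines <- c(lines, "")
    } else {
      lines <- c(lines, sprintf("%s = %s", sec, fmt(config[[sec]])))
    }
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Default run configuration
#'
#' All tunable pipeline parameters with their standard values: alignment
#' search (coarse 10 px, fine 2 px, sigma threshold 1.5, range 30 px),
#' overlap 0.09, distortion scaling S = 60, H&E colors (180, 0, 90) /
#' (210, 165, 250) with k = 2.5, enhancement gain caps 8.0 (THG) /
#' 5.0 (TPEF), background radius 31 px.
#'
#' @param overrides named list of sections to merge over the defaults;
#'   unknown sections or keys are rejected.
#' @return Named list of sections.
#' @export
default_config <- function(overrides = list()) {
  cfg <- list(
    mosaic = list(overlap = 0.09, pixel_pitch_nm = 167),
    align = list(range_x = 30, range_y = 30, coarse_step = 10, fine_step = 2,
                 sigma_threshold = 1.5, downscale = 2, blend = "overwrite"),
    distortion = list(A_deg = 25.2, x_off = 6.0, y_off = 20.0,
                      s_x = 60.0, s_y = 60.0, mode = "pincushion"),
    resonant = list(beta = 0.9),
    he = list(h_color = c(180, 0, 90), e_color = c(210, 165, 250), k = 2.5),
    dce = list(alpha_max_thg = 8.0, alpha_max_tpef = 5.0, bg_radius = 31,
               gamma = 1.0),
    simulate = list(tile_px = 400, jitter_px = 8, noise_sd = 5, seed = 1))
  for (sec in names(overrides)) {
    if (!sec %in% names(cfg))
      stop("unknown config section: [", sec, "]", call. = FALSE)
    for (key in names(overrides[[sec]])) {
      if (!key %in% names(cfg[[sec]]))
        stop("unknown config key: ", sec, ".", key, call. = FALSE)
      cfg[[sec]][[key]] <- overrides[[sec]][[key]]
    }
  }
  cfg
}
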