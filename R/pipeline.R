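#' Pipeline run configuration
#'
#' Bundles and validates every setting of the detect pipeline. All fields
#' are validated here, before any image is read, so an invalid configuration
#' never produces partial output.
#'
#' @param channel_policy Color reduction for [read_strip_image()].
#' @param scales,support_len,aggregate,boundary See [wavelet_params()].
#' @param n,mu,min_prominence,min_snr,exclude_boundary See
#'   [detector_config()].
#' @param mode ROI mode hint: `"auto"`, `"strip"` or `"dot"`.
#' @param format Report format, `"json"` or `"csv"`.
#' @param include_rows Include the per-row boundary table in reports.
#' @param verbosity 0 = silent, 1 = per-image summary, 2 = per-stage detail
#'   (written to `stderr`).
#' @return A list of class `run_config` with elements `channel_policy`,
#'   `cwt_params`, `det_config`, `mode`, `format`, `include_rows`,
#'   `verbosity`.
#' @export
run_config <- function(channel_policy = "red", scales = 30:37,
                       support_len = 128, aggregate = "mean",
                       boundary = "reflect", n = 2, mu = 32,
                       min_prominence = 0, min_snr = 4,
                       exclude_boundary = TRUE, mode = "auto",
                       format = "json", include_rows = FALSE, verbosity = 1) {
  if (!channel_policy %in% c("red", "luminance", "gray")) {
    abort_config("`channel_policy` must be one of red, luminance, gray.")
  }
  if (!mode %in% c("auto", "strip", "dot")) {
    abort_config("`mode` must be one of auto, strip, dot.")
  }
  if (!format %in% c("json", "csv")) {
    abort_config("`format` must be json or csv.")
  }
  structure(
    list(
      channel_policy = channel_policy,
      cwt_params = wavelet_params(scales, support_len, aggregate, boundary),
      det_config = detector_config(n, mu, min_prominence, min_snr, exclude_boundary),
      mode = mode, format = format,
      include_rows = isTRUE(include_rows),
      verbosity = as.integer(verbosity)
    ),
    class = "run_config"
  )
}

#' Read a run configuration from a key-value text file
#'
#' One `key = value` pair per line; `#` starts a comment. Keys are the
#' arguments of [run_config()]; `scales` accepts a range string like
#' `"30:37"` or a comma-separated list.
#'
#' @param path Path to the configuration file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("config file not found: '%s'.", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) {
    abort_config(sprintf("malformed config line: '%s'.", lines[bad][1]))
  }
  keys <- trimws(vapply(kv, `[[`, "", 1))
  vals <- trimws(vapply(kv, `[[`, "", 2))
  args <- list()
  for (i in seq_along(keys)) {
    key <- keys[i]; val <- vals[i]
    args[[key]] <- switch(key,
      channel_policy = , aggregate = , boundary = , mode = , format = val,
      scales = parse_scales(val),
      include_rows = , exclude_boundary = as.logical(val),
      support_len = , n = , mu = , verbosity = as.integer(val),
      min_prominence = , min_snr = as.numeric(val),
      abort_config(sprintf("unknown config key: '%s'.", key))
    )
  }
  do.call(run_config, args)
}

parse_scales <- function(val) {
  if (grepl(":", val, fixed = TRUE)) {
    parts <- as.numeric(strsplit(val, ":", fixed = TRUE)[[1]])
    if (length(parts) != 2 || any(is.na(parts))) {
      abort_config(sprintf("bad scales range: '%s'.", val))
    }
    seq(parts[1], parts[2])
  } else {
    out <- as.numeric(strsplit(val, ",", fixed = TRUE)[[1]])
    if (any(is.na(out))) abort_config(sprintf("bad scales list: '%s'.", val))
    out
  }
}

#' Write a machine-readable quantification report
#'
#' Serializes the per-signal table produced by [analyze_strip()] (ROI
#' bounds, apex positions, raw and max-gray-normalized avePix) to JSON or
#' CSV, optionally including each signal's per-row boundary table. An empty
#' result set produces a valid file with zero records. No timestamps are
#' written, so identical results serialize byte-identically.
#'
#' @param results Tibble from [analyze_strip()] (its `results` attribute, if
#'   present, supplies the row tables).
#' @param path Output file path.
#' @param format `"json"` or `"csv"`.
#' @param include_rows Include per-row trough/baseline/area tables
#'   (JSON: nested; CSV: a sibling `*_rows.csv` file).
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("json", "csv"),
                         include_rows = FALSE) {
  format <- match.arg(format)
  dir <- dirname(path)
  if (!dir.exists(dir)) abort_io(sprintf("output directory does not exist: '%s'.", dir))
  signals <- tibble::as_tibble(results)
  row_tables <- NULL
  if (include_rows) {
    qr <- attr(results, "results")
    if (!is.null(qr)) {
      row_tables <- lapply(qr, function(q) q$rows)
    }
  }
  ok <- tryCatch({
    if (format == "json") {
      payload <- list(signals = signals)
      if (!is.null(row_tables)) payload$rows <- row_tables
      jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, na = "null")
    } else {
      readr::write_csv(signals, path, na = "")
      if (!is.null(row_tables) && length(row_tables)) {
        rows_path <- sub("\\.csv$", "_rows.csv", path)
        all_rows <- dplyr::bind_rows(row_tables, .id = "roi_id")
        readr::write_csv(all_rows, rows_path, na = "")
      }
    }
    TRUE
  }, error = function(e) {
    if (inherits(e, "flfa_error")) rlang::cnd_signal(e)
    abort_io(sprintf("failed to write report '%s': %s", path, conditionMessage(e)))
  })
  invisible(path)
}

#' Read back a quantification report
#'
#' @param path Report file written by [write_report()].
#' @param format `"json"` or `"csv"`; guessed from the extension by default.
#' @return Tibble of per-signal records (JSON row tables, when present, are
#'   attached as a `rows` attribute).
#' @export
read_report <- function(path, format = NULL) {
  if (!file.exists(path)) abort_io(sprintf("report not found: '%s'.", path))
  if (is.null(format)) {
    format <- if (tolower(tools::file_ext(path)) == "json") "json" else "csv"
  }
  if (format == "json") {
    payload <- jsonlite::fromJSON(path)
    out <- tibble::as_tibble(payload$signals)
    if (!is.null(payload$rows)) attr(out, "rows") <- payload$rows
    out
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
}

#' Run the detect pipeline over image files
#'
#' Loads each image, extracts and quantifies all fluorescence signals, and
#' writes one report per image next to the requested output stem.
#'
#' @param paths Character vector of image file paths.
#' @param config A [run_config()].
#' @param out_dir Directory for report files (default: alongside each image).
#' @return Tibble binding all per-signal records (with an `image` column),
#'   invisibly; reports are written as a side effect.
#' @export
run_detect <- function(paths, config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  log_msg <- function(level, ...) {
    if (config$verbosity >= level) message(sprintf(...))
  }
  all_out <- list()
  for (p in paths) {
    img <- read_strip_image(p, config$channel_policy)
    res <- analyze_strip(img, config$cwt_params, config$det_config, mode = config$mode)
    log_msg(1, "%s: %d signal(s) detected", basename(p), nrow(res))
    if (config$verbosity >= 2 && nrow(res)) {
      for (i in seq_len(nrow(res))) {
        log_msg(2, "  roi %d [%d..%d] apex %d avePix %.4g (%d/%d rows)",
                res$roi_id[i], res$x_left[i], res$x_right[i], res$x_apex[i],
                res$ave_pix[i], res$n_detected[i], res$n_rows[i])
      }
    }
    stem <- tools::file_path_sans_ext(basename(p))
    dir <- if (is.null(out_dir)) dirname(p) else out_dir
    out_path <- file.path(dir, paste0(stem, "_report.", config$format))
    write_report(res, out_path, config$format, include_rows = config$include_rows)
    res$image <- basename(p)
    all_out[[length(all_out) + 1]] <- res
  }
  invisible(dplyr::bind_rows(all_out))
}
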