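#' Strip image container
#'
#' A thin wrapper around a numeric intensity matrix holding a grayscale
#' strip (or dot-matrix) image at its native gray scale. Row 1 is the top of
#' the image; the column index runs along the long axis of the strip (the
#' direction crossing the test/control lines), the row index across it.
#'
#' @param data Numeric matrix of intensities, values in `[0, max_gray]`.
#' @param max_gray Full-scale gray value of the source bit depth (255 for
#'   8-bit, 65535 for 16-bit). Defaults to 255.
#' @param channel_policy Label recording how color was reduced to one channel
#'   (`"red"`, `"luminance"` or `"gray"`).
#'
#' @return An object of class `lfa_image`.
#' @export
lfa_image <- function(data, max_gray = 255, channel_policy = "gray") {
  if (!is.matrix(data) || !is.numeric(data)) {
    abort_config("`data` must be a numeric matrix.")
  }
  if (nrow(data) < 1 || ncol(data) < 1) {
    abort_config("image must have at least one row and one column.")
  }
  if (!all(is.finite(data))) {
    abort_config("image intensities must all be finite.")
  }
  if (!is.numeric(max_gray) || length(max_gray) != 1 || max_gray <= 0) {
    abort_config("`max_gray` must be a single positive number.")
  }
  if (min(data) < 0 || max(data) > max_gray) {
    abort_config(sprintf(
      "image intensities must lie in [0, %s]; observed range [%s, %s].",
      format(max_gray), format(min(data)), format(max(data))
    ))
  }
  structure(
    list(data = data, max_gray = max_gray, channel_policy = channel_policy),
    class = "lfa_image"
  )
}

#' @export
print.lfa_image <- function(x, ...) {
  cat(sprintf(
    "<lfa_image> %d x %d, max_gray = %s, channel_policy = %s\n",
    nrow(x$data), ncol(x$data), format(x$max_gray), x$channel_policy
  ))
  invisible(x)
}

#' @export
dim.lfa_image <- function(x) dim(x$data)

# ITU-R BT.601 luminance weights.
.lum_weights <- c(0.299, 0.587, 0.114)

#' Read a strip image
#'
#' Reads an 8- or 16-bit PNG or TIFF image (single-channel or RGB) and
#' reduces it to a working grayscale intensity matrix at the native gray
#' scale of the file. Quantum-dot labels emit red fluorescence on a dark
#' background, so selecting the red plane (the default) maximizes band
#' contrast; standard 0.299/0.587/0.114 luminance weighting is available for
#' generality. Single-channel input ignores the policy.
#'
#' @param path Path to a PNG or TIFF file.
#' @param channel_policy One of `"red"`, `"luminance"`, `"gray"`. `"gray"`
#'   requires single-channel input.
#'
#' @return An [lfa_image].
#' @export
read_strip_image <- function(path, channel_policy = c("red", "luminance", "gray")) {
  channel_policy <- match.arg(channel_policy)
  if (!is.character(path) || length(path) != 1 || !file.exists(path)) {
    abort_io(sprintf("file not found or unreadable: '%s'.", path))
  }
  ext <- tolower(tools::file_ext(path))
  res <- tryCatch(
    switch(ext,
      png = {
        arr <- png::readPNG(path, info = TRUE)
        info <- attr(arr, "info")
        list(arr = arr, bits = info$bit.depth)
      },
      tif = ,
      tiff = {
        arr <- tiff::readTIFF(path, info = TRUE)
        info <- attributes(arr)
        bits <- info$bits.per.sample
        if (is.null(bits)) bits <- 8L
        list(arr = arr, bits = bits)
      },
      abort_io(sprintf("unsupported file format '.%s' (expected PNG or TIFF): '%s'.", ext, path))
    ),
    error = function(e) {
      if (inherits(e, "flfa_error")) rlang::cnd_signal(e)
      abort_io(sprintf("failed to read image '%s': %s", path, conditionMessage(e)))
    }
  )
  bits <- as.integer(res$bits[1])
  if (!bits %in% c(8L, 16L)) {
    abort_io(sprintf("unsupported bit depth %d in '%s' (expected 8 or 16).", bits, path))
  }
  max_gray <- 2^bits - 1
  arr <- res$arr

  if (is.matrix(arr)) {
    mat <- arr
    policy <- "gray" # single-channel input ignores the policy
  } else if (length(dim(arr)) == 3) {
    nchan <- dim(arr)[3]
    if (nchan == 1) {
      mat <- arr[, , 1]
      policy <- "gray"
    } else if (nchan == 3) {
      if (channel_policy == "gray") {
        abort_config("channel_policy 'gray' requires single-channel input; file has 3 channels.")
      }
      mat <- switch(channel_policy,
        red = arr[, , 1],
        luminance = .lum_weights[1] * arr[, , 1] +
          .lum_weights[2] * arr[, , 2] + .lum_weights[3] * arr[, , 3]
      )
      policy <- channel_policy
    } else {
      abort_io(sprintf("unsupported channel count %d in '%s' (expected 1 or 3).", nchan, path))
    }
  } else {
    abort_io(sprintf("unsupported image layout in '%s'.", path))
  }

  # readers return values on [0, 1]; restore the native gray scale
  data <- round(mat * max_gray)
  data <- pmin(pmax(data, 0), max_gray)
  lfa_image(data, max_gray = max_gray, channel_policy = policy)
}

#' Write a strip image to disk
#'
#' Writes an [lfa_image] as PNG (8-bit) or TIFF (8- or 16-bit), matching the
#' image's `max_gray`.
#'
#' @param image An [lfa_image].
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_strip_image <- function(image, path) {
  stopifnot(inherits(image, "lfa_image"))
  ext <- tolower(tools::file_ext(path))
  scaled <- image$data / image$max_gray
  ok <- tryCatch(
    {
      if (ext == "png") {
        if (image$max_gray > 255) {
          abort_config("PNG output supports 8-bit only here; use TIFF for 16-bit images.")
        }
        png::writePNG(scaled, target = path)
      } else if (ext %in% c("tif", "tiff")) {
        bits <- if (image$max_gray > 255) 16L else 8L
        tiff::writeTIFF(scaled, path, bits.per.sample = bits)
      } else {
        abort_io(sprintf("unsupported output format '.%s' (expected PNG or TIFF).", ext))
      }
      TRUE
    },
    error = function(e) {
      if (inherits(e, "flfa_error")) rlang::cnd_signal(e)
      abort_io(sprintf("failed to write image '%s': %s", path, conditionMessage(e)))
    }
  )
  invisible(path)
}
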