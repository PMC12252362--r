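#' Extract fluorescence regions of interest
#'
#' Two-stage projection positioning. First the image is projected along the
#' X direction (summing over rows): valid peaks on the wavelet-transformed
#' projection give column slabs `[x_left, x_right]` from their flanking
#' troughs. Each slab is then projected in the Y direction (summing over its
#' columns): if no valid peak is found there the slab is assumed to contain
#' only strip fluorescence and becomes one full-height strip ROI; otherwise
#' each valid Y peak yields one spot ROI (dot-matrix format).
#'
#' @param image An [lfa_image].
#' @param cwt_params [wavelet_params()].
#' @param det_config [detector_config()].
#' @param mode `"auto"` (default; the Y-projection decides, as above),
#'   `"strip"` (force full-height ROIs) or `"dot"` (use Y peaks when present,
#'   fall back to strip otherwise).
#' @return Tibble with one row per ROI: `roi_id`, `mode`, `x_left`,
#'   `x_right`, `x_apex`, `top`, `down`, `y_apex` (`NA` for strip ROIs).
#'   Zero rows when nothing is detected.
#' @export
extract_rois <- function(image, cwt_params = wavelet_params(),
                         det_config = detector_config(),
                         mode = c("auto", "strip", "dot")) {
  stopifnot(inherits(image, "lfa_image"))
  mode <- match.arg(mode)
  h <- nrow(image$data)
  empty <- tibble::tibble(
    roi_id = integer(), mode = character(),
    x_left = integer(), x_right = integer(), x_apex = integer(),
    top = integer(), down = integer(), y_apex = integer()
  )

  px <- project_profile(image, "collapse_rows")
  cx <- cwt(px, cwt_params)
  pkx <- find_peaks(cx, ref = px, config = det_config)
  pkx <- pkx[pkx$valid, , drop = FALSE]
  if (nrow(pkx) == 0) return(empty)

  rois <- list()
  for (i in seq_len(nrow(pkx))) {
    x_left <- pkx$j_left[i]
    x_right <- pkx$j_right[i]
    x_apex <- pkx$apex[i]
    spots <- NULL
    if (mode != "strip") {
      py <- project_profile(image, "collapse_cols", bounds = c(1L, h, x_left, x_right))
      cy <- cwt(py, cwt_params)
      pky <- find_peaks(cy, ref = py, config = det_config)
      pky <- pky[pky$valid, , drop = FALSE]
      if (nrow(pky) > 0) spots <- pky
    }
    if (is.null(spots)) {
      rois[[length(rois) + 1]] <- tibble::tibble(
        mode = "strip", x_left = x_left, x_right = x_right, x_apex = x_apex,
        top = 1L, down = h, y_apex = NA_integer_
      )
    } else {
      rois[[length(rois) + 1]] <- tibble::tibble(
        mode = "spot", x_left = x_left, x_right = x_right, x_apex = x_apex,
        top = spots$j_left, down = spots$j_right, y_apex = spots$apex
      )
    }
  }
  out <- dplyr::bind_rows(rois)
  dplyr::bind_cols(tibble::tibble(roi_id = seq_len(nrow(out))), out)
}

# Intensity-weighted center/width estimate (in samples) of the band inside
# an ROI, from the background-subtracted X projection over the ROI's rows.
# A linear baseline between the window endpoints removes the stray-light
# trend before the moments. The moment window starts at the ROI columns and
# iterates to center +/- 3 sigma_hat, growing beyond the ROI if the band is
# wider than the extraction slab (whose width is kernel-dominated) and
# shrinking away from rectified tail noise otherwise.
estimate_band_profile <- function(image, x_left, x_right, top, down) {
  px <- project_profile(image, "collapse_rows", bounds = c(top, down, 1L, ncol(image$data)))$value
  w <- length(px)
  roi_w <- x_right - x_left + 1L
  lo <- x_left; hi <- x_right
  m <- (x_left + x_right) / 2
  sigma <- roi_w / 4
  for (iter in 1:4) {
    seg <- px[lo:hi]
    ns <- length(seg)
    if (ns < 3) break
    base <- seq(seg[1], seg[ns], length.out = ns)
    p <- pmax(seg - base, 0)
    tot <- sum(p)
    if (tot <= 0) {
      return(list(center = m, sigma = max(2, roi_w / 6)))
    }
    xs <- lo:hi
    m <- sum(xs * p) / tot
    sigma <- sqrt(sum((xs - m)^2 * p) / tot)
    # undo the variance shrinkage of measuring a Gaussian over a +/- a sigma
    # window: var_trunc = var * (1 - 2 a phi(a) / (2 Phi(a) - 1))
    a <- min(m - lo, hi - m) / sigma
    shrink <- 1 - 2 * a * stats::dnorm(a) / pmax(2 * stats::pnorm(a) - 1, 1e-12)
    if (is.finite(shrink) && shrink > 0.1) sigma <- sigma / sqrt(shrink)
    sigma <- min(max(sigma, 2), roi_w / 2)
    lo <- max(1L, as.integer(floor(m - 3 * sigma)))
    hi <- min(w, as.integer(ceiling(m + 3 * sigma)))
  }
  list(center = m, sigma = sigma)
}

#' Quantify one fluorescence ROI by per-scan-line peak integration
#'
#' Scans the ROI row by row. Each row profile is wavelet-transformed at a
#' scale matched to the band width and its peak delimited by flanking
#' troughs `dp_l(y)`, `dp_r(y)`; the row baseline (mean of the raw row values
#' at the troughs) is subtracted and the row area integrated. Rows with no
#' valid peak contribute neither area nor width. The quantification
#' statistic is
#' `avePix = sum_y sum_x (f(x,y) - baseval_y) / sum_y (dp_r(y) - dp_l(y))`
#' over detected rows — the average background-subtracted fluorescence gray
#' value per pixel.
#'
#' By default the scan-line scale is `sqrt(2)` times the band width estimated
#' from the ROI's own X projection: at that scale the Ricker response's
#' flanking minima fall at three estimated band widths from the center, so
#' the integration window matches the band's effective support.
#'
#' @param image An [lfa_image].
#' @param roi One ROI: a single row of [extract_rois()] output (or a list
#'   with `x_left`, `x_right`, `top`, `down`).
#' @param cwt_params [wavelet_params()]; `aggregate` and `boundary` carry
#'   over to the scan-line transform.
#' @param det_config [detector_config()]; boundary exclusion is disabled for
#'   scan lines (the ROI is already a selected region whose edges act as
#'   fallback troughs).
#' @param row_scales Optional explicit wavelet scale(s) for the scan lines,
#'   overriding the matched-scale default.
#' @return An object of class `quant_result`: a list with `roi`, `rows`
#'   (tibble: `y`, `dp_l`, `dp_r`, `baseval`, `width`, `area`, `detected`),
#'   `ave_pix`, `rel_intensity` (`ave_pix / max_gray`), `volume` (sum of row
#'   areas), `surface` (background-subtracted value grid for 3D
#'   reconstruction), `sigma_hat` and `row_scales`.
#' @export
quantify_roi <- function(image, roi, cwt_params = wavelet_params(),
                         det_config = detector_config(), row_scales = NULL) {
  stopifnot(inherits(image, "lfa_image"))
  x_left <- as.integer(roi$x_left[1]); x_right <- as.integer(roi$x_right[1])
  top <- as.integer(roi$top[1]); down <- as.integer(roi$down[1])
  h <- nrow(image$data); w <- ncol(image$data)
  if (any(is.na(c(x_left, x_right, top, down))) ||
      x_left < 1 || x_right > w || top < 1 || down > h ||
      x_left > x_right || top > down) {
    abort_config("ROI bounds must lie inside the image with x_left <= x_right, top <= down.")
  }
  W <- x_right - x_left + 1L
  H <- down - top + 1L
  if (W < 2 && H < 2) {
    abort_config("degenerate ROI (single pixel) cannot be quantified.")
  }
  if (W < 8) {
    abort_processing(sprintf("ROI too narrow to scan (width %d < 8 samples).", W))
  }

  prof <- estimate_band_profile(image, x_left, x_right, top, down)
  sigma_hat <- prof$sigma
  if (is.null(row_scales)) {
    row_scales <- sqrt(2) * sigma_hat
  }
  # scan window: the ROI columns, expanded where needed so that (i) the
  # band's +/- 3 sigma support fits and (ii) the scan-line kernel, centered
  # at the expected trough position, stays clear of the window's mirrored
  # boundary extension
  half_win <- ceiling(3 * sigma_hat + 4 * max(row_scales))
  sx_l <- min(x_left, max(1L, as.integer(floor(prof$center - half_win))))
  sx_r <- max(x_right, min(w, as.integer(ceiling(prof$center + half_win))))
  W <- sx_r - sx_l + 1L
  # full 4 s kernel support, but never longer than the window itself: a
  # kernel longer than the window would see tiled reflections of the band
  # and drag the troughs to the window edges
  support_row <- min(
    2L * as.integer(ceiling(4 * max(row_scales))) + 1L,
    2L * as.integer(floor((W - 1) / 2)) + 1L
  )
  row_scales <- pmin(row_scales, (support_row - 1) / 4)
  rparams <- wavelet_params(
    scales = row_scales, support_len = support_row,
    aggregate = if (length(row_scales) == 1) "single_scale" else cwt_params$aggregate,
    boundary = cwt_params$boundary
  )
  row_config <- det_config
  row_config$exclude_boundary <- FALSE

  rows_mat <- image$data[top:down, sx_l:sx_r, drop = FALSE]
  ker <- cwt_kernels(rparams)
  hk <- ker$h

  if (rparams$aggregate == "max") {
    Wmat <- t(vapply(seq_len(H), function(r) {
      curve_values(cwt(rows_mat[r, ], rparams))
    }, numeric(W)))
  } else {
    kbar <- ker$kbar
    rows_ext <- if (rparams$boundary == "zero") {
      cbind(matrix(0, H, hk), rows_mat, matrix(0, H, hk))
    } else {
      rows_mat[, extension_index(W, hk, rparams$boundary), drop = FALSE]
    }
    # centered convolution of every row at once: one dense Toeplitz multiply
    L <- 2L * hk + 1L
    Tm <- matrix(0, W + 2L * hk, W)
    cols <- rep(seq_len(W), each = L)
    rws <- as.vector(outer(seq_len(L), seq_len(W), function(j, i) i + j - 1L))
    Tm[cbind(rws, cols)] <- rep(kbar, W)
    Wmat <- rows_ext %*% Tm
  }
  knorm <- if (rparams$aggregate == "max") {
    max(sqrt(rowSums(ker$K^2)))
  } else {
    sqrt(sum(ker$kbar^2))
  }

  y <- integer(H); dp_l <- rep(NA_integer_, H); dp_r <- rep(NA_integer_, H)
  baseval <- rep(NA_real_, H); area <- rep(NA_real_, H)
  width <- rep(NA_integer_, H); detected <- logical(H)
  surface <- matrix(0, H, W)

  for (r in seq_len(H)) {
    y[r] <- top + r - 1L
    raw <- rows_mat[r, ]
    wrow <- Wmat[r, ]
    quant_floor <- if (all(raw == round(raw))) sqrt(1 / 12) else 0
    noise_sd <- max(stats::mad(diff(raw)) / sqrt(2), quant_floor) * knorm
    d <- first_derivative(wrow, row_config$n)
    apexes <- derivative_crossings(wrow, d, from_pos = TRUE)
    if (!length(apexes)) next
    troughs <- derivative_crossings(wrow, d, from_pos = FALSE)
    best <- NULL
    for (a in apexes) {
      pk <- delimit_one(wrow, raw, a, row_config, troughs = troughs, noise_sd = noise_sd)
      if (pk$valid && (is.null(best) || pk$prominence > best$prominence)) best <- pk
    }
    if (is.null(best)) next
    detected[r] <- TRUE
    dp_l[r] <- best$j_left
    dp_r[r] <- best$j_right
    baseval[r] <- best$baseval
    width[r] <- best$j_right - best$j_left
    span <- best$j_left:best$j_right
    vals <- raw[span] - best$baseval
    area[r] <- sum(vals)
    surface[r, span] <- vals
  }

  rows <- tibble::tibble(
    y = y,
    dp_l = ifelse(is.na(dp_l), NA_integer_, sx_l - 1L + dp_l),
    dp_r = ifelse(is.na(dp_r), NA_integer_, sx_l - 1L + dp_r),
    baseval = baseval, width = width, area = area, detected = detected
  )
  volume <- sum(area[detected])
  widths_sum <- sum(width[detected])
  ave_pix <- if (widths_sum > 0) volume / widths_sum else 0
  structure(
    list(
      roi = tibble::as_tibble(roi)[1, , drop = FALSE],
      rows = rows,
      ave_pix = ave_pix,
      rel_intensity = ave_pix / image$max_gray,
      volume = volume,
      surface = surface,
      scan_left = sx_l,
      scan_right = sx_r,
      sigma_hat = sigma_hat,
      row_scales = row_scales,
      max_gray = image$max_gray
    ),
    class = "quant_result"
  )
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf(
    "<quant_result> ROI [%d, %d] x [%d, %d] (%s): avePix = %.4g (relative %.4g), volume = %.4g, %d/%d rows detected\n",
    x$roi$x_left, x$roi$x_right, x$roi$top, x$roi$down,
    if (!is.null(x$roi$mode)) x$roi$mode else "roi",
    x$ave_pix, x$rel_intensity, x$volume,
    sum(x$rows$detected), nrow(x$rows)
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.quant_result <- function(x, ...) x$rows

#' @importFrom generics glance
#' @export
glance.quant_result <- function(x, ...) {
  tibble::tibble(
    mode = if (!is.null(x$roi$mode)) x$roi$mode else NA_character_,
    x_left = x$roi$x_left, x_right = x$roi$x_right,
    x_apex = if (!is.null(x$roi$x_apex)) x$roi$x_apex else NA_integer_,
    top = x$roi$top, down = x$roi$down,
    n_rows = nrow(x$rows), n_detected = sum(x$rows$detected),
    ave_pix = x$ave_pix, rel_intensity = x$rel_intensity,
    volume = x$volume, sigma_hat = x$sigma_hat
  )
}

#' Detect and quantify every fluorescence signal on a strip image
#'
#' Convenience pipeline: [extract_rois()] followed by [quantify_roi()] on
#' each ROI.
#'
#' @inheritParams extract_rois
#' @inheritParams quantify_roi
#' @return Tibble with one row per detected signal (the [glance()] of each
#'   `quant_result`, plus `roi_id` and `y_apex`), with the full
#'   `quant_result` objects in a `results` attribute. Zero rows when nothing
#'   is detected.
#' @export
analyze_strip <- function(image, cwt_params = wavelet_params(),
                          det_config = detector_config(),
                          mode = c("auto", "strip", "dot"), row_scales = NULL) {
  rois <- extract_rois(image, cwt_params, det_config, mode)
  if (nrow(rois) == 0) {
    out <- tibble::tibble(
      roi_id = integer(), mode = character(), x_left = integer(),
      x_right = integer(), x_apex = integer(), top = integer(),
      down = integer(), y_apex = integer(), n_rows = integer(),
      n_detected = integer(), ave_pix = numeric(), rel_intensity = numeric(),
      volume = numeric(), sigma_hat = numeric()
    )
    attr(out, "results") <- list()
    return(out)
  }
  results <- lapply(seq_len(nrow(rois)), function(i) {
    quantify_roi(image, rois[i, ], cwt_params, det_config, row_scales = row_scales)
  })
  gl <- dplyr::bind_rows(lapply(results, glance))
  out <- dplyr::bind_cols(
    rois[, c("roi_id", "mode", "x_left", "x_right", "x_apex", "top", "down", "y_apex")],
    gl[, c("n_rows", "n_detected", "ave_pix", "rel_intensity", "volume", "sigma_hat")]
  )
  attr(out, "results") <- results
  out
}
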