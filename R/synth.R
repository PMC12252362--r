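#' Synthetic strip/dot-matrix scene specification
#'
#' Describes a synthetic filter-free fluorescence strip image: a dark
#' background elevated by a smooth stray-light gradient, transverse
#' Gaussian-profile bands (strip mode) and/or 2D Gaussian spots (dot-matrix
#' mode), additive Gaussian sensor noise and optional impulse (salt) noise,
#' quantized to 8 or 16 bits.
#'
#' @param shape `c(rows, cols)` of the image (default `c(200, 600)`).
#' @param background Named list/vector of stray-light model coefficients:
#'   `base` level plus `gx`, `gy` (linear gradient per pixel along columns /
#'   rows) and `gxx` (quadratic column term). Background at pixel (y, x) is
#'   `base + gx * (x - 1) + gy * (y - 1) + gxx * (x - 1)^2`.
#' @param bands `NULL` or a data frame with columns `center` (column of the
#'   band axis), `sigma` (transverse Gaussian width, px), `amplitude` (peak
#'   gray value above background) and optional `row_from`, `row_to`
#'   (default full height).
#' @param spots `NULL` or a data frame with columns `row`, `col`, `sigma`,
#'   `amplitude` for isotropic 2D Gaussian spots.
#' @param noise_sd Gaussian sensor noise standard deviation in gray levels.
#' @param impulse_frac Fraction of pixels replaced by saturated salt
#'   impulses (hot pixels), in `[0, 1]`.
#' @param bit_depth 8 or 16.
#' @param seed Integer seed making the generated image fully deterministic.
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(shape = c(200, 600),
                       background = c(base = 40, gx = 0.025, gy = 0.01, gxx = 0),
                       bands = NULL, spots = NULL,
                       noise_sd = 2, impulse_frac = 0,
                       bit_depth = 8, seed = 1L) {
  if (length(shape) != 2 || any(shape < 1)) {
    abort_config("`shape` must be c(rows, cols) with positive entries.")
  }
  shape <- as.integer(shape)
  bg <- c(base = 0, gx = 0, gy = 0, gxx = 0)
  bg[names(background)] <- unlist(background)
  if (!is.null(bands)) {
    bands <- tibble::as_tibble(bands)
    if (!all(c("center", "sigma", "amplitude") %in% names(bands))) {
      abort_config("`bands` needs columns center, sigma, amplitude.")
    }
    if (!"row_from" %in% names(bands)) bands$row_from <- 1L
    if (!"row_to" %in% names(bands)) bands$row_to <- shape[1]
    if (any(bands$amplitude < 0)) abort_config("band amplitudes must be >= 0.")
    if (any(bands$center < 1 | bands$center > shape[2])) {
      abort_config("band centers must lie inside the image.")
    }
    if (any(bands$sigma <= 0)) abort_config("band sigmas must be > 0.")
  }
  if (!is.null(spots)) {
    spots <- tibble::as_tibble(spots)
    if (!all(c("row", "col", "sigma", "amplitude") %in% names(spots))) {
      abort_config("`spots` needs columns row, col, sigma, amplitude.")
    }
    if (any(spots$amplitude < 0)) abort_config("spot amplitudes must be >= 0.")
    if (any(spots$row < 1 | spots$row > shape[1] |
            spots$col < 1 | spots$col > shape[2])) {
      abort_config("spot centers must lie inside the image.")
    }
    if (any(spots$sigma <= 0)) abort_config("spot sigmas must be > 0.")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) abort_config("`noise_sd` must be >= 0.")
  if (!is.numeric(impulse_frac) || impulse_frac < 0 || impulse_frac > 1) {
    abort_config("`impulse_frac` must lie in [0, 1].")
  }
  if (!bit_depth %in% c(8, 16)) abort_config("`bit_depth` must be 8 or 16.")
  structure(
    list(shape = shape, background = bg, bands = bands, spots = spots,
         noise_sd = noise_sd, impulse_frac = impulse_frac,
         bit_depth = as.integer(bit_depth), seed = as.integer(seed)),
    class = "scene_spec"
  )
}

#' Noise-free scene field
#'
#' The continuous pre-noise, pre-quantization scene model: background plus
#' the sum of all Gaussian signal profiles. Signals superpose linearly on
#' the shared background.
#'
#' @param spec A [scene_spec()].
#' @param component `"scene"` (background + signal), `"background"` or
#'   `"signal"`.
#' @return Numeric matrix `shape[1] x shape[2]`.
#' @export
scene_field <- function(spec, component = c("scene", "background", "signal")) {
  component <- match.arg(component)
  h <- spec$shape[1]; w <- spec$shape[2]
  xs <- seq_len(w) - 1
  ys <- seq_len(h) - 1
  bg <- spec$background
  background <- outer(ys, xs, function(y, x) {
    bg[["base"]] + bg[["gx"]] * x + bg[["gy"]] * y + bg[["gxx"]] * x^2
  })
  signal <- matrix(0, h, w)
  if (!is.null(spec$bands)) {
    for (i in seq_len(nrow(spec$bands))) {
      b <- spec$bands[i, ]
      prof <- b$amplitude * exp(-(seq_len(w) - b$center)^2 / (2 * b$sigma^2))
      rows <- max(1L, b$row_from):min(h, b$row_to)
      signal[rows, ] <- signal[rows, , drop = FALSE] +
        matrix(prof, length(rows), w, byrow = TRUE)
    }
  }
  if (!is.null(spec$spots)) {
    for (i in seq_len(nrow(spec$spots))) {
      s <- spec$spots[i, ]
      gx <- exp(-(seq_len(w) - s$col)^2 / (2 * s$sigma^2))
      gy <- exp(-(seq_len(h) - s$row)^2 / (2 * s$sigma^2))
      signal <- signal + s$amplitude * outer(gy, gx)
    }
  }
  switch(component,
    scene = background + signal,
    background = background,
    signal = signal
  )
}

# Mean of a unit-peak Gaussian over its +/- 3 sigma window:
# integral / (6 sigma) = sqrt(2 pi) * erf(3 / sqrt(2)) / 6, independent of sigma.
gaussian_window_mean <- function() {
  sqrt(2 * pi) * (2 * stats::pnorm(3) - 1) / 6
}

#' Generate a synthetic strip image with ground truth
#'
#' Renders the scene field, adds seeded Gaussian and impulse noise, clips to
#' `[0, max_gray]` and quantizes to the requested bit depth. The same spec
#' (including its seed) always produces a bit-identical image.
#'
#' @param spec A [scene_spec()].
#' @return A list with `image` (an [lfa_image]) and `truth`, a list holding
#'   `bands` / `spots` tibbles augmented with the analytic ground truth
#'   (true center, `left`/`right`/`top`/`bottom` boundaries at three sigmas,
#'   per-row integrated background-subtracted signal, analytic `ave_pix`
#'   over the three-sigma window, declared `snr`), a `saturated` flag (set
#'   when the noise-free scene already exceeds full scale) and the echoed
#'   `spec`.
#' @export
simulate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  max_gray <- 2^spec$bit_depth - 1
  field <- scene_field(spec, "scene")
  saturated <- any(field > max_gray)
  img <- withr::with_seed(spec$seed, {
    noisy <- field
    if (spec$noise_sd > 0) {
      noisy <- noisy + stats::rnorm(length(field), sd = spec$noise_sd)
    }
    if (spec$impulse_frac > 0) {
      n_imp <- round(spec$impulse_frac * length(field))
      if (n_imp > 0) {
        idx <- sample.int(length(field), n_imp)
        noisy[idx] <- max_gray
      }
    }
    noisy
  })
  data <- pmin(pmax(round(img), 0), max_gray)
  image <- lfa_image(data, max_gray = max_gray, channel_policy = "synthetic")

  kmean <- gaussian_window_mean()
  bands <- NULL
  if (!is.null(spec$bands)) {
    bands <- dplyr::mutate(
      spec$bands,
      left = .data$center - 3 * .data$sigma,
      right = .data$center + 3 * .data$sigma,
      row_integral = .data$amplitude * .data$sigma * sqrt(2 * pi) * (2 * stats::pnorm(3) - 1),
      ave_pix = .data$amplitude * kmean,
      snr = if (spec$noise_sd > 0) .data$amplitude / spec$noise_sd else Inf
    )
  }
  spots <- NULL
  if (!is.null(spec$spots)) {
    erf3 <- 2 * stats::pnorm(3) - 1
    spots <- dplyr::mutate(
      spec$spots,
      left = .data$col - 3 * .data$sigma,
      right = .data$col + 3 * .data$sigma,
      top = .data$row - 3 * .data$sigma,
      bottom = .data$row + 3 * .data$sigma,
      # total 2D Gaussian mass over the 3-sigma box / box pixel count
      ave_pix = .data$amplitude * 2 * pi * erf3^2 / 36,
      snr = if (spec$noise_sd > 0) .data$amplitude / spec$noise_sd else Inf
    )
  }
  list(
    image = image,
    truth = list(bands = bands, spots = spots, saturated = saturated, spec = spec)
  )
}

# Scene geometries used by the synthetic evaluation suites: band centers sit
# on evenly spaced anchors with a bounded jitter so slabs stay separated and
# clear of the boundary cone of influence, matching strip margins.
suite_band_centers <- function(n_bands, w) {
  if (n_bands == 1) {
    stats::runif(1, 0.25 * w, 0.75 * w)
  } else if (n_bands == 2) {
    c(w / 3, 2 * w / 3) + stats::runif(2, -0.05 * w, 0.05 * w)
  } else {
    c(0.25 * w, 0.5 * w, 0.75 * w) + stats::runif(3, -0.025 * w, 0.025 * w)
  }
}

#' Seeded suite of weak-signal synthetic strip scenes
#'
#' Generates the scene specifications for an algorithm-accuracy evaluation:
#' `n_scenes` random strip geometries (1-3 full-height transverse Gaussian
#' bands of width sigma 18-28 px on a gradient background), each rendered
#' `n_replicates` times with independent noise, with band peak contrast
#' drawn uniformly from `snr_range` times the noise standard deviation.
#' Everything is reproducible from `seed`.
#'
#' @param n_scenes Number of distinct scene geometries (>= 1).
#' @param n_replicates Noise replicates per scene.
#' @param snr_range Band peak contrast range, in multiples of `noise_sd`;
#'   both ends must be > 0. Default 2-4 (the weak-signal regime where bands
#'   are barely visible).
#' @param seed Integer master seed.
#' @param shape,noise_sd,impulse_frac,background,bit_depth Passed to
#'   [scene_spec()]; defaults give 200 x 600 8-bit strips with Gaussian
#'   noise sd 2.
#' @return Tibble with one row per image: `scene`, `replicate`, `n_bands`,
#'   `snr` (per-scene contrast multiplier) and a `spec` list-column of
#'   [scene_spec()] objects. Render any row with [simulate_scene()].
#' @export
weak_signal_suite <- function(n_scenes = 50, n_replicates = 5,
                              snr_range = c(2, 4), seed = 1,
                              shape = c(200, 600), noise_sd = 2,
                              impulse_frac = 0,
                              background = c(base = 40, gx = 0.025, gy = 0.01, gxx = 0),
                              bit_depth = 8) {
  if (n_scenes < 1) abort_config("`n_scenes` must be >= 1.")
  if (n_replicates < 1) abort_config("`n_replicates` must be >= 1.")
  if (length(snr_range) != 2 || any(snr_range <= 0) || snr_range[1] > snr_range[2]) {
    abort_config("`snr_range` must be two positive values, low <= high.")
  }
  if (noise_sd <= 0) abort_config("suite generation requires `noise_sd` > 0.")
  w <- shape[2]
  withr::with_seed(as.integer(seed), {
    rows <- list()
    for (sc in seq_len(n_scenes)) {
      n_bands <- sample(1:3, 1)
      centers <- suite_band_centers(n_bands, w)
      sigmas <- stats::runif(n_bands, 18, 28)
      contrast <- stats::runif(1, snr_range[1], snr_range[2])
      bands <- tibble::tibble(
        center = centers, sigma = sigmas,
        amplitude = contrast * noise_sd
      )
      sub_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)
      for (rep in seq_len(n_replicates)) {
        spec <- scene_spec(
          shape = shape, background = background, bands = bands,
          noise_sd = noise_sd, impulse_frac = impulse_frac,
          bit_depth = bit_depth, seed = sub_seeds[rep]
        )
        rows[[length(rows) + 1]] <- tibble::tibble(
          scene = sc, replicate = rep, n_bands = n_bands,
          snr = contrast, spec = list(spec)
        )
      }
    }
    dplyr::bind_rows(rows)
  })
}
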