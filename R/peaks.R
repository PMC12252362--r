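#' Peak detector configuration
#'
#' @param n Half-width of the derivative interval, in samples (default 2;
#'   smooths single-sample jitter on the wavelet curve).
#' @param mu Minimum trough separation for a peak to count as a real signal
#'   (default 32 samples): a peak is valid only when
#'   `j_right - j_left > mu`, which rejects narrow spurious spikes.
#' @param min_prominence Minimum apex height above the trough baseline, in
#'   detection-curve units (default 0 = disabled).
#' @param min_snr Minimum ratio of apex prominence to the estimated noise
#'   standard deviation of the detection curve (default 4). Set to 0 to
#'   disable. This rejects smooth noise undulations, which the
#'   trough-separation rule alone cannot (noise filtered at scale `s` has
#'   trough separations of order `2 * sqrt(3) * s`).
#' @param exclude_boundary Drop apexes inside the boundary cone of influence
#'   (within half a kernel support of either curve end), where boundary
#'   extension makes coefficients unreliable (default `TRUE`).
#' @return A list of class `detector_config`.
#' @export
detector_config <- function(n = 2, mu = 32, min_prominence = 0, min_snr = 4,
                            exclude_boundary = TRUE) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    abort_config("`n` must be a single number >= 1.")
  }
  if (!is.numeric(mu) || length(mu) != 1 || mu < 1) {
    abort_config("`mu` must be a single number >= 1.")
  }
  if (!is.numeric(min_prominence) || length(min_prominence) != 1 || min_prominence < 0) {
    abort_config("`min_prominence` must be a single number >= 0.")
  }
  if (!is.numeric(min_snr) || length(min_snr) != 1 || min_snr < 0) {
    abort_config("`min_snr` must be a single number >= 0.")
  }
  structure(
    list(n = as.integer(n), mu = mu, min_prominence = min_prominence,
         min_snr = min_snr, exclude_boundary = isTRUE(exclude_boundary)),
    class = "detector_config"
  )
}

#' Symmetric first derivative of a curve
#'
#' Computes `W'_j = (W_{j+n} - W_{j-n}) / (2n + 1)` for
#' `j in [n+1, w-n]` (1-based). The `2n + 1` denominator is kept as such;
#' only the zero-crossing positions matter downstream and those are
#' denominator-invariant.
#'
#' @param curve Numeric vector (or curve object accepted by [cwt()]).
#' @param n Half-width of the derivative interval.
#' @return Numeric vector of the same length with `NA` outside the valid
#'   range.
#' @export
first_derivative <- function(curve, n = 2) {
  x <- curve_values(curve)
  w <- length(x)
  n <- as.integer(n)
  if (n < 1) abort_config("`n` must be >= 1.")
  if (w <= 2 * n) {
    abort_processing(sprintf("curve too short for derivative half-width n = %d (length %d).", n, w))
  }
  d <- rep(NA_real_, w)
  j <- (n + 1):(w - n)
  d[j] <- (x[j + n] - x[j - n]) / (2 * n + 1)
  d
}

# Sign-change crossings of the derivative. `from_pos = TRUE` finds + -> -
# crossings (apexes), FALSE finds - -> + crossings (troughs). Returns the
# representative sample of each crossing: the extremum of `x` over the
# crossing interval, with flat plateaus reporting their center sample
# (left-biased for even plateaus).
derivative_crossings <- function(x, d, from_pos) {
  valid <- which(!is.na(d))
  s <- sign(d[valid])
  nz <- which(s != 0)
  out <- integer(0)
  if (length(nz) < 2) return(out)
  prev <- nz[1]
  for (k in 2:length(nz)) {
    cur <- nz[k]
    hit <- if (from_pos) s[prev] > 0 && s[cur] < 0 else s[prev] < 0 && s[cur] > 0
    if (hit) {
      lo <- valid[prev]
      hi <- valid[cur]
      seg <- x[lo:hi]
      m <- if (from_pos) which(seg == max(seg)) else which(seg == min(seg))
      out <- c(out, lo + m[ceiling(length(m) / 2)] - 1L)
    }
    prev <- cur
  }
  out
}

#' Locate peak apexes on a detection curve
#'
#' Apexes are the positions where the symmetric first derivative crosses
#' from positive to negative; a flat apex plateau reports its center sample.
#' Apexes inside the boundary cone of influence are dropped when the curve
#' is a [cwt()] result and `config$exclude_boundary` is `TRUE`.
#'
#' @param curve Detection curve ([cwt()] result or numeric vector).
#' @param config [detector_config()].
#' @return Integer vector of apex indices (1-based, left to right; may be
#'   empty).
#' @export
find_apexes <- function(curve, config = detector_config()) {
  x <- curve_values(curve)
  d <- first_derivative(x, config$n)
  apexes <- derivative_crossings(x, d, from_pos = TRUE)
  h <- attr(curve, "half_support")
  if (config$exclude_boundary && !is.null(h)) {
    apexes <- apexes[apexes > h & apexes <= length(x) - h]
  }
  apexes
}

# Core single-peak delimitation; returns a plain list (fast path for
# per-scan-line use). `troughs` may be precomputed.
delimit_one <- function(x, ref, apex, config, troughs = NULL, noise_sd = 0) {
  w <- length(x)
  if (is.null(troughs)) {
    d <- first_derivative(x, config$n)
    troughs <- derivative_crossings(x, d, from_pos = FALSE)
  }
  lefts <- troughs[troughs < apex]
  rights <- troughs[troughs > apex]
  j_left <- if (length(lefts)) max(lefts) else 1L   # curve ends serve as
  j_right <- if (length(rights)) min(rights) else w # fallback troughs
  baseval <- (ref[j_left] + ref[j_right]) / 2
  # height above the HIGHER flanking trough: a flat stretch next to a deep
  # side lobe must not count as prominent
  prominence <- x[apex] - max(x[j_left], x[j_right])
  sep <- j_right - j_left
  floor_eps <- 1e-8 * max(abs(x)) # reject numerical ripple on flat curves
  # the SNR rule tests both the prominence and the apex value itself: on a
  # zero-mean wavelet curve a real band apex is strongly positive, whereas
  # small bumps riding beside a deep side lobe inherit a large prominence
  # from the lobe while staying near zero
  snr_ok <- config$min_snr <= 0 || noise_sd <= 0 ||
    (prominence >= config$min_snr * noise_sd && x[apex] >= config$min_snr * noise_sd)
  valid <- sep > config$mu &&
    prominence > floor_eps &&
    prominence >= config$min_prominence &&
    snr_ok
  list(
    apex = as.integer(apex), j_left = as.integer(j_left),
    j_right = as.integer(j_right), sep = as.integer(sep),
    baseval = baseval, amplitude = x[apex] - baseval,
    prominence = prominence, valid = valid
  )
}

#' Delimit and validate one detected peak
#'
#' Traces back from the apex to the nearest flanking troughs (derivative
#' negative-to-positive crossings; the curve ends act as troughs when no
#' interior trough exists on one side), computes the baseline as the mean of
#' the reference-curve values at the two troughs,
#' `baseval = (ref(j_left) + ref(j_right)) / 2`, and marks the peak valid
#' when `j_right - j_left > mu` (and the prominence criteria of
#' [detector_config()] hold).
#'
#' @param curve Detection curve (where troughs are traced).
#' @param ref Reference curve for baseline values (defaults to `curve`);
#'   trough positions always come from `curve`, baseline values are read from
#'   `ref` — the curve being quantified.
#' @param apex Apex index (from [find_apexes()]).
#' @param config [detector_config()].
#' @return One-row tibble with columns `apex`, `j_left`, `j_right`, `sep`,
#'   `baseval`, `amplitude` (curve value at apex minus `baseval`),
#'   `prominence` (apex height of `curve` above its higher flanking trough)
#'   and `valid`.
#' @export
delimit_peak <- function(curve, ref = NULL, apex, config = detector_config()) {
  x <- curve_values(curve)
  r <- if (is.null(ref)) x else curve_values(ref)
  if (length(r) != length(x)) {
    abort_config("`ref` must have the same length as `curve`.")
  }
  noise_sd <- attr(curve, "noise_sd")
  if (is.null(noise_sd)) noise_sd <- 0
  tibble::as_tibble(delimit_one(x, r, apex, config, noise_sd = noise_sd))
}

#' Find, delimit and validate all peaks on a detection curve
#'
#' Runs [find_apexes()] and [delimit_peak()] over a whole curve.
#'
#' @inheritParams delimit_peak
#' @param noise_sd Noise standard deviation of the detection curve used for
#'   the `min_snr` rule; defaults to the `noise_sd` attribute of a [cwt()]
#'   result, or 0 (rule disabled) for plain vectors.
#' @return Tibble with one row per apex (see [delimit_peak()] for columns);
#'   zero rows when no apex exists.
#' @export
find_peaks <- function(curve, ref = NULL, config = detector_config(),
                       noise_sd = NULL) {
  x <- curve_values(curve)
  r <- if (is.null(ref)) x else curve_values(ref)
  if (length(r) != length(x)) {
    abort_config("`ref` must have the same length as `curve`.")
  }
  if (is.null(noise_sd)) {
    noise_sd <- attr(curve, "noise_sd")
    if (is.null(noise_sd)) noise_sd <- 0
  }
  d <- first_derivative(x, config$n)
  apexes <- derivative_crossings(x, d, from_pos = TRUE)
  h <- attr(curve, "half_support")
  if (config$exclude_boundary && !is.null(h)) {
    apexes <- apexes[apexes > h & apexes <= length(x) - h]
  }
  troughs <- derivative_crossings(x, d, from_pos = FALSE)
  rows <- lapply(apexes, function(a) {
    delimit_one(x, r, a, config, troughs = troughs, noise_sd = noise_sd)
  })
  if (!length(rows)) {
    return(tibble::tibble(
      apex = integer(), j_left = integer(), j_right = integer(),
      sep = integer(), baseval = numeric(), amplitude = numeric(),
      prominence = numeric(), valid = logical()
    ))
  }
  dplyr::bind_rows(lapply(rows, tibble::as_tibble))
}
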