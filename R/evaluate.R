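# One-to-one greedy matching of detected positions to true positions by
# distance; returns number matched within tolerance.
match_positions <- function(truth, detected, tolerance) {
  if (!length(truth) || !length(detected)) return(0L)
  pairs <- expand.grid(t = seq_along(truth), d = seq_along(detected))
  pairs$dist <- abs(truth[pairs$t] - detected[pairs$d])
  pairs <- pairs[order(pairs$dist), , drop = FALSE]
  used_t <- logical(length(truth)); used_d <- logical(length(detected))
  n <- 0L
  for (k in seq_len(nrow(pairs))) {
    if (pairs$dist[k] > tolerance) break
    ti <- pairs$t[k]; di <- pairs$d[k]
    if (!used_t[ti] && !used_d[di]) {
      used_t[ti] <- TRUE; used_d[di] <- TRUE
      n <- n + 1L
    }
  }
  n
}

#' Score detection accuracy on a synthetic suite
#'
#' Renders every scene of a [weak_signal_suite()] tibble, runs the ROI
#' extraction pipeline, and scores each image as correct when every true
#' band is matched by a detected valid peak within `tolerance` pixels
#' (one-to-one greedy matching by distance) and no spurious valid peak is
#' reported.
#'
#' @param suite Tibble from [weak_signal_suite()] (or any tibble with a
#'   `spec` list-column of [scene_spec()] objects).
#' @param tolerance Localization tolerance in pixels (default 5).
#' @param cwt_params,det_config Pipeline settings.
#' @param mode Passed to [extract_rois()].
#' @return A list with `accuracy` (fraction of correct images), `n_images`,
#'   and `per_image`, a tibble with one row per image (`scene`, `replicate`,
#'   `n_true`, `n_detected`, `n_matched`, `correct`).
#' @export
run_eval <- function(suite, tolerance = 5,
                     cwt_params = wavelet_params(),
                     det_config = detector_config(),
                     mode = "auto") {
  if (!is.data.frame(suite) || !"spec" %in% names(suite)) {
    abort_config("`suite` must be a tibble with a `spec` list-column (see weak_signal_suite()).")
  }
  n_img <- nrow(suite)
  res <- vector("list", n_img)
  for (i in seq_len(n_img)) {
    spec <- suite$spec[[i]]
    sim <- simulate_scene(spec)
    truth <- sim$truth
    if (is.null(truth$bands) && is.null(truth$spots)) {
      abort_config("suite rows must carry ground truth (bands or spots) in their specs.")
    }
    # zero-amplitude entries are negative controls: nothing to find
    true_x <- c(
      if (!is.null(truth$bands)) truth$bands$center[truth$bands$amplitude > 0],
      if (!is.null(truth$spots)) unique(truth$spots$col[truth$spots$amplitude > 0])
    )
    rois <- extract_rois(sim$image, cwt_params, det_config, mode = mode)
    detected_x <- rois$x_apex
    n_matched <- match_positions(true_x, detected_x, tolerance)
    res[[i]] <- tibble::tibble(
      scene = if ("scene" %in% names(suite)) suite$scene[i] else i,
      replicate = if ("replicate" %in% names(suite)) suite$replicate[i] else 1L,
      n_true = length(true_x),
      n_detected = length(detected_x),
      n_matched = n_matched,
      correct = n_matched == length(true_x) && length(detected_x) == length(true_x)
    )
  }
  per_image <- dplyr::bind_rows(res)
  list(
    accuracy = mean(per_image$correct),
    n_images = n_img,
    per_image = per_image
  )
}
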