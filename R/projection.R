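#' Directional projection curve
#'
#' Collapses a 2D image (or an inclusive sub-rectangle of it) into a 1D
#' profile by summing gray values along one axis:
#' `Y_j = sum_i y_ij`. Projections are raw sums, not means — downstream
#' trough-separation thresholds are positional, so the overall scale of the
#' curve is harmless, and raw sums keep integer inputs exact.
#'
#' @param image An [lfa_image].
#' @param axis `"collapse_rows"` sums over rows, giving one value per column
#'   (length `w`); `"collapse_cols"` sums over columns, giving one value per
#'   row (length `h`).
#' @param bounds Optional inclusive sub-rectangle `c(top, down, left, right)`
#'   (1-based row/column bounds). `NULL` uses the whole image.
#'
#' @return A tibble of class `projection_curve` with columns `index` (position
#'   in full-image coordinates along the kept axis) and `value`, plus
#'   attributes `axis`, `origin` (index of the first sample in the source
#'   image), `collapsed_n` (number of summed pixels per sample) and
#'   `max_gray`.
#' @export
project_profile <- function(image, axis = c("collapse_rows", "collapse_cols"),
                            bounds = NULL) {
  stopifnot(inherits(image, "lfa_image"))
  axis <- match.arg(axis)
  h <- nrow(image$data)
  w <- ncol(image$data)
  if (is.null(bounds)) {
    bounds <- c(1L, h, 1L, w)
  }
  if (length(bounds) != 4 || any(!is.finite(bounds))) {
    abort_config("`bounds` must be c(top, down, left, right).")
  }
  bounds <- as.integer(bounds)
  top <- bounds[1]; down <- bounds[2]; left <- bounds[3]; right <- bounds[4]
  if (top < 1 || down > h || left < 1 || right > w) {
    abort_config("`bounds` must lie inside the image.")
  }
  if (top > down || left > right) {
    abort_config("empty `bounds`: need top <= down and left <= right.")
  }
  sub <- image$data[top:down, left:right, drop = FALSE]
  if (axis == "collapse_rows") {
    values <- colSums(sub)
    origin <- left
    collapsed_n <- down - top + 1L
  } else {
    values <- rowSums(sub)
    origin <- top
    collapsed_n <- right - left + 1L
  }
  out <- tibble::tibble(index = origin + seq_along(values) - 1L, value = values)
  structure(
    out,
    axis = axis, origin = origin, collapsed_n = collapsed_n,
    max_gray = image$max_gray,
    class = c("projection_curve", class(out))
  )
}

# Pull the numeric values out of whatever curve representation we were given.
curve_values <- function(curve) {
  if (is.numeric(curve)) {
    as.numeric(curve)
  } else if (inherits(curve, "projection_curve") || inherits(curve, "cwt_result")) {
    as.numeric(curve$value)
  } else if (is.data.frame(curve) && "value" %in% names(curve)) {
    as.numeric(curve$value)
  } else {
    abort_config("expected a numeric vector, projection_curve or cwt_result.")
  }
}
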