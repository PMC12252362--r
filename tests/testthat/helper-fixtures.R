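# Shared fixtures and independent oracles, built in code at test time.

# Independent brute-force CWT oracle: O(N * K) direct convolution of the
# boundary-extended curve with each balanced kernel, written against the
# package's exported contract but via its own loop.
naive_cwt <- function(x, params = wavelet_params()) {
  h <- floor(params$support_len / 2)
  n <- length(x)
  per_scale <- matrix(NA_real_, length(params$scales), n)
  for (si in seq_along(params$scales)) {
    s <- params$scales[si]
    t <- seq.int(-h, h)
    k <- (1 - t^2 / s^2) * exp(-t^2 / (2 * s^2)) / sqrt(s)
    g <- exp(-t^2 / (2 * s^2))
    k <- k - (sum(k) / sum(g)) * g
    # boundary extension by explicit triangle-wave folding
    idx <- vapply(seq.int(1 - h, n + h), function(gp) {
      if (n == 1) return(1L)
      m <- (gp - 1) %% (2 * n - 2)
      if (m < n) as.integer(m + 1) else as.integer(2 * n - 1 - m)
    }, integer(1))
    xe <- x[idx]
    for (i in seq_len(n)) {
      per_scale[si, i] <- sum(k * xe[i:(i + 2 * h)])
    }
  }
  list(per_scale = per_scale, combined = colMeans(per_scale))
}

# A smooth single-bump test curve.
gaussian_curve <- function(n = 400, center = 200, sigma = 12, amplitude = 100,
                           offset = 0) {
  offset + amplitude * exp(-((seq_len(n)) - center)^2 / (2 * sigma^2))
}

# Canonical noise-free single-band strip scene.
band_scene <- function(center = 300, sigma = 20, amplitude = 50, noise_sd = 0,
                       seed = 1, shape = c(200, 600)) {
  scene_spec(
    shape = shape,
    bands = data.frame(center = center, sigma = sigma, amplitude = amplitude),
    noise_sd = noise_sd, seed = seed
  )
}

# Write an lfa_image matrix (or array) to a temporary PNG and return the path.
tmp_png <- function(data, max_gray = 255) {
  path <- tempfile(fileext = ".png")
  png::writePNG(data / max_gray, target = path)
  path
}
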