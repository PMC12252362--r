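test_that("first derivative follows the printed formula", {
  expect_equal(
    unique(stats::na.omit(first_derivative(rep(7, 50), n = 2))), 0
  )
  # linear ramp W_j = 3j with n = 1: (3(j+1) - 3(j-1)) / 3 = 2
  d <- first_derivative(3 * (1:60), n = 1)
  expect_equal(unique(stats::na.omit(d)), 2)
  expect_true(all(is.na(d[c(1, 60)])))
  # the valid range is [n+1, w-n]
  d2 <- first_derivative(1:20, n = 3)
  expect_true(all(is.na(d2[1:3])) && all(is.na(d2[18:20])))
  expect_error(first_derivative(1:4, n = 2), class = "flfa_error_processing")
})

test_that("derivative sign changes bracket a sampled Gaussian apex", {
  x <- gaussian_curve(n = 200, center = 77, sigma = 9, amplitude = 10)
  cfg <- detector_config()
  # brute-force oracle: global argmax
  expect_lte(abs(find_apexes(x, cfg) - which.max(x)), 1)
})

test_that("apex finding handles monotone, multi-peak and mirrored curves", {
  cfg <- detector_config()
  expect_length(find_apexes(seq(0, 10, length.out = 100), cfg), 0)
  expect_length(find_apexes(seq(10, 0, length.out = 100), cfg), 0)

  two <- gaussian_curve(400, 120, 10, 50) + gaussian_curve(400, 300, 10, 80)
  ap <- find_apexes(two, cfg)
  expect_length(ap, 2)
  expect_lte(max(abs(ap - c(120, 300))), 1)

  mir <- rev(two)
  expect_equal(sort(401 - find_apexes(mir, cfg)), sort(ap))
})

test_that("flat apex plateaus report their center sample", {
  x <- c(rep(0, 20), 1:5, rep(5, 4), 5:1, rep(0, 20))
  ap <- find_apexes(x, detector_config(n = 1))
  expect_length(ap, 1)
  # plateau spans indices 25..29 after the rise; center sample
  expect_equal(x[ap], 5)
  expect_equal(ap, 27)
})

test_that("peak delimitation computes the trough baseline and the mu rule", {
  # curve with troughs exactly at 100 and 131 (separation 31)
  mk <- function(right) {
    v <- numeric(260)
    v[1:100] <- seq(5, 0, length.out = 100)
    up <- 100:floor((100 + right) / 2)
    v[up] <- seq(0, 15, length.out = length(up))
    dn <- floor((100 + right) / 2):right
    v[dn] <- seq(15, 0, length.out = length(dn))
    v[right:260] <- seq(0, 5, length.out = 260 - right + 1)
    v
  }
  cfg <- detector_config(n = 1, min_snr = 0)
  v31 <- mk(131)
  apex <- find_apexes(v31, cfg)
  pk <- delimit_peak(v31, apex = apex, config = cfg)
  expect_equal(pk$j_left, 100)
  expect_equal(pk$j_right, 131)
  expect_false(pk$valid) # separation 31 is not > mu = 32

  v40 <- mk(140)
  pk40 <- delimit_peak(v40, apex = find_apexes(v40, cfg), config = cfg)
  expect_equal(pk40$sep, 40)
  expect_true(pk40$valid) # separation 40 > mu = 32

  # Eq. 5 arithmetic on a reference curve: baseval = (ref(jl) + ref(jr)) / 2
  ref <- seq_along(v40) * 0
  ref[pk40$j_left] <- 10
  ref[pk40$j_right] <- 20
  pk_ref <- delimit_peak(v40, ref = ref, apex = find_apexes(v40, cfg), config = cfg)
  expect_equal(pk_ref$baseval, 15)
  expect_equal(pk_ref$amplitude, v40[pk_ref$apex] - 15)
})

test_that("every returned peak satisfies the type invariants", {
  set.seed(3)
  cfg <- detector_config(min_snr = 0)
  for (rep in 1:20) {
    x <- as.numeric(stats::filter(rnorm(300), rep(1 / 15, 15), circular = TRUE))
    pks <- find_peaks(x, config = cfg)
    if (nrow(pks) == 0) next
    expect_true(all(pks$j_left < pks$apex & pks$apex < pks$j_right))
    expect_equal(pks$valid & (pks$sep > cfg$mu), pks$valid)
    expect_equal(pks$baseval, (x[pks$j_left] + x[pks$j_right]) / 2)
  }
})

test_that("apex and trough indices shift with the input", {
  # the wavelet response of a band has interior flanking troughs (side
  # lobes), so all three indices must track a 40-sample input shift
  cfg <- detector_config()
  cx <- cwt(gaussian_curve(500, 200, 14, 60))
  cy <- cwt(gaussian_curve(500, 240, 14, 60))
  px <- find_peaks(cx, config = cfg)
  py <- find_peaks(cy, config = cfg)
  px <- px[px$valid, ]
  py <- py[py$valid, ]
  expect_equal(nrow(px), 1)
  expect_equal(py$apex, px$apex + 40)
  expect_equal(py$j_left, px$j_left + 40)
  expect_equal(py$j_right, px$j_right + 40)
})

test_that("narrow spikes are never valid and noise-free bands localize", {
  cfg <- detector_config()
  # impulse-noise fixture: spikes of width << mu on a flat background
  x <- rep(10, 400)
  x[c(50, 180, 307)] <- c(200, 150, 400)
  pks <- find_peaks(x, config = cfg)
  expect_false(any(pks$valid[pks$sep <= cfg$mu]))
  # a genuine wide peak among spikes stays valid on the transformed curve
  sim <- simulate_scene(band_scene(center = 250, sigma = 20, amplitude = 40))
  px <- project_profile(sim$image, "collapse_rows")
  pk <- find_peaks(cwt(px), ref = px, config = cfg)
  pk <- pk[pk$valid, ]
  expect_equal(nrow(pk), 1)
  expect_lte(abs(pk$apex - 250), 1)
})
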