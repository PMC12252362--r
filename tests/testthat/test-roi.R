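test_that("blank and noise-only images yield no regions", {
  expect_equal(nrow(extract_rois(simulate_scene(scene_spec(noise_sd = 0))$image)), 0)
  for (s in 1:5) {
    sim <- simulate_scene(scene_spec(noise_sd = 2, seed = s))
    expect_equal(nrow(extract_rois(sim$image)), 0)
  }
})

test_that("a two-band strip gives two full-height strip regions", {
  sp <- scene_spec(
    bands = data.frame(center = c(200, 400), sigma = c(20, 24), amplitude = c(30, 50)),
    noise_sd = 2, seed = 5
  )
  sim <- simulate_scene(sp)
  rois <- extract_rois(sim$image)
  expect_equal(nrow(rois), 2)
  expect_true(all(rois$mode == "strip"))
  expect_equal(rois$top, c(1L, 1L))
  expect_equal(rois$down, c(200L, 200L))
  expect_lte(max(abs(sort(rois$x_apex) - c(200, 400))), 2)
  expect_true(all(rois$x_left < rois$x_apex & rois$x_apex < rois$x_right))
})

test_that("a 2x3 dot-matrix grid gives six spot regions at the true centers", {
  spots <- expand.grid(row = c(140, 260), col = c(150, 300, 450))
  sp <- scene_spec(
    shape = c(400, 600),
    spots = data.frame(spots, sigma = 16, amplitude = 40),
    noise_sd = 2, seed = 4
  )
  sim <- simulate_scene(sp)
  rois <- extract_rois(sim$image)
  expect_equal(nrow(rois), 6)
  expect_true(all(rois$mode == "spot"))
  found <- rois[order(rois$x_apex, rois$y_apex), ]
  truth <- spots[order(spots$col, spots$row), ]
  expect_lte(max(abs(found$x_apex - truth$col)), 2)
  expect_lte(max(abs(found$y_apex - truth$row)), 2)
})

test_that("row aggregation reproduces the quantification arithmetic", {
  # one detected row with f = (0, 3, 6, 3, 0), troughs at the ends,
  # zero baseline: area 12 over width 4 -> 3 per pixel
  f <- c(0, 3, 6, 3, 0)
  area <- sum(f - 0)
  width <- 5 - 1
  expect_equal(area / width, 3)
  # the same arithmetic through the scan-line machinery
  sim <- simulate_scene(band_scene(center = 160, sigma = 12, amplitude = 60,
                                   shape = c(40, 320)))
  q <- quantify_roi(sim$image, extract_rois(sim$image, mode = "strip")[1, ])
  rows <- q$rows[q$rows$detected, ]
  manual <- vapply(seq_len(nrow(rows)), function(i) {
    f <- sim$image$data[rows$y[i], rows$dp_l[i]:rows$dp_r[i]]
    sum(f - rows$baseval[i])
  }, numeric(1))
  expect_equal(rows$area, manual)
  expect_equal(q$volume, sum(rows$area))
  expect_equal(q$ave_pix, sum(rows$area) / sum(rows$width))
  expect_equal(q$rel_intensity, q$ave_pix / 255)
})

test_that("avePix matches the analytic band mean within five percent", {
  for (sig in c(6, 12, 24)) {
    sim <- simulate_scene(band_scene(sigma = sig, amplitude = 50))
    rois <- extract_rois(sim$image, mode = "strip")
    expect_equal(nrow(rois), 1)
    q <- quantify_roi(sim$image, rois[1, ])
    expect_lt(abs(q$ave_pix / sim$truth$bands$ave_pix - 1), 0.05)
    expect_equal(sum(q$rows$detected), 200)
  }
})

test_that("avePix is offset-invariant and linear in band amplitude", {
  mk <- function(base, A) {
    sim <- simulate_scene(scene_spec(
      bands = data.frame(center = 300, sigma = 20, amplitude = A),
      background = c(base = base, gx = 0.025, gy = 0.01, gxx = 0),
      noise_sd = 0
    ))
    quantify_roi(sim$image, extract_rois(sim$image, mode = "strip")[1, ])$ave_pix
  }
  # constant offset on the whole scene changes nothing (to quantization)
  expect_equal(mk(40, 40), mk(90, 40), tolerance = 0.01)
  # linear in amplitude within 2% over a 10x range
  amps <- c(10, 20, 50, 100)
  ratio <- vapply(amps, function(A) mk(40, A), numeric(1)) / amps
  expect_lt(max(ratio) / min(ratio) - 1, 0.02)
})

test_that("amplitude doubling strictly increases avePix", {
  q1 <- {
    sim <- simulate_scene(band_scene(amplitude = 25))
    quantify_roi(sim$image, extract_rois(sim$image, mode = "strip")[1, ])
  }
  q2 <- {
    sim <- simulate_scene(band_scene(amplitude = 50))
    quantify_roi(sim$image, extract_rois(sim$image, mode = "strip")[1, ])
  }
  expect_gt(q2$ave_pix, q1$ave_pix)
})

test_that("rows without a valid peak contribute neither area nor width", {
  sim <- simulate_scene(scene_spec(
    bands = data.frame(center = 300, sigma = 18, amplitude = 40,
                       row_from = 60, row_to = 140),
    noise_sd = 2, seed = 8
  ))
  roi <- tibble::tibble(x_left = 240, x_right = 360, top = 1, down = 200)
  q <- quantify_roi(sim$image, roi)
  det <- q$rows$detected
  expect_true(any(!det))
  expect_true(all(is.na(q$rows$area[!det])))
  expect_equal(q$volume, sum(q$rows$area[det]))
  expect_equal(q$ave_pix * sum(q$rows$width[det]), q$volume, tolerance = 1e-12)
  # detected rows sit inside the band's row extent (within scan jitter)
  expect_gt(mean(q$rows$y[det] >= 55 & q$rows$y[det] <= 145), 0.9)
})

test_that("degenerate regions are rejected", {
  sim <- simulate_scene(band_scene())
  expect_error(
    quantify_roi(sim$image, tibble::tibble(x_left = 10, x_right = 10, top = 5, down = 5)),
    class = "flfa_error_config"
  )
  expect_error(
    quantify_roi(sim$image, tibble::tibble(x_left = 10, x_right = 13, top = 1, down = 200)),
    class = "flfa_error_processing"
  )
  expect_error(
    quantify_roi(sim$image, tibble::tibble(x_left = 500, x_right = 700, top = 1, down = 200)),
    class = "flfa_error_config"
  )
})

test_that("analyze_strip binds per-signal summaries with quant results", {
  sp <- scene_spec(
    bands = data.frame(center = c(200, 400), sigma = 22, amplitude = c(20, 45)),
    noise_sd = 2, seed = 12
  )
  sim <- simulate_scene(sp)
  res <- analyze_strip(sim$image)
  expect_equal(nrow(res), 2)
  expect_true(all(c("roi_id", "ave_pix", "rel_intensity", "volume") %in% names(res)))
  # stronger band quantifies higher
  expect_gt(res$ave_pix[res$x_apex > 300], res$ave_pix[res$x_apex < 300])
  qr <- attr(res, "results")
  expect_length(qr, 2)
  expect_s3_class(tidy(qr[[1]]), "tbl_df")
  expect_equal(glance(qr[[1]])$ave_pix, res$ave_pix[1])
})
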