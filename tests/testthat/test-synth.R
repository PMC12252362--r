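test_that("generation is bit-identical for the same spec and seed", {
  sp <- scene_spec(bands = data.frame(center = 300, sigma = 20, amplitude = 6),
                   noise_sd = 2, impulse_frac = 0.01, seed = 99)
  a <- simulate_scene(sp)
  b <- simulate_scene(sp)
  expect_identical(a$image$data, b$image$data)
  # a different seed gives a different noise realization
  sp2 <- scene_spec(bands = sp$bands, noise_sd = 2, impulse_frac = 0.01, seed = 100)
  expect_false(identical(a$image$data, simulate_scene(sp2)$image$data))
})

test_that("the noise-free scene obeys superposition over the background", {
  b1 <- data.frame(center = 200, sigma = 15, amplitude = 20)
  b2 <- data.frame(center = 400, sigma = 25, amplitude = 35)
  f1 <- scene_field(scene_spec(bands = b1, noise_sd = 0))
  f2 <- scene_field(scene_spec(bands = b2, noise_sd = 0))
  f12 <- scene_field(scene_spec(bands = rbind(b1, b2), noise_sd = 0))
  bg <- scene_field(scene_spec(noise_sd = 0), "background")
  expect_equal(f12, f1 + f2 - bg, tolerance = 1e-12)
})

test_that("analytic ground-truth avePix agrees with dense numerical integration", {
  for (sig in c(6, 18, 27)) {
    sp <- scene_spec(bands = data.frame(center = 300, sigma = sig, amplitude = 44),
                     noise_sd = 0)
    sim <- simulate_scene(sp)
    # dense quadrature of the band profile over its 3-sigma window
    u <- seq(-3 * sig, 3 * sig, length.out = 20001)
    dense <- mean(44 * exp(-u^2 / (2 * sig^2)))
    expect_lt(abs(sim$truth$bands$ave_pix / dense - 1), 0.005)
    # unit-spacing Riemann sum over the rendered scene agrees too
    sig_field <- scene_field(sp, "signal")
    win <- round(300 + c(-3, 3) * sig)
    num <- sum(sig_field[1, win[1]:win[2]]) / (6 * sig)
    expect_lt(abs(sim$truth$bands$ave_pix / num - 1), 0.005)
  }
})

test_that("zero-amplitude scenes carry no signal and detect nothing", {
  sp <- scene_spec(bands = data.frame(center = 300, sigma = 20, amplitude = 0),
                   noise_sd = 2, seed = 21)
  sim <- simulate_scene(sp)
  expect_equal(scene_field(sp, "signal"), matrix(0, 200, 600))
  expect_equal(nrow(extract_rois(sim$image)), 0)
})

test_that("saturation is flagged, not an error", {
  sp <- scene_spec(bands = data.frame(center = 300, sigma = 20, amplitude = 250),
                   background = c(base = 40, gx = 0, gy = 0, gxx = 0), noise_sd = 0)
  expect_true(simulate_scene(sp)$truth$saturated)
  expect_false(simulate_scene(band_scene())$truth$saturated)
})

test_that("suite generation is reproducible and matches the requested contrast", {
  s1 <- weak_signal_suite(4, 3, seed = 7)
  s2 <- weak_signal_suite(4, 3, seed = 7)
  expect_equal(nrow(s1), 12)
  expect_identical(simulate_scene(s1$spec[[5]])$image$data,
                   simulate_scene(s2$spec[[5]])$image$data)
  # empirical contrast of the generated scene matches the declared snr
  for (i in c(1, 7)) {
    spec <- s1$spec[[i]]
    peak <- max(scene_field(spec, "signal"))
    expect_lt(abs(peak / spec$noise_sd / s1$snr[i] - 1), 0.1)
  }
  # all bands inside the strip margins, pairwise separated
  for (i in seq_len(nrow(s1))) {
    b <- s1$spec[[i]]$bands
    expect_true(all(b$center >= 120 & b$center <= 480))
    if (nrow(b) > 1) expect_gt(min(diff(sort(b$center))), 100)
  }
})

test_that("spec validation rejects impossible scenes", {
  expect_error(weak_signal_suite(5, 2, snr_range = c(0, 3)), class = "flfa_error_config")
  expect_error(scene_spec(bands = data.frame(center = 900, sigma = 5, amplitude = 1)),
               class = "flfa_error_config")
  expect_error(scene_spec(bands = data.frame(center = 300, sigma = 5, amplitude = -1)),
               class = "flfa_error_config")
  expect_error(scene_spec(noise_sd = -1), class = "flfa_error_config")
  expect_error(scene_spec(impulse_frac = 1.5), class = "flfa_error_config")
  expect_error(scene_spec(bit_depth = 12), class = "flfa_error_config")
})
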