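fourpl_curve <- function(x, A, D, C, B) D + (A - D) / (1 + (x / C)^B)

test_that("exact 4PL data are recovered to high precision", {
  doses <- c(0.01, 0.05, 0.2, 0.5, 2, 10)
  y <- fourpl_curve(doses, A = 1, D = 0, C = 0.5, B = 1)
  f <- fit_4pl(tibble::tibble(dose = doses, signal = y))
  expect_lt(max(abs(coef(f) - c(A = 1, D = 0, C = 0.5, B = 1))), 1e-6)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  # noise-free fit matches the generating curve pointwise
  grid <- exp(seq(log(0.01), log(10), length.out = 50))
  expect_lt(max(abs(predict(f, grid) - fourpl_curve(grid, 1, 0, 0.5, 1))), 1e-6)
})

test_that("the curve passes through (C, (A+D)/2) and supports both directions", {
  doses <- c(0.02, 0.1, 0.4, 1.5, 6, 25)
  # increasing (sandwich-type) response
  yi <- fourpl_curve(doses, A = 2, D = 80, C = 1.2, B = 2)
  fi <- fit_4pl(tibble::tibble(dose = doses, signal = yi))
  expect_equal(predict(fi, coef(fi)[["C"]]),
               (coef(fi)[["A"]] + coef(fi)[["D"]]) / 2, tolerance = 1e-8)
  expect_lt(abs(coef(fi)[["C"]] - 1.2), 1e-5)
  # decreasing (competitive) response
  yd <- fourpl_curve(doses, A = 90, D = 5, C = 0.8, B = 1.4)
  fd <- fit_4pl(tibble::tibble(dose = doses, signal = yd))
  expect_lt(max(abs(predict(fd, doses) - yd)), 1e-6)
})

test_that("swapping asymptotes with a negated slope leaves the curve unchanged", {
  x <- exp(seq(log(0.01), log(50), length.out = 40))
  y1 <- fourpl_curve(x, A = 1, D = 10, C = 2, B = 1.7)
  y2 <- fourpl_curve(x, A = 10, D = 1, C = 2, B = -1.7)
  expect_equal(y1, y2, tolerance = 1e-12)
})

test_that("inversion is the closed form and round-trips", {
  doses <- c(0.01, 0.05, 0.2, 0.5, 2, 10)
  f <- fit_4pl(tibble::tibble(
    dose = doses, signal = fourpl_curve(doses, 1, 0, 0.5, 1.3)
  ))
  cf <- coef(f)
  # y at the midpoint signal inverts to C
  expect_equal(invert_4pl(f, (cf[["A"]] + cf[["D"]]) / 2), cf[["C"]], tolerance = 1e-9)
  # forward-then-invert identity on 50 random in-range signals
  set.seed(5)
  xs <- exp(runif(50, log(0.02), log(8)))
  expect_lt(max(abs(invert_4pl(f, predict(f, xs)) / xs - 1)), 1e-9)
  # a signal approaching the zero-dose asymptote inverts toward zero dose
  expect_lt(invert_4pl(f, cf[["D"]] + 0.999999 * (cf[["A"]] - cf[["D"]])), 1e-3)
  # out-of-range signals are rejected
  expect_error(invert_4pl(f, 1.5), class = "flfa_error_processing")
  expect_error(invert_4pl(f, -0.2), class = "flfa_error_processing")
})

test_that("C is recovered within 10% median error under 1% signal noise", {
  doses <- c(0.01, 0.05, 0.2, 0.5, 2, 10)
  clean <- fourpl_curve(doses, A = 1, D = 0.02, C = 0.5, B = 1.2)
  set.seed(31)
  errs <- replicate(100, {
    y <- clean * (1 + rnorm(length(doses), 0, 0.01))
    abs(coef(fit_4pl(tibble::tibble(dose = doses, signal = y)))[["C"]] / 0.5 - 1)
  })
  expect_lt(stats::median(errs), 0.10)
})

test_that("degenerate calibration inputs give classed errors", {
  expect_error(fit_4pl(tibble::tibble(dose = c(1, 2, 3), signal = c(1, 2, 3))),
               class = "flfa_error_config")
  expect_error(fit_4pl(tibble::tibble(dose = c(0, 1, 2, 3), signal = 1:4)),
               class = "flfa_error_config")
  expect_error(fit_4pl(tibble::tibble(dose = c(1, 2, 4, 8), signal = c(1, NA, 3, 4))),
               class = "flfa_error_config")
})

test_that("broom-style methods expose the fit", {
  doses <- c(0.01, 0.05, 0.2, 0.5, 2, 10)
  set.seed(2)
  y <- fourpl_curve(doses, 1, 0, 0.5, 1) + rnorm(6, 0, 0.002)
  f <- fit_4pl(tibble::tibble(dose = doses, signal = y))
  td <- tidy(f)
  expect_equal(td$term, c("A", "D", "C", "B"))
  expect_true(all(is.finite(td$std.error)))
  gl <- glance(f)
  expect_gt(gl$r.squared, 0.999)
  expect_equal(gl$nobs, 6L)
})
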