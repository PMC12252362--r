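#' Fit a four-parameter logistic (4PL) calibration curve
#'
#' Fits the dose-response model
#' `y(x) = D + (A - D) / (1 + (x / C)^B)`
#' by Levenberg-Marquardt least squares, where `A` is the asymptote at zero
#' dose, `D` the asymptote at infinite dose, `C` the inflection concentration
#' and `B` the slope factor. Both increasing (sandwich assay) and decreasing
#' (competitive assay) responses are supported via the orientation of
#' `A`/`D` and the sign of `B` (the curve is invariant under swapping `A`
#' with `D` while negating `B`).
#'
#' Starting values: `A`/`D` from the mean signal at the lowest/highest dose,
#' `C` from the dose whose signal is nearest the half-range, `B = 1`.
#'
#' @param data Data frame with one row per measurement.
#' @param dose,signal Column names (unquoted) holding positive analyte
#'   concentrations and the measured signal (e.g. `ave_pix`). Defaults
#'   `dose` and `signal`.
#' @param weights Optional numeric vector of fit weights (e.g. `1 / y^2`);
#'   default unweighted.
#' @return An object of class `fourpl` with components `coefficients`
#'   (named `A`, `D`, `C`, `B`), `r_squared`, `fitted`, `residuals`, `data`
#'   and the underlying `nls` fit. Supports [coef()], [predict()],
#'   [tidy()], [glance()], [invert_4pl()] and [ggplot2::autoplot()].
#' @export
fit_4pl <- function(data, dose = dose, signal = signal, weights = NULL) {
  dose_q <- rlang::enquo(dose)
  signal_q <- rlang::enquo(signal)
  x <- rlang::eval_tidy(dose_q, data)
  y <- rlang::eval_tidy(signal_q, data)
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y)) {
    abort_config("`dose` and `signal` must be numeric columns of equal length.")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort_config("doses and signals must be finite.")
  }
  if (any(x <= 0)) {
    abort_config("doses must be strictly positive (the 4PL uses (x/C)^B).")
  }
  if (length(unique(x)) < 4) {
    abort_config(sprintf(
      "need at least 4 distinct doses to fit a 4PL; got %d.", length(unique(x))
    ))
  }
  means <- tapply(y, x, mean)
  xs <- as.numeric(names(means))
  A0 <- means[[which.min(xs)]]
  D0 <- means[[which.max(xs)]]
  half <- (A0 + D0) / 2
  C0 <- xs[which.min(abs(means - half))]
  if (C0 <= 0) C0 <- stats::median(xs)
  # log parameterization keeps the inflection concentration positive
  # throughout the Levenberg-Marquardt iterations
  start <- list(A = A0, D = D0, logC = log(C0), B = 1)

  df <- data.frame(x = x, y = y)
  fit_args <- list(
    formula = y ~ D + (A - D) / (1 + (x / exp(logC))^B),
    data = df, start = start,
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  if (!is.null(weights)) fit_args$weights <- weights
  fit <- tryCatch(
    do.call(minpack.lm::nlsLM, fit_args),
    error = function(e) {
      abort_processing(sprintf(
        "4PL fit did not converge: %s (start: A=%.4g, D=%.4g, C=%.4g, B=1)",
        conditionMessage(e), A0, D0, C0
      ))
    }
  )
  cf <- stats::coef(fit)
  cf <- c(A = unname(cf[["A"]]), D = unname(cf[["D"]]),
          C = exp(unname(cf[["logC"]])), B = unname(cf[["B"]]))
  fitted <- stats::predict(fit)
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(
    list(
      coefficients = cf,
      r_squared = r2,
      fitted = fitted,
      residuals = y - fitted,
      data = tibble::tibble(dose = x, signal = y),
      fit = fit
    ),
    class = "fourpl"
  )
}

fourpl_eval <- function(coefs, x) {
  coefs[["D"]] + (coefs[["A"]] - coefs[["D"]]) / (1 + (x / coefs[["C"]])^coefs[["B"]])
}

#' @export
coef.fourpl <- function(object, ...) object$coefficients

#' @export
print.fourpl <- function(x, ...) {
  cf <- x$coefficients
  cat(sprintf(
    "<fourpl> y = D + (A - D) / (1 + (x/C)^B)\n  A = %.6g, D = %.6g, C = %.6g, B = %.6g;  R^2 = %.6f\n",
    cf["A"], cf["D"], cf["C"], cf["B"], x$r_squared
  ))
  invisible(x)
}

#' Predict signal from dose for a fitted 4PL curve
#'
#' @param object A [fit_4pl()] result.
#' @param newdata Optional numeric vector of doses, or a data frame with a
#'   `dose` column; defaults to the fitted doses.
#' @param ... Unused.
#' @return Numeric vector of predicted signals.
#' @export
predict.fourpl <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) {
    object$data$dose
  } else if (is.data.frame(newdata)) {
    newdata$dose
  } else {
    as.numeric(newdata)
  }
  fourpl_eval(object$coefficients, x)
}

#' @export
tidy.fourpl <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  s <- s[c("A", "D", "logC", "B"), , drop = FALSE]
  se <- unname(s[, "Std. Error"])
  # delta method maps the fitted log C standard error back to C units
  se[3] <- se[3] * x$coefficients[["C"]]
  tibble::tibble(
    term = c("A", "D", "C", "B"),
    estimate = unname(x$coefficients[c("A", "D", "C", "B")]),
    std.error = se,
    statistic = unname(x$coefficients[c("A", "D", "C", "B")]) / se,
    p.value = 2 * stats::pt(abs(unname(x$coefficients[c("A", "D", "C", "B")]) / se),
                            df = stats::df.residual(x$fit), lower.tail = FALSE)
  )
}

#' @export
glance.fourpl <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared,
    sigma = summary(x$fit)$sigma,
    df.residual = stats::df.residual(x$fit),
    nobs = nrow(x$data),
    converged = x$fit$convInfo$isConv %||% TRUE
  )
}

#' Invert a 4PL calibration curve
#'
#' Closed-form inversion
#' `x = C * ((A - D) / (y - D) - 1)^(1 / B)`
#' mapping a measured signal back to a concentration. Signals must lie
#' strictly between the two asymptotes.
#'
#' @param model A [fit_4pl()] result, or a named vector/list with `A`, `D`,
#'   `C`, `B`.
#' @param signal Numeric vector of measured signals.
#' @return Numeric vector of concentrations.
#' @export
invert_4pl <- function(model, signal) {
  cf <- if (inherits(model, "fourpl")) model$coefficients else unlist(model)[c("A", "D", "C", "B")]
  if (any(is.na(cf))) abort_config("`model` must provide A, D, C and B.")
  lo <- min(cf[["A"]], cf[["D"]])
  hi <- max(cf[["A"]], cf[["D"]])
  if (any(!is.finite(signal)) || any(signal <= lo) || any(signal >= hi)) {
    abort_processing(sprintf(
      "signal out of range: inversion requires values strictly between the asymptotes (%.6g, %.6g).",
      lo, hi
    ))
  }
  cf[["C"]] * ((cf[["A"]] - cf[["D"]]) / (signal - cf[["D"]]) - 1)^(1 / cf[["B"]])
}
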