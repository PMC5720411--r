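#' Correlation function model F(w)
#'
#' The correlation function relates the EPID transit signal St \[CU\] behind a
#' water-equivalent thickness `w` to the midplane dose Dm \[Gy\]:
#' `F(w) = a1 w^2 + a2 w + a3`, with `F` in CU/Gy. It is measured on
#' cylindrical water phantoms and found independent of field size, wedge angle
#' and phantom radius within measurement reproducibility, so a single quadratic
#' serves all tangential fields.
#'
#' @param a1 Quadratic coefficient \[CU Gy^-1 cm^-2\].
#' @param a2 Linear coefficient \[CU Gy^-1 cm^-1\].
#' @param a3 Constant term \[CU Gy^-1\].
#' @param valid_w Length-2 interval \[cm\] over which the fit is supported;
#'   evaluation outside warns.
#' @param fit_residual_2sd Two standard deviations of the percent fit
#'   residuals, when the model came from [correlation_fit()].
#' @return An object of class `correlation_model`.
#' @seealso [correlation_eval()], [correlation_fit()], [default_calibration()]
#' @export
correlation_model <- function(a1, a2, a3, valid_w = c(5, 29),
                              fit_residual_2sd = NA_real_) {
  stopifnot(is.numeric(a1), is.numeric(a2), is.numeric(a3),
            length(valid_w) == 2, valid_w[1] < valid_w[2])
  m <- structure(
    list(a1 = a1, a2 = a2, a3 = a3, valid_w = as.numeric(valid_w),
         fit_residual_2sd = fit_residual_2sd),
    class = "correlation_model")
  wg <- seq(valid_w[1], valid_w[2], length.out = 101)
  if (any(a1 * wg^2 + a2 * wg + a3 <= 0)) {
    stop("F(w) must be positive over `valid_w`")
  }
  m
}

#' @export
print.correlation_model <- function(x, ...) {
  cat(sprintf("<correlation_model> F(w) = %.4g w^2 + %.4g w + %.4g [CU/Gy], w in [%g, %g] cm\n",
              x$a1, x$a2, x$a3, x$valid_w[1], x$valid_w[2]))
  if (!is.na(x$fit_residual_2sd)) {
    cat(sprintf("  fit residuals: %.2f%% (2 SD)\n", x$fit_residual_2sd))
  }
  invisible(x)
}

#' Evaluate the correlation function
#'
#' @param model A [correlation_model()].
#' @param w Water-equivalent thickness \[cm\], positive; vectorized.
#' @param warn Warn when `w` falls outside the model's supported interval.
#' @return F(w) \[CU/Gy\].
#' @export
correlation_eval <- function(model, w, warn = TRUE) {
  if (any(w <= 0)) stop("`w` must be positive")
  if (warn && any(w < model$valid_w[1] | w > model$valid_w[2])) {
    warning(sprintf("w outside the calibrated interval [%g, %g] cm; extrapolating",
                    model$valid_w[1], model$valid_w[2]))
  }
  model$a1 * w^2 + model$a2 * w + model$a3
}

#' Fit the correlation function to calibration samples
#'
#' Least-squares quadratic fit of `St/Dm` versus chord thickness `w`. The
#' samples from different wedge filters are pooled: measured `St/Dm` ratios
#' for the 15 and 30 degree wedges agree within measurement reproducibility.
#'
#' @param samples Data frame with columns `w_cm`, `st_cu`, `dm_gy` (a `kind`
#'   column, if present, restricts the fit to `kind == "correlation"` rows).
#' @param valid_w Supported interval recorded on the returned model; default
#'   spans the observed `w` range.
#' @return A [correlation_model()] with `fit_residual_2sd` set to twice the
#'   standard deviation of the percent residuals.
#' @export
correlation_fit <- function(samples, valid_w = NULL) {
  samples <- as.data.frame(samples)
  if (!is.null(samples$kind)) samples <- samples[samples$kind == "correlation", ]
  req <- c("w_cm", "st_cu", "dm_gy")
  if (!all(req %in% names(samples))) {
    stop("`samples` needs columns ", paste(req, collapse = ", "))
  }
  w <- samples$w_cm
  y <- samples$st_cu / samples$dm_gy
  if (length(unique(w)) < 3) {
    stop(sprintf("rank-deficient design: only %d distinct w value(s) (%s); a quadratic needs at least 3",
                 length(unique(w)), paste(format(sort(unique(w))), collapse = ", ")))
  }
  fit <- stats::lm(y ~ w + I(w^2))
  co <- stats::coef(fit)
  pred <- stats::fitted(fit)
  pct <- 100 * (y - pred) / pred
  resid_2sd <- if (length(y) > 3) 2 * stats::sd(pct) else 0
  if (is.null(valid_w)) valid_w <- range(w)
  correlation_model(a1 = unname(co["I(w^2)"]), a2 = unname(co["w"]),
                    a3 = unname(co["(Intercept)"]), valid_w = valid_w,
                    fit_residual_2sd = resid_2sd)
}

#' Scatter factor model f(d, r)
#'
#' The scatter factor corrects the transit signal for the change of phantom
#' scatter reaching the EPID when the phantom midpoint sits a distance `d`
#' from the isocenter: `f(d, r) = f0(r) d + 1`, where the slope `f0(r)`
#' \[cm^-1\] depends on the equivalent cylinder radius `r` and is tabulated at
#' the four calibration phantom radii. Evaluation interpolates `f0` linearly
#' in `r` and clamps beyond the table ends.
#'
#' @param radii Increasing vector of phantom radii \[cm\].
#' @param f0 Slopes \[cm^-1\] matching `radii`.
#' @param valid_d Supported displacement interval \[cm\].
#' @param fit_residual_2sd Percent residual spread (2 SD) from [scatter_fit()].
#' @return An object of class `scatter_model`.
#' @export
scatter_model <- function(radii, f0, valid_d = c(-4, 4),
                          fit_residual_2sd = NA_real_) {
  stopifnot(length(radii) == length(f0), length(radii) >= 1)
  if (is.unsorted(radii, strictly = TRUE)) {
    stop("`radii` must be strictly increasing")
  }
  structure(
    list(radii = as.numeric(radii), f0 = as.numeric(f0),
         valid_d = as.numeric(valid_d), fit_residual_2sd = fit_residual_2sd),
    class = "scatter_model")
}

#' @export
print.scatter_model <- function(x, ...) {
  cat("<scatter_model> f(d, r) = f0(r) d + 1\n")
  cat(sprintf("  r  [cm]: %s\n", paste(format(x$radii), collapse = "  ")))
  cat(sprintf("  f0 [1/cm]: %s\n", paste(format(x$f0, digits = 4), collapse = "  ")))
  invisible(x)
}

#' Evaluate the scatter factor
#'
#' @param model A [scatter_model()].
#' @param d Signed displacement \[cm\] of the chord midpoint from the
#'   isocenter; vectorized.
#' @param r Equivalent cylinder radius \[cm\].
#' @param warn Warn when `d` exceeds the calibrated range or `r` falls outside
#'   the tabulated radii (where `f0` is clamped to the table end).
#' @return Dimensionless factor `f0(r) d + 1`.
#' @export
scatter_eval <- function(model, d, r, warn = TRUE) {
  if (warn && any(d < model$valid_d[1] | d > model$valid_d[2])) {
    warning(sprintf("|d| outside the calibrated range [%g, %g] cm",
                    model$valid_d[1], model$valid_d[2]))
  }
  if (warn && any(r < model$radii[1] | r > model$radii[length(model$radii)])) {
    warning("r outside the tabulated radii; f0 clamped to the table end")
  }
  f0 <- if (length(model$radii) == 1) rep(model$f0, length(r)) else {
    stats::approx(model$radii, model$f0, xout = r, rule = 2)$y
  }
  f0 * d + 1
}

#' Fit per-radius scatter slopes
#'
#' For each phantom radius, forms the ratios `f = St / S't` of the reference
#' signal at `d = 0` to the signal at displacement `d` and fits the slope of
#' `f - 1` versus `d` by least squares with the intercept fixed at 1.
#'
#' @param samples Data frame with columns `r_cm`, `d_cm`, `st_cu` (a `kind`
#'   column, if present, restricts to `kind == "scatter"` rows). Each radius
#'   group must contain a `d = 0` reference row and at least 3 distinct `d`.
#' @return A [scatter_model()] with pooled percent-residual 2 SD.
#' @export
scatter_fit <- function(samples) {
  samples <- as.data.frame(samples)
  if (!is.null(samples$kind)) samples <- samples[samples$kind == "scatter", ]
  req <- c("r_cm", "d_cm", "st_cu")
  if (!all(req %in% names(samples))) {
    stop("`samples` needs columns ", paste(req, collapse = ", "))
  }
  radii <- sort(unique(samples$r_cm))
  f0 <- numeric(length(radii))
  pct <- numeric(0)
  for (k in seq_along(radii)) {
    g <- samples[samples$r_cm == radii[k], ]
    if (length(unique(g$d_cm)) < 3) {
      stop(sprintf("radius %g cm: need at least 3 distinct d values, got %d",
                   radii[k], length(unique(g$d_cm))))
    }
    ref <- g$st_cu[g$d_cm == 0]
    if (length(ref) == 0) {
      stop(sprintf("radius %g cm: no d = 0 reference sample", radii[k]))
    }
    ratio <- mean(ref) / g$st_cu
    slope <- sum(g$d_cm * (ratio - 1)) / sum(g$d_cm^2)
    pred <- slope * g$d_cm + 1
    pct <- c(pct, 100 * (ratio - pred) / pred)
    f0[k] <- slope
  }
  n_par <- length(radii)
  resid_2sd <- if (length(pct) > n_par) 2 * stats::sd(pct) else 0
  scatter_model(radii = radii, f0 = f0,
                valid_d = range(samples$d_cm), fit_residual_2sd = resid_2sd)
}

#' Packaged calibration tables
#'
#' The published calibration for the aS500 EPID at SED 150 cm and 6 MV:
#' correlation coefficients `a1 = 5.819e-4`, `a2 = 2.880e-2`, `a3 = 5.480e-1`
#' and scatter slopes `f0 = (0.998, 1.487, 2.094, 2.756) x 10^-3 cm^-1` at
#' radii 6.0, 8.3, 10.7 and 14.5 cm.
#'
#' @return An object of class `epid_calibration`: a list with elements
#'   `correlation` ([correlation_model()]) and `scatter` ([scatter_model()]).
#' @examples
#' calib <- default_calibration()
#' correlation_eval(calib$correlation, 15)
#' scatter_eval(calib$scatter, 4, 10.7)
#' @export
default_calibration <- function() {
  epid_calibration(
    correlation = correlation_model(a1 = 5.819e-4, a2 = 2.880e-2, a3 = 5.480e-1),
    scatter = scatter_model(radii = c(6.0, 8.3, 10.7, 14.5),
                            f0 = c(0.998e-3, 1.487e-3, 2.094e-3, 2.756e-3))
  )
}

#' Bundle a correlation and a scatter model
#'
#' @param correlation A [correlation_model()].
#' @param scatter A [scatter_model()].
#' @return An object of class `epid_calibration`.
#' @export
epid_calibration <- function(correlation, scatter) {
  stopifnot(inherits(correlation, "correlation_model"),
            inherits(scatter, "scatter_model"))
  structure(list(correlation = correlation, scatter = scatter),
            class = "epid_calibration")
}

#' @export
print.epid_calibration <- function(x, ...) {
  cat("<epid_calibration>\n")
  print(x$correlation)
  print(x$scatter)
  invisible(x)
}
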