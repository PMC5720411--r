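test_that("correlation function evaluates the calibrated quadratic", {
  m <- fix_calib$correlation
  expect_equal(correlation_eval(m, 15), polyval2(5.819e-4, 2.880e-2, 5.480e-1, 15))
  expect_equal(correlation_eval(m, 15), 1.1109275)
  # constant-term limit as w -> 0 (outside the supported interval)
  expect_equal(correlation_eval(m, 1e-9, warn = FALSE), 0.5480, tolerance = 1e-6)
  expect_warning(correlation_eval(m, 2), "outside")
  expect_error(correlation_eval(m, 0), "positive")
  # monotone increasing over the supported interval
  wg <- seq(m$valid_w[1], m$valid_w[2], by = 0.1)
  expect_true(all(diff(correlation_eval(m, wg)) > 0))
})

test_that("correlation fit recovers generating coefficients", {
  gen <- correlation_model(a1 = 4e-4, a2 = 0.031, a3 = 0.52)
  w <- c(6, 11, 17, 23, 28)
  samples <- data.frame(w_cm = w, st_cu = correlation_eval(gen, w) * 1.8, dm_gy = 1.8)
  fit <- correlation_fit(samples)
  expect_equal(fit$a1, gen$a1, tolerance = 1e-8)
  expect_equal(fit$a2, gen$a2, tolerance = 1e-8)
  expect_equal(fit$a3, gen$a3, tolerance = 1e-8)
  expect_lt(fit$fit_residual_2sd, 1e-8)
})

test_that("correlation fit errors on a rank-deficient design", {
  samples <- data.frame(w_cm = c(10, 10, 20, 20), st_cu = c(1, 1, 2, 2), dm_gy = 1.8)
  expect_error(correlation_fit(samples), "rank-deficient")
})

test_that("fitted F(w) stays within 1% of the generator under 0.5% noise", {
  samples <- generate_calibration_set(fix_calib, n_w = 40, noise_2sd = 0.5, seed = 42)
  fit <- correlation_fit(samples)
  wg <- seq(5, 29, by = 0.5)
  dev <- correlation_eval(fit, wg, warn = FALSE) /
    correlation_eval(fix_calib$correlation, wg, warn = FALSE) - 1
  expect_lt(max(abs(dev)), 0.01)
})

test_that("scatter factor evaluates and interpolates the slope table", {
  s <- fix_calib$scatter
  expect_equal(scatter_eval(s, 0, 7), 1)
  expect_equal(scatter_eval(s, 0, 12.2), 1)
  expect_equal(scatter_eval(s, 4, 10.7), 1 + 2.094e-3 * 4)
  expect_equal(scatter_eval(s, -4, 6.0), 1 - 0.998e-3 * 4)
  # linear-in-r interpolation between knots
  mid <- scatter_eval(s, 2, (8.3 + 10.7) / 2)
  expect_equal(mid, 1 + 2 * (1.487e-3 + 2.094e-3) / 2)
  # continuity across knots
  expect_equal(scatter_eval(s, 3, 8.3 - 1e-9), scatter_eval(s, 3, 8.3 + 1e-9),
               tolerance = 1e-6)
  # clamped beyond the table, with warning
  expect_warning(lo <- scatter_eval(s, 2, 4), "clamped")
  expect_equal(lo, scatter_eval(s, 2, 6))
  expect_warning(scatter_eval(s, 5, 8.3), "calibrated range")
})

test_that("scatter fit recovers the generating slopes from noiseless ratios", {
  samples <- generate_calibration_set(fix_calib, noise_2sd = 0, ratio_noise_2sd = 0)
  fit <- scatter_fit(samples)
  expect_equal(fit$radii, c(6, 8.3, 10.7, 14.5))
  expect_equal(fit$f0, fix_calib$scatter$f0, tolerance = 1e-10)
  expect_lt(fit$fit_residual_2sd, 1e-8)
})

test_that("scatter fit rejects degenerate designs", {
  expect_error(
    scatter_fit(data.frame(r_cm = 8.3, d_cm = c(0, 2), st_cu = c(1, 0.99))),
    "3 distinct d")
  expect_error(
    scatter_fit(data.frame(r_cm = 8.3, d_cm = c(-2, 2, 3), st_cu = c(1, 0.99, 0.98))),
    "reference")
})

test_that("packaged calibration tables carry the published values", {
  calib <- default_calibration()
  expect_equal(calib$correlation$a3, 5.480e-1)
  expect_equal(calib$scatter$radii, c(6.0, 8.3, 10.7, 14.5))
  expect_equal(calib$scatter$f0[4], 2.756e-3)
  expect_equal(scatter_eval(calib$scatter, 0, 8.3), 1)
})

test_that("correlation model rejects non-positive F over its support", {
  expect_error(correlation_model(a1 = 0, a2 = -0.1, a3 = 0.5), "positive")
})
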