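test_that("cylinder slices discretize the phantom geometry faithfully", {
  sl <- make_cylinder_slice(6, spacing = 0.1)
  area <- sum(sl$grid) * sl$spacing^2
  expect_lt(abs(area / (pi * 36) - 1), 0.01)
  expect_equal(radiological_path(sl, c(-6, 0), c(6, 0)), 12, tolerance = 0.05)
  expect_error(make_cylinder_slice(0.1, spacing = 0.1), "two grid cells")
})

test_that("breast slices have exactly three density levels and a lung shadow", {
  expect_identical(sort(unique(as.vector(fix_breast$grid))), c(0, 0.3, 1))
  full <- make_breast_slice(lung_density = 1, spacing = 0.2)
  ch <- chord_through(full, fan_line(-9))
  expect_equal(ch$w_prime, ch$w, tolerance = 0.05)
  # fan line above the apex: outside-field marker
  miss <- chord_through(fix_breast, fan_line(5))
  expect_false(miss$in_body)
  expect_error(make_breast_slice(lung_margin = 10), "no room")
})

test_that("forward transit is deterministic under a fixed seed", {
  p1 <- forward_transit(fix_cyl, noise_2sd = 0.5, seed = 123)
  p2 <- forward_transit(fix_cyl, noise_2sd = 0.5, seed = 123)
  expect_identical(p1$signals, p2$signals)
  p3 <- forward_transit(fix_cyl, noise_2sd = 0.5, seed = 124)
  expect_false(identical(p3$signals, p1$signals))
})

test_that("the central-axis forward sample inverts through the midpoint relation", {
  sl <- make_cylinder_slice(8.25, spacing = 0.1, center = c(2, 0))
  prof <- forward_transit(sl, positions = seq(-6, 6, by = 0.25), noise_2sd = 0)
  st <- prof$signals[prof$positions == 0]
  dm <- midpoint_dose(st, w = prof$meta$w, d = prof$meta$d, r = prof$meta$r,
                      warn = FALSE)
  expect_equal(dm, 1.8, tolerance = 2e-3)
})

test_that("calibration-set generation is seeded and exact at zero noise", {
  s1 <- generate_calibration_set(noise_2sd = 0.5, seed = 7)
  s2 <- generate_calibration_set(noise_2sd = 0.5, seed = 7)
  expect_identical(s1, s2)
  clean <- generate_calibration_set(noise_2sd = 0, ratio_noise_2sd = 0,
                                    w_grid = seq(5, 29, by = 2))
  cf <- correlation_fit(clean)
  expect_equal(cf$a1, 5.819e-4, tolerance = 1e-10)
  sf <- scatter_fit(clean)
  expect_equal(sf$f0, c(0.998e-3, 1.487e-3, 2.094e-3, 2.756e-3), tolerance = 1e-12)
  expect_error(generate_calibration_set(d_grid = c(-2, 2)), "reference")
})

test_that("misalignment shifts the signal support rigidly", {
  p <- fix_breast_ref
  expect_identical(apply_misalignment(p, 0), p)
  sh <- apply_misalignment(p, 1.5)
  # interior samples: shifted profile at y equals original at y - 1.5
  interior <- which(p$positions > min(p$positions) + 2 &
                    p$positions < max(p$positions) - 2)
  orig <- stats::approx(p$positions, p$signals,
                        xout = p$positions[interior] - 1.5)$y
  expect_equal(sh$signals[interior], orig, tolerance = 1e-9)
})

test_that("simulated cohorts carry their truth and recover draw statistics", {
  co0 <- simulate_cohort(fix_breast, n = 3, setup_sd_mm = 0, systematic_mm = 0,
                         noise_2sd = 0, seed = 1)
  expect_true(all(vapply(co0$sessions, `[[`, numeric(1), "true_shift_cm") == 0))
  co <- simulate_cohort(fix_breast, n = 300, setup_sd_mm = 3.3,
                        systematic_mm = 1.5, noise_2sd = 0, seed = 2)
  shifts_mm <- 10 * vapply(co$sessions, `[[`, numeric(1), "true_shift_cm")
  expect_equal(mean(shifts_mm), 1.5, tolerance = 0.5)
  expect_equal(sd(shifts_mm), 3.3, tolerance = 0.5)
})

test_that("alignment shrinks the spread of R in a misaligned cohort", {
  co <- simulate_cohort(fix_breast, n = 16, setup_sd_mm = 5, noise_2sd = 0.5,
                        seed = 11)
  aligned <- cohort_records(co, fix_breast, align = TRUE)
  unaligned <- cohort_records(co, fix_breast, align = FALSE)
  expect_lt(sd(aligned$ratio_r), sd(unaligned$ratio_r))
  # aligned reconstruction is accurate on average
  expect_equal(mean(aligned$ratio_r), 1, tolerance = 0.02)
  rep <- session_report(aligned, tolerance = 5)
  expect_equal(rep$fraction_within_percent, 100)
})
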