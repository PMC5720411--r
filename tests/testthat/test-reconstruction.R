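test_that("midpoint dose inverts the transit relation", {
  # at d = 0 the relation reduces to St/F(w)
  st <- correlation_eval(fix_calib$correlation, 14) * 1.8
  expect_equal(midpoint_dose(st, w = 14, d = 0, r = 8.3, fix_calib), 1.8)
  # forward-inverse round trip at d = +3 via the same factors
  Fw <- correlation_eval(fix_calib$correlation, 16.5)
  f <- scatter_eval(fix_calib$scatter, 3, 8.3)
  st3 <- 1.8 * Fw / (f * inverse_square(100, 3))
  expect_equal(midpoint_dose(st3, w = 16.5, d = 3, r = 8.3, fix_calib), 1.8)
  # linearity in the signal
  expect_equal(midpoint_dose(2 * st3, 16.5, 3, 8.3, fix_calib),
               2 * midpoint_dose(st3, 16.5, 3, 8.3, fix_calib))
})

test_that("off-axis dose is the midpoint relation at d = 0", {
  Fw <- correlation_eval(fix_calib$correlation, 12)
  expect_equal(offaxis_dose(Fw, 12, fix_calib), 1)
  expect_equal(offaxis_dose(0.9, 12, fix_calib),
               midpoint_dose(0.9, 12, 0, 10, fix_calib))
  expect_equal(offaxis_dose(0, 12, fix_calib), 0)
})

test_that("attenuation factor is the signed exponential", {
  expect_equal(attenuation_factor(0), 1)
  expect_equal(attenuation_factor(10), exp(-0.273))
  expect_equal(attenuation_factor(-10), exp(0.273))
  k <- physics_constants(mu_en_over_rho = 0.03)
  expect_equal(attenuation_factor(5, k), exp(-0.15))
})

test_that("fan-line C factor is the product of its four terms", {
  mk_chord <- function(w_prime, d1, d2, w2) {
    structure(list(in_body = TRUE, w_prime = w_prime, d1 = d1, d2 = d2,
                   w2_prime = w2), class = "chord_geometry")
  }
  # d1 = d2 = 0: reduces to f(d,r)/F(w')
  c0 <- fanline_c_factor(mk_chord(16.5, 0, 0, 0), d = 0, r = 8.3, fix_calib)
  expect_equal(c0, 1 / correlation_eval(fix_calib$correlation, 16.5))
  # general case against an independently assembled term-by-term product
  ch <- mk_chord(16.5, 2, -3, -3)
  got <- fanline_c_factor(ch, d = 2, r = 8.3, fix_calib)
  sad <- 100
  want <- scatter_eval(fix_calib$scatter, 2, 8.3) /
    correlation_eval(fix_calib$correlation, 16.5) *
    ((sad + 2) / sad)^2 * ((sad + 2) / (sad + 2 - 3))^2 * exp(-2.73e-2 * -3)
  expect_equal(got, want)
  expect_error(fanline_c_factor(mk_chord(16.5, -50, -60, 0), d = 0, r = 8.3,
                                fix_calib), "positive")
})

test_that("on the central axis the C factor degenerates to the midpoint relation", {
  sl <- make_cylinder_slice(8.25, spacing = 0.1, center = c(2, 0))
  ch <- chord_through(sl, fan_line(0))
  ch <- chord_through(sl, fan_line(0), t_p0 = 100 + ch$d)
  C <- fanline_c_factor(ch, d = ch$d, r = 8.25, fix_calib, warn = FALSE)
  dm_factor <- midpoint_dose(1, ch$w_prime, ch$d, 8.25, fix_calib, warn = FALSE)
  expect_equal(C, dm_factor, tolerance = 1e-3)
})

test_that("profile reconstruction inverts the forward model exactly at zero noise", {
  prof <- forward_transit(fix_cyl, fix_beam, fix_calib, noise_2sd = 0)
  dp <- profile_dose(prof, fix_cyl, fix_beam, fix_calib)
  ok <- !dp$excluded & !is.na(dp$dose)
  expect_gt(sum(ok), 40)
  expect_lt(max(abs(dp$dose[ok] / 1.8 - 1)), 1e-3)
  # the reported central-axis geometry matches the phantom
  expect_equal(attr(dp, "r"), 8.25, tolerance = 0.1)
  expect_equal(attr(dp, "d"), 0, tolerance = 0.05)
})

test_that("points within 1 cm of the lung interface are excluded", {
  prof <- forward_transit(fix_breast, fix_beam, fix_calib, noise_2sd = 0)
  dp <- profile_dose(prof, fix_breast, fix_beam, fix_calib)
  # lung top boundary sits 5 cm below the breast midpoint on the CD segment
  near <- !is.na(dp$dose) & dp$position > -5.8 & dp$position < -4.2
  expect_true(all(dp$excluded[near]))
  expect_true(all(dp$reason[near] == "interface"))
  # mid-breast points are reconstructed
  mid <- dp$position > -2 & dp$position < 1 & !dp$excluded
  expect_gt(sum(mid), 5)
  expect_lt(max(abs(dp$dose[mid] / 1.8 - 1)), 1e-3)
})

test_that("an all-air slice yields an empty profile with a diagnostic", {
  air <- phantom_slice(matrix(0, 40, 40), spacing = 0.25)
  prof <- transit_profile(seq(-4, 4, by = 0.5), rep(1, 17))
  dp <- profile_dose(prof, air)
  expect_identical(nrow(dp), 0L)
  expect_match(attr(dp, "diagnostic"), "central axis")
})

test_that("interface exclusion masks positions within the margin of a density step", {
  uni <- phantom_slice(matrix(1, 60, 60), spacing = 0.25)
  pos <- seq(-5, 5, by = 0.5)
  expect_false(any(exclude_interfaces(uni, c(0, 0), c(0, 1), pos)))
  # single step interface at y = 5
  g <- matrix(1, 60, 80)
  g[, (1:80) > 60] <- 0  # cells centered above y = 5 are air
  step_slice <- phantom_slice(g, spacing = 0.25, origin = c(-7.5, -10))
  probe <- c(3.5, 4.3, 5.7, 6.5)
  m1 <- exclude_interfaces(step_slice, c(0, 0), c(0, 1), probe, margin = 1)
  expect_identical(m1, c(FALSE, TRUE, TRUE, FALSE))
  m0 <- exclude_interfaces(step_slice, c(0, 0), c(0, 1), probe, margin = 0)
  expect_false(any(m0))
})

test_that("midpoint reconstruction from a session profile recovers the dose", {
  res <- reconstruct_midpoint(fix_breast_ref, fix_breast, fix_beam, fix_calib,
                              align = TRUE, reference_edge = fix_breast_edge)
  expect_equal(res$shift_s, 0, tolerance = 0.05)
  expect_equal(res$dm, 1.8, tolerance = 0.02)
  expect_error(
    reconstruct_midpoint(fix_breast_ref, fix_breast, align = TRUE),
    "reference_edge")
})
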