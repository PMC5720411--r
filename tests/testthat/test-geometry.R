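test_that("sagitta radius reproduces circles through chord and apex", {
  # diameter chord: sagitta equals the radius
  expect_equal(sagitta_radius(12, 6), 6)
  for (h in c(0.5, 2, 7.3)) expect_equal(sagitta_radius(2 * h, h), h)
  # circumcircle through (-5,0), (5,0), (0,2): center (0, -21/4), radius 29/4
  expect_equal(sagitta_radius(10, 2), 7.25)
  expect_error(sagitta_radius(-1, 2), "positive")
  expect_error(sagitta_radius(10, 0), "positive")
})

test_that("iso/EPID projection is similar triangles with exact round trip", {
  b <- beam_geometry(sad = 100, sed = 150)
  expect_equal(project_iso_to_epid(0, b), 0)
  expect_equal(project_iso_to_epid(4, b), 6)
  expect_equal(project_epid_to_iso(6, b), 4)
  xs <- seq(-12, 12, by = 0.7)
  expect_equal(project_epid_to_iso(project_iso_to_epid(xs, b), b), xs)
  fl <- fan_line(5, b)
  expect_equal(fl$iso_coord, project_epid_to_iso(fl$epid_coord, b))
})

test_that("inverse-square and Sterling factors", {
  expect_equal(inverse_square(100, 0), 1)
  expect_equal(inverse_square(100, 4), 1.0816)
  expect_equal(inverse_square(100, -4), 0.9216)
  expect_error(inverse_square(100, -100), "positive")
  expect_equal(sterling_equivalent_square(10, 10), 10)
  expect_equal(sterling_equivalent_square(16, 24), 19.2)
  expect_equal(sterling_equivalent_square(3, 7), sterling_equivalent_square(7, 3))
  expect_error(sterling_equivalent_square(0, 5), "positive")
})

test_that("radiological path integrates relative density along segments", {
  sl <- make_cylinder_slice(6, spacing = 0.1)
  # diameter of a uniform water cylinder
  expect_equal(radiological_path(sl, c(-6, 0), c(6, 0)), 12, tolerance = 0.02)
  # insert a 4 cm band of density 0.3 across the path: 12 - 4 + 4*0.3 = 9.2
  sl2 <- sl
  xs <- sl2$origin[1] + (seq_len(nrow(sl2$grid)) - 1) * sl2$spacing
  band <- abs(xs) <= 2
  sl2$grid[band, ] <- pmin(sl2$grid[band, ], 0.3)
  expect_equal(radiological_path(sl2, c(-6, 0), c(6, 0)), 9.2, tolerance = 0.05)
  # entirely in air, and degenerate segments
  expect_equal(radiological_path(sl, c(-8, 7.5), c(8, 7.5)), 0)
  expect_equal(radiological_path(sl, c(1, 1), c(1, 1)), 0)
})

test_that("radiological path is additive over splits and converges in step", {
  sl <- make_cylinder_slice(6, spacing = 0.1)
  p0 <- c(-7, -2); p1 <- c(1, 0.5); p2 <- c(7, 3)
  whole <- radiological_path(sl, p0, p2)
  parts <- radiological_path(sl, p0, p1) + radiological_path(sl, p1, p2)
  expect_equal(whole, parts, tolerance = 0.02)
  coarse <- radiological_path(sl, c(-7, 0.7), c(7, 0.7), step = 0.05)
  fine <- radiological_path(sl, c(-7, 0.7), c(7, 0.7), step = 0.005)
  expect_lt(abs(coarse / fine - 1), 0.001)
})

test_that("chord geometry on a centered cylinder matches the construction", {
  sl <- make_cylinder_slice(8.25, spacing = 0.1)
  ch <- chord_through(sl, fan_line(0), t_p0 = 100)
  expect_true(ch$in_body)
  expect_equal(ch$w, 16.5, tolerance = 0.25)
  expect_equal(ch$w_prime, 16.5, tolerance = 0.1)
  expect_equal(ch$d, 0, tolerance = 0.05)
  expect_equal(ch$d1, 0, tolerance = 0.05)
  expect_equal(ch$d2, 0, tolerance = 0.05)
  expect_equal(ch$w2_prime, 0, tolerance = 0.05)
})

test_that("displacing the cylinder displaces the chord midpoint and P'", {
  sl <- make_cylinder_slice(8.25, spacing = 0.1, center = c(3, 0))
  ch <- chord_through(sl, fan_line(0))
  expect_equal(ch$d, 3, tolerance = 0.05)
  expect_equal(ch$d1, 3, tolerance = 0.05)
})

test_that("fan lines missing the body report outside-field, not an error", {
  ch <- chord_through(fix_cyl, fan_line(20), fix_beam)
  expect_false(ch$in_body)
  expect_identical(ch$w, 0)
})

test_that("off-center fan lines recover the construction radius via the sagitta", {
  sl <- make_cylinder_slice(10.7, spacing = 0.1)
  for (iso in c(-4, 0, 3)) {
    ch <- chord_through(sl, fan_line(iso))
    up <- epidtransit:::contour_crossing(sl, ch$midpoint, c(0, 1), max_len = 30)
    dn <- epidtransit:::contour_crossing(sl, ch$midpoint, c(0, -1), max_len = 30)
    cp <- min(up, dn)
    expect_equal(sagitta_radius(ch$w, cp), 10.7, tolerance = 0.1)
  }
})

test_that("lung-crossing fan lines have radiological thickness below geometric", {
  sl <- make_breast_slice(spacing = 0.1)
  ch <- chord_through(sl, fan_line(-9))  # through the chest wall and lung
  expect_true(ch$in_body)
  # 2 x 1 cm tissue rind + 12 cm lung at density 0.3
  expect_equal(ch$w, 14, tolerance = 0.3)
  expect_equal(ch$w_prime, 2 + 12 * 0.3, tolerance = 0.3)
  expect_lt(ch$w_prime, ch$w)
})
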