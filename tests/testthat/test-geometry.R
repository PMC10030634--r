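test_that("sphere area follows pi d^2 with quadratic scaling", {
  expect_equal(sphere_surface_area(2), 4 * pi)
  expect_equal(
    sphere_surface_area(2) / sphere_surface_area(1), 4
  )
  # thorax diameter back-solved from the published area via d = sqrt(A/pi)
  expect_equal(sphere_surface_area(3.90), 47.78, tolerance = 1e-4)
  expect_error(sphere_surface_area(0), "positive")
  expect_error(sphere_surface_area(-1), "positive")
})

test_that("ellipsoid closed forms match numerical quadrature", {
  expect_equal(oblate_ellipsoid_area(5, 3), oblate_area_quadrature(5, 3),
    tolerance = 1e-9
  )
  expect_equal(oblate_ellipsoid_area(5, 3), 234.735959322, tolerance = 1e-9)
  expect_equal(prolate_ellipsoid_area(5, 3), prolate_area_quadrature(5, 3),
    tolerance = 1e-9
  )
  expect_equal(prolate_ellipsoid_area(5, 3), 165.793061936, tolerance = 1e-9)
  for (ratio in c(0.05, 0.2, 0.5, 0.8, 0.95, 1)) {
    a <- 4.0
    expect_equal(
      oblate_ellipsoid_area(a, a * ratio),
      oblate_area_quadrature(a, a * ratio),
      tolerance = 1e-9
    )
    expect_equal(
      prolate_ellipsoid_area(a, a * ratio),
      prolate_area_quadrature(a, a * ratio),
      tolerance = 1e-9
    )
  }
})

test_that("ellipsoid formulas are continuous at the sphere limit", {
  expect_equal(oblate_ellipsoid_area(3, 3), 4 * pi * 9)
  expect_equal(prolate_ellipsoid_area(3, 3), 4 * pi * 9)
  # at axis ratio 1 - delta the true areas differ from the sphere by
  # (2/3) delta (oblate) and (4/3) delta (prolate); the formulas must track
  # that limit without numerical blow-up near e = 0
  delta <- 1e-6
  r <- 1 - delta
  expect_equal(oblate_ellipsoid_area(5, 5 * r), 4 * pi * 25,
    tolerance = 2 * delta
  )
  expect_equal(prolate_ellipsoid_area(5, 5 * r), 4 * pi * 25,
    tolerance = 2 * delta
  )
  expect_equal(oblate_ellipsoid_area(5, 5 * r),
    oblate_area_quadrature(5, 5 * r),
    tolerance = 1e-9
  )
  expect_equal(prolate_ellipsoid_area(5, 5 * r),
    prolate_area_quadrature(5, 5 * r),
    tolerance = 1e-9
  )
})

test_that("ellipsoid areas scale quadratically and reject wrong axis order", {
  k <- 2.5
  expect_equal(
    oblate_ellipsoid_area(k * 5, k * 3), k^2 * oblate_ellipsoid_area(5, 3)
  )
  expect_equal(
    prolate_ellipsoid_area(k * 5, k * 3), k^2 * prolate_ellipsoid_area(5, 3)
  )
  expect_error(oblate_ellipsoid_area(3, 5), "c <= equatorial")
  expect_error(prolate_ellipsoid_area(3, 5), "b <= long")
  expect_error(oblate_ellipsoid_area(3, 0), "positive")
})

test_that("published constant areas carry both whole-body totals", {
  s <- body_surface()
  expect_equal(s$A_hd, 30.80e-6)
  expect_equal(s$A_th, 47.78e-6)
  expect_equal(s$A_ab, 85.91e-6)
  # the printed whole-body area differs from the component sum by 0.79 mm^2;
  # both are carried, neither silently corrected
  expect_equal(s$A_b, 163.7e-6)
  expect_equal(body_surface(total = "sum")$A_b, 164.49e-6)
})

test_that("dimension-based areas reproduce the published parts", {
  s <- body_surface(body_dimensions())
  expect_equal(s$A_th * 1e6, 47.78, tolerance = 1e-4)
  expect_equal(s$A_hd * 1e6, 30.80, tolerance = 1e-3)
  expect_equal(s$A_ab * 1e6, 85.91, tolerance = 1e-3)
  # computed mode always totals to the component sum, converted exactly
  expect_identical(s$A_b, s$A_hd + s$A_th + s$A_ab)
  dims <- body_dimensions(
    head_width = 3, head_depth = 2, thorax_diameter = 4,
    abdomen_length = 6, abdomen_width = 4
  )
  s2 <- body_surface(dims)
  expect_equal(s2$A_th * 1e6, sphere_surface_area(4))
  expect_error(body_dimensions(thorax_diameter = 0), "positive")
  expect_error(body_dimensions(head_depth = 5), "head_depth <= head_width")
  expect_error(
    body_dimensions(abdomen_length = 3, abdomen_width = 4), "abdomen_width"
  )
})
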