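test_that("line integrals match hand-computed chords", {
  mat <- material("m", 1, mu = 0.3)              # 0.3 /cm = 0.03 /mm
  ph <- uniform_cyl(radius = 75, mu = 0.3)
  src <- c(0, 1000, 0)
  # central ray: chord 150 mm at 0.03 /mm
  expect_equal(line_integral(ph, src, c(0, -500, 0)), 4.5)
  # two-region chord superposition: 100 mm at 0.03 + 50 mm at 0.02
  ph2 <- phantom(list(
    cylinder_element(0, 0, 75, -75, 75, mat),
    cylinder_element(0, 0, 25, -75, 75, material("m2", 1, mu = 0.2), 2L)))
  expect_equal(line_integral(ph2, src, c(0, -500, 0)), 4.0)
  # ray missing every element
  expect_equal(line_integral(ph, src, c(200, -500, 0)), 0)
})

test_that("oblique line integrals agree with the analytic chord formula", {
  ph <- uniform_cyl(radius = 75, mu = 0.3)
  src <- c(0, 1000, 0)
  det <- c(90, -500, 0)
  d <- det - src
  # impact parameter of the ray to the cylinder axis
  b <- abs(src[1] * d[2] - src[2] * d[1]) / sqrt(sum(d^2))
  expect_equal(line_integral(ph, src, det),
               0.03 * 2 * sqrt(75^2 - b^2), tolerance = 1e-12)
})

test_that("line integrals agree with dense numerical sampling of mu", {
  ph <- build_simple_phantom()
  src <- c(0, 1000, 0)
  det <- c(90, -500, 30)
  got <- line_integral(ph, src, det)
  # midpoint-rule oracle over a t-bracket that contains the phantom
  d <- det - src
  n <- 4e6
  t_mid <- seq(0.55, 0.80, length.out = n + 1)
  t_mid <- (t_mid[-1] + t_mid[-(n + 1)]) / 2
  pts <- cbind(src[1] + t_mid * d[1], src[2] + t_mid * d[2], src[3] + t_mid * d[3])
  dl <- (0.80 - 0.55) / n * sqrt(sum(d^2))
  oracle <- sum(mu_at(ph, pts) / 10) * dl
  # nothing outside the bracket
  t_out <- c(0.2, 0.5, 0.85, 0.99)
  expect_true(all(mu_at(ph, cbind(src[1] + t_out * d[1], src[2] + t_out * d[2],
                                  src[3] + t_out * d[3])) == 0))
  expect_equal(got, oracle, tolerance = 1e-6)
})

test_that("primary projections follow the exponential law", {
  g <- tiny_geometry()
  pr <- project_primary(phantom(), g, angle = 0, i0 = 2.5)
  expect_true(all(pr$primary == 2.5))
  ph1 <- uniform_cyl(mu = 0.15)
  ph2 <- uniform_cyl(mu = 0.30)
  p1 <- project_primary(ph1, g, 0)
  p2 <- project_primary(ph2, g, 0)
  # doubling mu squares every transmission factor
  expect_equal(p2$primary, p1$primary^2, tolerance = 1e-12)
  expect_equal(p1$primary, exp(-p1$line_integral))
})

test_that("projection geometry is consistent across gantry angles", {
  g <- tiny_geometry()
  ph <- uniform_cyl()
  p0 <- project_primary(ph, g, 0)$primary
  # a coaxial cylinder projects identically at every angle
  for (a in c(37, 90, 215)) {
    expect_equal(project_primary(ph, g, a)$primary, p0, tolerance = 1e-9)
  }
  # an off-centre insert is view-dependent
  ph_off <- phantom(list(cylinder_element(40, 0, 20, -75, 75,
                                          material("m", 1, mu = 0.3))))
  expect_gt(max(abs(project_primary(ph_off, g, 90)$primary -
                      project_primary(ph_off, g, 0)$primary)), 1e-3)
})
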