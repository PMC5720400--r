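test_that("default material table is consistent", {
  m <- default_materials()
  for (mat in m) {
    expect_gt(mat$density, 0)
    expect_gte(mat$mu, 0)
  }
  expect_equal(m$pmma$mu, 1.19 * 0.2351)
  expect_error(material("bad", density = 0, mu = 1), "density")
  expect_error(material("bad", density = 1), "mu")
})

test_that("simple phantom resolves materials by position and priority", {
  ph <- build_simple_phantom()
  m <- default_materials()
  expect_equal(mu_at(ph, c(0, 0, 0)), m$paraffin$mu)
  expect_equal(mu_at(ph, c(50, 0, 0)), m$pmma$mu)
  expect_equal(mu_at(ph, c(0, 0, 100)), 0)   # beyond the 75 mm half-length
  # half-open boundary convention: r < R
  expect_equal(mu_at(ph, c(25, 0, 0)), m$pmma$mu)
  expect_equal(mu_at(ph, c(75, 0, 0)), 0)
  expect_error(build_simple_phantom(materials = list()), "material table")
})

test_that("lung-n-bone phantom places its inserts as configured", {
  ph <- build_lung_bone_phantom()
  m <- default_materials()
  expect_equal(mu_at(ph, c(0, -25, 0)), m$teflon$mu)
  expect_equal(mu_at(ph, c(40, 0, 0)), m$polyurethane$mu)
  expect_equal(mu_at(ph, c(-40, 0, 0)), m$polyurethane$mu)
  expect_equal(mu_at(ph, c(40, 0, 60)), m$pmma$mu)  # beyond the 45 mm lung half-length
  expect_equal(mu_at(ph, c(0, 40, 0)), m$pmma$mu)
})

test_that("inserted cross-sectional area matches the overridden PMMA area", {
  ph <- build_lung_bone_phantom()
  m <- default_materials()
  h <- 0.25
  xs <- seq(-76, 76, by = h)
  pts <- cbind(rep(xs, times = length(xs)), rep(xs, each = length(xs)), 0)
  mu <- mu_at(ph, pts)
  inserted <- sum(mu != m$pmma$mu & mu != 0) * h^2
  expect_equal(inserted, pi * (2 * 25^2 + 10^2), tolerance = 1e-2)
})

test_that("attenuation is rotation-invariant about a coaxial phantom's axis", {
  ph <- build_simple_phantom()
  r <- c(10, 40, 70)
  for (th in c(0.3, 1.2, 2.5)) {
    expect_equal(mu_at(ph, cbind(r * cos(th), r * sin(th), 0)),
                 mu_at(ph, cbind(r, 0, 0)))
  }
})

test_that("empty phantoms and nested priorities behave", {
  expect_equal(mu_at(phantom(), cbind(c(0, 10), c(0, 0), c(0, 0))), c(0, 0))
  inner <- cylinder_element(0, 0, 10, -10, 10, material("in", 1, mu = 0.9), 3L)
  outer <- cylinder_element(0, 0, 20, -10, 10, material("out", 1, mu = 0.1), 1L)
  expect_equal(mu_at(phantom(list(outer, inner)), c(0, 0, 0)), 0.9)
  expect_equal(mu_at(phantom(list(inner, outer)), c(0, 0, 0)), 0.9)
  expect_error(cylinder_element(0, 0, -5, 0, 1, material("m", 1, mu = 0)), "radius")
  expect_error(cylinder_element(0, 0, 5, 1, 0, material("m", 1, mu = 0)), "z_hi")
})

test_that("both phantoms fit the reconstructable field of view", {
  fov_radius <- 300 / 2 * 1000 / 1500   # 100 mm at the isocenter
  for (ph in list(build_simple_phantom(), build_lung_bone_phantom())) {
    for (e in ph$elements) {
      expect_lte(sqrt(e$center_x^2 + e$center_y^2) + e$radius, fov_radius)
    }
  }
})
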