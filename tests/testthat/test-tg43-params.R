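test_that("geometry factor matches limits and the line-integration oracle", {
  # point-source limit is exact
  expect_identical(geometry_factor(2, 45, L = 0), 0.25)
  expect_equal(geometry_factor(c(1, 2, 10), 90, L = 0), c(1, 0.25, 0.01))
  # closed form at the reference point, beta/(L r) with beta = 2 atan(L/2r)
  expect_equal(geometry_factor(1, 90, L = 0.35), 0.98998, tolerance = 1e-5)
  # far-field approach to inverse square (residual ~ L^2/(12 r^2))
  expect_lt(abs(geometry_factor(10, 90, L = 0.35) / 0.01 - 1), 2e-4)
  # numerical line-integration oracle over a grid of points
  for (r in c(0.3, 1, 2.5, 7)) {
    for (th in c(5, 30, 60, 90, 120, 175)) {
      expect_equal(geometry_factor(r, th, L = 0.35),
                   geometry_factor_oracle(r, th, 0.35),
                   tolerance = 1e-6)
    }
  }
  # continuity across the transverse plane and near the long axis
  expect_equal(geometry_factor(1, 90, 0.35), geometry_factor(1, 90 + 1e-7, 0.35),
               tolerance = 1e-9)
  expect_equal(geometry_factor(2, 1e-8, 0.35), 1 / (4 - 0.35^2 / 4),
               tolerance = 1e-6)
  expect_error(geometry_factor(0.1, 0, L = 0.35), "inside the active length")
  expect_error(geometry_factor(-1, 90), "positive")
})

test_that("g(r) is exactly one at r0 and scale-invariant", {
  t <- water_small()
  g <- radial_dose_function(t)
  expect_identical(g$g[g$r_cm == 1], 1)
  expect_identical(g$se[g$r_cm == 1], 0)
  expect_true(all(is.finite(g$g)) && all(g$g > 0))
  # uniform rescaling of the dose grid leaves g untouched
  t2 <- t
  t2$cyl_dose <- t$cyl_dose * 7.3
  t2$cyl_var <- t$cyl_var * 7.3^2
  g2 <- radial_dose_function(t2)
  expect_equal(g2$g, g$g, tolerance = 1e-12)
})

test_that("g(r) shape in water is physically sensible", {
  g <- radial_dose_function(water_1e6())
  # near unity around the normalisation point, decreasing by 10 cm
  expect_lt(abs(g$g[which.min(abs(g$r_cm - 2))] - 1), 0.03)
  g10 <- g$g[which.min(abs(g$r_cm - 10))]
  expect_lt(g10, 0.95)
  expect_gt(g10, 0.75)
})

test_that("anisotropy function is normalised and mirror-symmetric", {
  t <- water_small()
  fr <- anisotropy_function(t, r_list = c(1, 3))
  it0 <- which(fr$theta_values == 90)
  expect_identical(fr$F_matrix[, it0], c(1, 1))
  expect_identical(fr$F_se[, it0], c(0, 0))
  # mirror symmetry about the transverse plane within 3 combined SE
  sel <- which(fr$theta_values > 20 & fr$theta_values < 89)
  mir <- length(fr$theta_values) + 1 - sel
  z <- abs(fr$F_matrix[2, sel] - fr$F_matrix[2, mir]) /
    sqrt(fr$F_se[2, sel]^2 + fr$F_se[2, mir]^2)
  expect_gt(mean(z < 3, na.rm = TRUE), 0.95)
  # scale invariance, as for g
  t2 <- t
  t2$cyl_dose <- t$cyl_dose * 0.42
  t2$cyl_var <- t$cyl_var * 0.42^2
  fr2 <- anisotropy_function(t2, r_list = c(1, 3))
  expect_equal(fr2$F_matrix, fr$F_matrix, tolerance = 1e-12)
})

test_that("bone anisotropy flattens with distance from the source", {
  fb <- anisotropy_function(bone_1e6(), r_list = c(1, 3, 5, 10))
  m <- f_flatness(fb)
  # pronounced near the source, drifting toward a point source far away
  expect_gt(m[1], m[4])
  expect_true(all(diff(m) < 0.01))  # monotone trend within noise
})

test_that("long-format anisotropy table is consistent", {
  fr <- anisotropy_function(water_small(), r_list = c(1, 5))
  df <- as.data.frame(fr)
  expect_equal(nrow(df), 2 * length(fr$theta_values))
  expect_equal(df$F[df$r_cm == 5 & df$theta_deg == 90], 1)
})

test_that("reference comparison interpolates and summarises", {
  g <- radial_dose_function(water_small())
  ref <- data.frame(r_cm = c(0.3, 1, 5, 11), g = c(0.99, 1, 0.96, 0.85))
  cmp <- compare_radial_to_reference(g, ref)
  expect_true(all(cmp$r_cm >= 0.5 & cmp$r_cm <= 10))
  expect_equal(cmp$ratio, cmp$g / cmp$g_ref)
  expect_equal(attr(cmp, "max_abs_rel_diff"), max(abs(cmp$ratio - 1)))
})
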