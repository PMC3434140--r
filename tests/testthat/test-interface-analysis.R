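test_that("a tally compared with itself gives zero difference", {
  t <- water_small()
  for (m in c("normalized_at_r0", "pointwise_relative")) {
    cp <- compare_profiles(t, t, positions = 2:8, mode = m)
    expect_true(all(cp$rel_diff == 0))
    expect_true(all(cp$se >= 0))
    expect_true(all(diff(cp$position_cm) > 0))
  }
})

test_that("pointwise profile differences are antisymmetric under swap", {
  a <- water_small()
  b <- cached_tally("water_4e5_b", "water", 4e5, 207)
  ab <- compare_profiles(a, b, positions = 2:8, mode = "pointwise_relative")
  ba <- compare_profiles(b, a, positions = 2:8, mode = "pointwise_relative")
  # exact antisymmetry holds to first order; allow combined noise plus the
  # quadratic term of the differing denominators
  tol <- 3 * sqrt(ab$se^2 + ba$se^2) + 0.02 * abs(ab$rel_diff) + 0.05
  expect_true(all(abs(ab$rel_diff + ba$rel_diff) < tol))
})

test_that("incompatible grids and bad positions are rejected", {
  t <- water_small()
  small_box <- run_simulation(source_spec(),
                              phantom_preset("water", half_size_cm = 10),
                              1e4, seed = 5)
  expect_error(compare_profiles(t, small_box), "grids differ")
  expect_error(compare_profiles(t, t, positions = c(3, 2)), "increasing")
})

test_that("contours of an exact inverse-square field are circles", {
  x <- seq(-125, 125, by = 1) / 10
  xc <- (x[-1] + x[-length(x)]) / 2
  field <- outer(xc, xc, function(a, b) 1 / (a^2 + b^2))
  lev2 <- 1 / 4   # value at r = 2
  cl <- irbrachy:::contour_polylines(xc, xc, field, lev2)
  rr <- sqrt(cl$x_cm^2 + cl$y_cm^2)
  expect_gt(nrow(cl), 20)
  expect_lt(max(abs(rr - 2)), 0.05)
  # nesting: higher levels lie strictly inside lower ones
  cl_all <- irbrachy:::contour_polylines(xc, xc, field, c(1 / 4, 1 / 16))
  r_hi <- sqrt(cl_all$x_cm[cl_all$level == 1 / 4]^2 +
                 cl_all$y_cm[cl_all$level == 1 / 4]^2)
  r_lo <- sqrt(cl_all$x_cm[cl_all$level == 1 / 16]^2 +
                 cl_all$y_cm[cl_all$level == 1 / 16]^2)
  expect_lt(max(r_hi), min(r_lo))
})

test_that("simulated water isodoses are symmetric about both axes", {
  t <- water_1e6()
  ct <- isodose_contours(t, levels = 0.25, smooth = TRUE)
  expect_gt(nrow(ct), 10)
  expect_lt(abs(mean(range(ct$x_cm))), 0.15)
  expect_lt(abs(mean(range(ct$z_cm))), 0.15)
  # mildly elliptical: pellet self-absorption trims the dose along the
  # source axis, so the contour is a touch wider than tall
  w <- diff(range(ct$x_cm)); h <- diff(range(ct$z_cm))
  expect_gt(w / h, 0.95)
  expect_lt(w / h, 1.35)
  expect_error(isodose_contours(t, levels = numeric(0)), "levels")
})

test_that("lung side of an interface contour is smaller near the source", {
  th <- water_1e6()
  ti <- water_lung_1e6()
  ref <- profile_dose_at(th, -1)$dose
  ct <- isodose_contours(ti, levels = 0.5, ref_dose = ref, smooth = TRUE)
  # reduced scatter beyond the interface pulls the contour inward on +x
  expect_lt(max(ct$x_cm), abs(min(ct$x_cm)))
})

test_that("transverse-axis profile shows deficit then attenuation crossover", {
  # two effects compete along the axis into the lung: just past the
  # interface the lost backscatter lowers the interface-phantom dose;
  # deeper, the lung's lower attenuation raises it above the homogeneous
  # dose.  The crossover is fast for bone (large attenuation contrast).
  th <- water_1e6(); ti <- water_lung_1e6()
  near <- compare_profiles(th, ti, positions = c(2, 2.5, 3),
                           mode = "pointwise_relative")
  z_near <- mean(near$rel_diff) / (sqrt(sum(near$se^2)) / nrow(near))
  expect_gt(z_near, 0)    # backscatter-deficit window
  far <- compare_profiles(th, ti, positions = c(8, 9, 10),
                          mode = "pointwise_relative")
  z_far <- mean(far$rel_diff) / (sqrt(sum(far$se^2)) / nrow(far))
  expect_lt(z_far, -2)    # attenuation gain dominates at depth

  tb <- bone_1e6(); tbl <- bone_lung_1e6()
  farb <- compare_profiles(tb, tbl, positions = c(8, 9, 10),
                           mode = "pointwise_relative")
  z_farb <- mean(farb$rel_diff) / (sqrt(sum(farb$se^2)) / nrow(farb))
  expect_lt(z_farb, -3)
})

test_that("film-plane differences are positive and grow with distance", {
  fp <- interface_film_profile(water_1e6(), water_lung_1e6(), r_values = 2:9)
  expect_true(all(fp$rel_diff > 0))
  expect_gt(mean(fp$rel_diff[fp$r_cm > 6]), mean(fp$rel_diff[fp$r_cm < 4]))
})
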