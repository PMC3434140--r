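test_that("noiseless readings reproduce the tally exactly", {
  t <- water_small()
  ms <- generate_readings(t, noise_cv = 0, seed = 1)
  expect_identical(ms$readings, ms$true_dose)
  rep <- agreement_report(ms, t)
  expect_true(all(rep$per_point$ratio == 1))
  expect_equal(rep$summary$mean_ratio, 1)
  expect_equal(rep$summary$max_abs_deviation, 0)
})

test_that("noise model is unbiased with the stated coefficient of variation", {
  t <- water_small()
  pts <- data.frame(r_cm = rep(3, 4000), theta_deg = 90)
  ms <- generate_readings(t, pts, noise_cv = 0.03, n_repeats = 3, seed = 9)
  ratio <- ms$readings / ms$true_dose
  # averaging three repeats shrinks the CV by sqrt(3)
  expect_lt(abs(sd(ratio) / (0.03 / sqrt(3)) - 1), 0.10)
  expect_lt(abs(mean(ratio) - 1), 3 * sd(ratio) / sqrt(length(ratio)))
  # bit-exact reproducibility
  ms2 <- generate_readings(t, pts, noise_cv = 0.03, n_repeats = 3, seed = 9)
  expect_identical(ms$repeats, ms2$repeats)
})

test_that("readings fail cleanly outside the scored region", {
  t <- water_small()
  expect_error(generate_readings(t, data.frame(r_cm = 50, theta_deg = 90)),
               "outside")
  expect_error(generate_readings(t, default_measurement_points(),
                                 noise_cv = -1), "noise_cv")
})

test_that("linearity fit recovers exact, noisy and degenerate responses", {
  doses <- c(3, 15, 30, 60, 120)   # design range of the dose-response study
  fit <- linearity_fit(doses, 2.5 * doses)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$slope, 2.5, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-9)
  # constant readings carry no explained variance
  expect_equal(linearity_fit(doses, rep(7, 5))$r_squared, 0)
  expect_error(linearity_fit(c(3, 120), c(1, 2)), "3 distinct")
  # 1% multiplicative noise keeps the determination coefficient above 0.999
  r2 <- with_seed_local(42, replicate(50, {
    y <- doses * exp(rnorm(5, 0, 0.01))
    linearity_fit(doses, y)$r_squared
  }))
  expect_gt(median(r2), 0.999)
})

test_that("agreement ratios have calibrated coverage under known noise", {
  t <- water_small()
  pts <- default_measurement_points()
  cover <- with_seed_local(7, {
    unlist(lapply(1:15, function(s) {
      ms <- generate_readings(t, pts, noise_cv = 0.03, n_repeats = 3,
                              seed = 1000 + s)
      rep <- agreement_report(ms, t)
      abs(rep$per_point$ratio - 1) < 2 * rep$per_point$se_ratio
    }))
  })
  expect_gt(mean(cover), 0.90)
  expect_lt(mean(cover), 0.999)
})

test_that("cross-media comparison diverges with depth", {
  msw <- generate_readings(water_1e6(),
                           data.frame(r_cm = c(1, 10), theta_deg = 90),
                           noise_cv = 0, seed = 1)
  rep <- agreement_report(msw, bone_1e6())
  dev <- abs(rep$per_point$ratio - 1)
  expect_gt(dev[rep$per_point$r_cm == 10], dev[rep$per_point$r_cm == 1])
})
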