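test_that("default spectrum holds the five printed lines exactly", {
  sp <- default_ir192_spectrum()
  expect_equal(nrow(sp), 5)
  expect_equal(sp$probability[sp$energy_keV == 317], 0.4096)
  expect_equal(sum(sp$probability), 1, tolerance = 1e-12)
  # hand-computed probability-weighted mean of the five lines
  expect_equal(sum(sp$energy_keV * sp$probability), 366.29, tolerance = 1e-4)
})

test_that("source_spec validates its invariants", {
  expect_s3_class(source_spec(), "source_spec")
  expect_error(source_spec(active_length_cm = 0), "active_length")
  expect_error(source_spec(axis = c(0, 0, 2)), "unit vector")
  bad <- data.frame(energy_keV = c(100, 200), probability = c(0.6, 0.5))
  expect_error(source_spec(spectrum = bad), "sum to 1")
})

test_that("sampled emissions follow the spectrum, cylinder and isotropy", {
  spec <- source_spec()
  em <- sample_emissions(spec, 1e6, seed = 7)

  # empirical line fractions: chi-square GOF not rejected at alpha = 0.001
  obs <- table(factor(em$energy_keV, levels = spec$spectrum$energy_keV))
  gof <- chisq.test(obs, p = spec$spectrum$probability)
  expect_gt(gof$p.value, 0.001)

  # 317 keV line within 3 binomial standard errors of 0.4096
  p <- 0.4096
  se3 <- 3 * sqrt(p * (1 - p) / nrow(em))
  expect_lt(abs(mean(em$energy_keV == 317) - p), se3)

  # positions uniform inside the stated active cylinder
  sub <- em[1:1e5, ]
  expect_true(all(sqrt(sub$x^2 + sub$y^2) <= 0.03 + 1e-12))
  expect_true(all(abs(sub$z) <= 0.175 + 1e-12))
  expect_lt(abs(mean(sub$z)), 3 * 0.35 / sqrt(12) / sqrt(nrow(sub)))

  # directional isotropy: mean direction vector norm below the 3-sigma bound
  mdir <- c(mean(sub$ux), mean(sub$uy), mean(sub$uz))
  expect_lt(sqrt(sum(mdir^2)), 4 / sqrt(nrow(sub)))
  expect_equal(sqrt(sub$ux^2 + sub$uy^2 + sub$uz^2), rep(1, nrow(sub)),
               tolerance = 1e-12)
})

test_that("degenerate one-line spectrum and seeding contracts hold", {
  mono <- source_spec(spectrum = data.frame(energy_keV = 400,
                                            probability = 1))
  em <- sample_emissions(mono, 100, seed = 1)
  expect_true(all(em$energy_keV == 400))

  a <- sample_emissions(source_spec(), 5000, seed = 11)
  b <- sample_emissions(source_spec(), 5000, seed = 11)
  expect_identical(a, b)
  c <- sample_emissions(source_spec(), 5000, seed = 12)
  expect_false(identical(a, c))

  expect_error(sample_emissions(source_spec(), 0), "positive")
})

test_that("sampling does not disturb the caller's RNG stream", {
  set.seed(99)
  x1 <- runif(1)
  set.seed(99)
  invisible(sample_emissions(source_spec(), 10, seed = 5))
  x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("source config round-trips through YAML", {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  spec <- source_spec()
  write_source_config(spec, f)
  back <- read_source_config(f)
  expect_equal(back$active_length_cm, spec$active_length_cm)
  expect_equal(back$spectrum$probability, spec$spectrum$probability)
  expect_equal(back$spectrum$energy_keV, spec$spectrum$energy_keV)
})
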