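test_that("a photon in a non-interacting medium escapes untouched", {
  ev <- transport_one(317, c(0, 0, 0), c(1, 0, 0), phantom_preset("water"),
                      seed = 3, disable_interactions = TRUE)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$channel, 5)
  expect_equal(sum(ev$energy_transferred_keV), 0)
})

test_that("primary transmission matches the closed-form attenuation oracle", {
  ph <- phantom_preset("water")
  n <- 2e4
  ev <- transport_events(317, c(0, 0, 0), c(1, 0, 0), ph, n = n, seed = 17)
  first <- ev[!duplicated(ev$id), ]
  # photon counts as uncollided past 5 cm if its first real interaction (or
  # escape) lies at x >= 5
  reached <- mean(first$x >= 5)
  p <- exp(-mu_total(load_material("water"), 317) * 5)
  expect_lt(abs(reached - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("Compton kinematics and the Klein-Nishina sampler are correct", {
  ph <- phantom_preset("water")
  ev <- transport_events(317, c(0, 0, 0), c(0, 1, 0), ph, n = 2e4, seed = 23)
  sc <- ev[ev$channel == 2, ]
  e_in <- sc$energy_transferred_keV + sc$energy_after_keV
  # kinematic bounds on the scattered energy at every collision
  emin <- e_in / (1 + 2 * e_in / 510.99895)
  expect_true(all(sc$energy_after_keV >= emin - 1e-9))
  expect_true(all(sc$energy_after_keV <= e_in + 1e-9))
  # mean scattered fraction at 317 keV against the quadrature oracle
  f317 <- sc$energy_after_keV[abs(e_in - 317) < 1e-9] / 317
  mu_hat <- mean(f317)
  mu_ref <- kn_mean_scattered_fraction(317)
  expect_lt(abs(mu_hat - mu_ref), 3 * sd(f317) / sqrt(length(f317)))
})

test_that("fixed seeds reproduce tallies bit-identically", {
  ph <- phantom_preset("water")
  a <- run_simulation(source_spec(), ph, 5e4, seed = 31)
  b <- run_simulation(source_spec(), ph, 5e4, seed = 31)
  expect_identical(a$cyl_dose, b$cyl_dose)
  expect_identical(a$plane_dose, b$plane_dose)
  c <- run_simulation(source_spec(), ph, 5e4, seed = 32)
  expect_false(identical(a$cyl_dose, c$cyl_dose))
})

test_that("analog transport conserves energy exactly", {
  for (pn in c("water", "bone_lung")) {
    t <- run_simulation(source_spec(), phantom_preset(pn), 5e4, seed = 41,
                        estimator = "analog")
    closure <- (t$total_emitted_energy - t$total_deposited_energy -
                  t$total_escaped_energy) / t$total_emitted_energy
    expect_lt(abs(closure), 1e-6)
  }
})

test_that("track-length and analog estimators agree bin by bin", {
  tl <- water_small()
  an <- cached_tally("water_analog_4e5", "water", 4e5, 107,
                     estimator = "analog")
  it0 <- which.min(abs(tl$theta_centers - 90))
  d1 <- tl$cyl_dose[, it0]; s1 <- sqrt(tl$cyl_var[, it0])
  d2 <- an$cyl_dose[, it0]; s2 <- sqrt(an$cyl_var[, it0])
  ok <- d1 > 0 & d2 > 0 & s1 / d1 < 0.2 & s2 / d2 < 0.2
  expect_gt(sum(ok), 20)
  z <- abs(d1[ok] - d2[ok]) / sqrt(s1[ok]^2 + s2[ok]^2)
  expect_gt(mean(z < 3.5), 0.9)
  expect_true(all(z < 5))
})

test_that("homogeneous tallies are mirror-symmetric about the source plane", {
  t <- water_small()
  nth <- length(t$theta_centers)
  ir <- which(t$r_centers > 0.5 & t$r_centers < 6)
  it <- which(t$theta_centers > 30 & t$theta_centers < 89)
  mirror <- nth + 1 - it   # theta grid is symmetric about 90 degrees
  z <- abs(t$cyl_dose[ir, it] - t$cyl_dose[ir, mirror]) /
    sqrt(t$cyl_var[ir, it] + t$cyl_var[ir, mirror])
  expect_gt(mean(z < 3), 0.97)
})

test_that("without interactions the transverse dose obeys inverse square", {
  src <- source_spec(active_length_cm = 1e-3, active_diameter_cm = 1e-3)
  t <- run_simulation(src, phantom_preset("water"), 2e5, seed = 53,
                      disable_interactions = TRUE)
  # bins whose geometric centers are exactly at the checkpoint radii
  d <- dose_at(t, c(1, 2, 4, 8))
  v <- d$dose * d$r_cm^2
  rel_se <- d$se / d$dose
  z <- abs(v / mean(v) - 1) / rel_se
  expect_true(all(z < 4))
  expect_lt(max(abs(v / mean(v) - 1)), 0.02)
})

test_that("standard errors shrink with the square root of history count", {
  t1 <- cached_tally("water_1e5_se", "water", 1e5, 61)
  t4 <- water_small()  # 4e5 histories
  r1 <- relative_standard_error(t1, 5)
  r4 <- relative_standard_error(t4, 5)
  expect_gt(r1 / r4, 1.4)
  expect_lt(r1 / r4, 2.9)
})

test_that("empty bins signal insufficient statistics", {
  t <- run_simulation(source_spec(), phantom_preset("water"), 200, seed = 71,
                      estimator = "analog")
  expect_error(relative_standard_error(t, 0.11, 0.5), "insufficient|empty")
})

test_that("invalid transport arguments are rejected", {
  expect_error(run_simulation(source_spec(), phantom_preset("water"), 0),
               "n_histories")
  expect_error(run_simulation(source_spec(), phantom_preset("water"), 10,
                              cutoff_kev = 1), "cutoff")
  expect_error(run_simulation(source_spec(), phantom_preset("water"), 10,
                              estimator = "magic"), "arg")
  expect_error(transport_one(Inf, c(0, 0, 0), c(1, 0, 0),
                             phantom_preset("water")), "corrupted|finite")
})
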