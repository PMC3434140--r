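mats <- material_library()

test_that("packaged tables satisfy their structural invariants", {
  expect_equal(mats$water$density, 1.00)
  expect_equal(mats$bone_cortical$density, 1.92)
  expect_equal(mats$lung_inflated$density, 0.26)
  for (m in mats) {
    t <- m$table
    expect_gte(nrow(t), 25)
    expect_lte(min(t$energy_keV), 10)
    expect_gte(max(t$energy_keV), 700)
    ch_sum <- t$mu_over_rho_pe + t$mu_over_rho_incoh + t$mu_over_rho_coh
    expect_lt(max(abs(ch_sum / t$mu_over_rho_total - 1)), 0.01)
    expect_true(all(t$mu_en_over_rho <= t$mu_over_rho_total))
  }
  # water total decreases monotonically over 100-700 keV
  w <- mats$water$table
  sel <- w$energy_keV >= 100 & w$energy_keV <= 700
  expect_true(all(diff(w$mu_over_rho_total[sel]) < 0))
})

test_that("interpolation reproduces nodes exactly and is monotone between", {
  w <- mats$water
  # 300 keV is a grid node: no interpolation
  node <- w$table$mu_over_rho_total[w$table$energy_keV == 300]
  expect_equal(mu_total(w, 300), node * w$density, tolerance = 1e-12)
  # geometric midpoint lies between the bracketing nodes
  e <- w$table$energy_keV
  i <- which(e == 200)
  mid <- sqrt(e[i] * e[i + 1])
  v <- mu_total(w, mid)
  expect_true(v < mu_total(w, e[i]) && v > mu_total(w, e[i + 1]))
  # pure lookup: identical calls give identical values
  expect_identical(mu_total(w, 123.4), mu_total(w, 123.4))
  expect_error(mu_total(w, 5), "outside")
  expect_error(mu_total(w, 1000), "outside")
})

test_that("lung attenuates less than water at every tabulated energy", {
  e <- mats$water$table$energy_keV
  expect_true(all(mu_total(mats$lung_inflated, e) < mu_total(mats$water, e)))
})

test_that("channel probabilities are normalised and physically ordered", {
  p <- channel_probabilities(mats$water, 317)
  expect_equal(rowSums(p), 1, tolerance = 1e-9)
  expect_true(all(p >= 0))
  # incoherent scattering dominates water at the main emission line
  expect_true(p$p_incoherent > p$p_photoelectric &&
                p$p_incoherent > p$p_coherent)
  # photoelectric falls steeply with energy in bone
  pb <- channel_probabilities(mats$bone_cortical, c(30, 300))
  expect_gt(pb$p_photoelectric[1], pb$p_photoelectric[2])
})

test_that("material aliases resolve and unknown names fail", {
  expect_equal(load_material("bone")$name, "bone_cortical")
  expect_equal(load_material("lung")$name, "lung_inflated")
  expect_error(load_material("steel"), "unknown material")
})
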