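# Shared simulation fixtures, built lazily and cached for the whole test run
# so the heavier Monte Carlo runs are paid for once.

.tally_cache <- new.env(parent = emptyenv())

cached_tally <- function(key, phantom_name, n, seed, ...) {
  if (!exists(key, envir = .tally_cache)) {
    assign(key,
           run_simulation(source_spec(), phantom_preset(phantom_name),
                          n_histories = n, seed = seed, ...),
           envir = .tally_cache)
  }
  get(key, envir = .tally_cache)
}

water_1e6 <- function() cached_tally("water_1e6", "water", 1e6, 101)
bone_1e6 <- function() cached_tally("bone_1e6", "bone", 1e6, 102)
lung_1e6 <- function() cached_tally("lung_1e6", "lung", 1e6, 103)
water_lung_1e6 <- function() cached_tally("wl_1e6", "water_lung", 1e6, 104)
bone_lung_1e6 <- function() cached_tally("bl_1e6", "bone_lung", 1e6, 105)
water_small <- function() cached_tally("water_4e5", "water", 4e5, 106)
water_1e7 <- function() cached_tally("water_1e7", "water", 1e7, 108)

# mean |F - 1| over a polar band, excluding the normalisation bin
f_flatness <- function(fr, band = c(20, 160)) {
  sel <- fr$theta_values >= band[1] & fr$theta_values <= band[2]
  rowMeans(abs(fr$F_matrix[, sel, drop = FALSE] - 1), na.rm = TRUE)
}

# run code under a local seed, restoring the ambient RNG state
with_seed_local <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

# independent Klein-Nishina oracle: mean scattered-energy fraction at energy
# e_kev, by numerical quadrature of the differential cross section
kn_mean_scattered_fraction <- function(e_kev) {
  a <- e_kev / 510.99895
  dsdc <- function(c) {
    f <- 1 / (1 + a * (1 - c))         # E'/E
    f^2 * (f + 1 / f - (1 - c^2))
  }
  num <- integrate(function(c) dsdc(c) / (1 + a * (1 - c)), -1, 1,
                   rel.tol = 1e-10)$value
  den <- integrate(dsdc, -1, 1, rel.tol = 1e-10)$value
  num / den
}

# independent geometry-factor oracle: numerical line integration over the
# active length
geometry_factor_oracle <- function(r, theta_deg, L) {
  th <- theta_deg * pi / 180
  px <- r * sin(th); pz <- r * cos(th)
  integrate(function(l) 1 / (px^2 + (pz - l)^2), -L / 2, L / 2,
            rel.tol = 1e-12)$value / L
}
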