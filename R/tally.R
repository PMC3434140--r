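# Dose tally container: cylindrical (r, theta) grid around the source,
# transverse-axis profile, and a planar slab grid through the source
# transverse axis.

# Default scoring grids.  Radial bins are log-spaced (8 bins per factor of
# two) with geometric centers exactly at ... 0.5, 1, 2, 4 ... cm so that
# dose ratios at the classic checkpoint radii are read from bins centred on
# them; a final bin extends to the cube face so that r = 12 cm is covered.
# Polar bins are 2 degrees wide with 90 degrees a bin *center* (the TG-43
# normalisation angle must not sit on a bin edge).
default_grids <- function(half_size_cm = 12.5) {
  r_edges <- c(2^(seq(-27.5, 28.5, by = 1) / 8), half_size_cm)
  theta_edges <- c(0, seq(1, 179, by = 2), 180)
  list(
    r_edges = r_edges,
    theta_edges = theta_edges,
    profile_edges = seq(-1275, 1275, by = 50) / 100,
    profile_radius = 0.3,
    plane_edges = seq(-125, 125, by = 1) / 10,
    slab_half = 0.25,
    # "film" tally: thin slab just upstream of the default interface plane,
    # scored in annular rings about the transverse (x) axis -- emulates a
    # radiochromic film placed at the slab interface
    film_x_range = c(0.8, 1.0),
    film_rho_edges = seq(0, 124, by = 4) / 10
  )
}

bin_centers_log <- function(edges) sqrt(edges[-length(edges)] * edges[-1])
bin_centers_lin <- function(edges) (edges[-length(edges)] + edges[-1]) / 2

# Mass (g) of every cylindrical (r, theta) bin, profile bin and plane pixel,
# honouring a planar interface at x = d (normal +x, region 2 beyond).
# Interface-straddling cylindrical bins are integrated numerically via the
# azimuthal-fraction formula.
tally_bin_masses <- function(phantom, grids) {
  rho1 <- phantom$materials[[1]]$density
  rho2 <- if (length(phantom$materials) == 2) phantom$materials[[2]]$density else rho1
  d <- phantom$interface_offset_cm   # NULL for homogeneous

  re <- grids$r_edges; te <- grids$theta_edges * pi / 180
  nr <- length(re) - 1; nt <- length(te) - 1
  vol <- outer((re[-1]^3 - re[-(nr + 1)]^3) / 3,
               cos(te[-(nt + 1)]) - cos(te[-1])) * 2 * pi  # nr x nt
  if (is.null(d)) {
    cyl_mass <- vol * rho1
  } else {
    # fraction of each bin's volume beyond the plane x = d
    frac <- matrix(0, nr, nt)
    nsub <- 8
    for (i in seq_len(nr)) {
      rmid <- exp(seq(log(re[i]), log(re[i + 1]), length.out = 2 * nsub + 1))
      rmid <- rmid[seq(2, 2 * nsub, by = 2)]
      drr <- diff(exp(seq(log(re[i]), log(re[i + 1]), length.out = nsub + 1)))
      if (re[i + 1] <= d) next  # wholly on source side
      for (j in seq_len(nt)) {
        tmid <- seq(te[j], te[j + 1], length.out = 2 * nsub + 1)
        tmid <- tmid[seq(2, 2 * nsub, by = 2)]
        dtt <- diff(seq(te[j], te[j + 1], length.out = nsub + 1))
        s <- outer(rmid, sin(tmid))                     # nsub x nsub
        az <- ifelse(s > d, acos(pmin(1, d / s)) / pi, 0)
        integ <- sum((rmid^2 * drr) %*% t(rep(1, nsub)) *
                       outer(rep(1, nsub), sin(tmid) * dtt) * az) * 2 * pi
        frac[i, j] <- integ / vol[i, j]
      }
    }
    cyl_mass <- vol * (rho1 * (1 - frac) + rho2 * frac)
  }

  pe <- grids$profile_edges
  a2 <- pi * grids$profile_radius^2
  half <- phantom$half_size_cm
  seg_mass <- function(lo, hi) {
    lo <- max(lo, -half); hi <- min(hi, half)   # outer bins clip at the cube
    if (hi <= lo) return(NA_real_)
    if (is.null(d)) return(a2 * (hi - lo) * rho1)
    w2 <- pmax(0, hi - pmax(lo, d))
    a2 * ((hi - lo - w2) * rho1 + w2 * rho2)
  }
  prof_mass <- mapply(seg_mass, pe[-length(pe)], pe[-1])

  fe <- grids$film_rho_edges
  fx <- grids$film_x_range
  w2f <- if (is.null(d)) 0 else max(0, fx[2] - max(fx[1], d))
  rho_f <- ((fx[2] - fx[1] - w2f) * rho1 + w2f * rho2) / (fx[2] - fx[1])
  film_mass <- pi * (fe[-1]^2 - fe[-length(fe)]^2) * (fx[2] - fx[1]) * rho_f

  ple <- grids$plane_edges
  npl <- length(ple) - 1
  dz <- diff(ple)
  xw2 <- if (is.null(d)) rep(0, npl) else
    pmax(0, ple[-1] - pmax(ple[-(npl + 1)], d))
  xrho <- ((diff(ple) - xw2) * rho1 + xw2 * rho2) / diff(ple)
  plane_mass <- outer(diff(ple) * xrho, dz) * 2 * grids$slab_half  # x by z

  list(cyl = cyl_mass, profile = prof_mass, plane = plane_mass,
       film = film_mass)
}

new_dose_tally <- function(raw, grids, masses, phantom, source, estimator,
                           seed, cutoff_kev, include_coherent,
                           disable_interactions) {
  B <- raw$batches
  nb <- raw$n_per_batch
  conv <- function(sum, sumsq, mass) {
    dose <- sum / (raw$n_histories * mass)
    # sample variance of the batch totals, then variance of the mean dose
    vb <- (sumsq - sum^2 / B) / max(B - 1, 1)
    list(dose = dose, var = vb / B / (nb * mass)^2)
  }
  cyl <- conv(t(raw$cyl_sum), t(raw$cyl_sumsq), masses$cyl)     # r x theta
  prof <- conv(raw$profile_sum, raw$profile_sumsq, masses$profile)
  plane <- conv(t(raw$plane_sum), t(raw$plane_sumsq), masses$plane)  # x x z
  film <- conv(raw$film_sum, raw$film_sumsq, masses$film)

  structure(list(
    phantom_name = phantom$name,
    interface_offset_cm = phantom$interface_offset_cm,
    estimator = estimator, seed = seed, cutoff_kev = cutoff_kev,
    include_coherent = include_coherent,
    disable_interactions = disable_interactions,
    n_histories = raw$n_histories, batches = B,
    r_edges = grids$r_edges, r_centers = bin_centers_log(grids$r_edges),
    theta_edges = grids$theta_edges,
    theta_centers = bin_centers_lin(grids$theta_edges),
    cyl_dose = cyl$dose, cyl_var = cyl$var,
    profile_edges = grids$profile_edges,
    profile_centers = bin_centers_lin(grids$profile_edges),
    profile_dose = prof$dose, profile_var = prof$var,
    plane_edges = grids$plane_edges,
    plane_centers = bin_centers_lin(grids$plane_edges),
    plane_dose = plane$dose, plane_var = plane$var,
    film_x_range = grids$film_x_range,
    film_rho_edges = grids$film_rho_edges,
    film_rho_centers = bin_centers_lin(grids$film_rho_edges),
    film_dose = film$dose, film_var = film$var,
    total_emitted_energy = raw$total_emitted_energy,
    total_deposited_energy = raw$total_deposited_energy,
    total_escaped_energy = raw$total_escaped_energy,
    n_escaped_photons = raw$n_escaped_photons,
    source = source),
    class = "dose_tally")
}

#' @export
print.dose_tally <- function(x, ...) {
  cat("dose tally:", x$phantom_name, "phantom |",
      format(x$n_histories, big.mark = ","), "histories |",
      x$estimator, "estimator\n")
  cat("grids: ", length(x$r_centers), " r-bins (",
      signif(min(x$r_edges), 3), "-", max(x$r_edges), " cm) x ",
      length(x$theta_centers), " theta-bins; profile ",
      length(x$profile_centers), " bins; plane ",
      nrow(x$plane_dose), "^2 pixels\n", sep = "")
  fesc <- x$total_escaped_energy / x$total_emitted_energy
  cat("energy: ", signif(100 * (1 - fesc), 4), "% deposited, ",
      signif(100 * fesc, 4), "% escaped\n", sep = "")
  invisible(x)
}

find_bin <- function(edges, v) {
  i <- findInterval(v, edges, left.open = FALSE, rightmost.closed = FALSE)
  i[v >= edges[length(edges)]] <- NA_integer_
  i[i == 0] <- NA_integer_
  i
}

#' Dose and uncertainty at a cylindrical tally bin
#'
#' Evaluates the dose of the (r, theta) bin containing each requested point
#' (no smoothing or interpolation).
#'
#' @param tally A `dose_tally` from [run_simulation()].
#' @param r Radial distance(s) from the source center, cm.
#' @param theta Polar angle(s) from the source long axis, degrees
#'   (default 90, the transverse axis).
#' @return Data frame with columns `r_cm`, `theta_deg`, `dose`, `se`
#'   (dose in tally units: keV deposited per gram per emitted photon).
#' @export
dose_at <- function(tally, r, theta = 90) {
  stopifnot(inherits(tally, "dose_tally"))
  n <- max(length(r), length(theta))
  r <- rep_len(r, n); theta <- rep_len(theta, n)
  ir <- find_bin(tally$r_edges, r)
  it <- find_bin(tally$theta_edges, theta)
  if (anyNA(ir) || anyNA(it))
    stop("requested point outside the tally grid", call. = FALSE)
  idx <- cbind(ir, it)
  data.frame(r_cm = r, theta_deg = theta,
             dose = tally$cyl_dose[idx],
             se = sqrt(tally$cyl_var[idx]))
}

#' Relative standard error of a tally bin
#'
#' @inheritParams dose_at
#' @return Fractional standard error(s) (standard error / dose) of the bin
#'   containing each `(r, theta)` point.  Errors if the bin has no score.
#' @export
relative_standard_error <- function(tally, r, theta = 90) {
  d <- dose_at(tally, r, theta)
  if (any(d$dose <= 0))
    stop("insufficient statistics: empty bin at the requested point",
         call. = FALSE)
  d$se / d$dose
}

#' Dose along the transverse measurement axis
#'
#' Dose profile along the signed transverse axis (+x crosses the interface
#' in interface phantoms), scored in a thin cylinder around the axis.
#'
#' @inheritParams dose_at
#' @param x Signed transverse position(s), cm.
#' @return Data frame with columns `x_cm`, `dose`, `se`.
#' @export
profile_dose_at <- function(tally, x) {
  stopifnot(inherits(tally, "dose_tally"))
  i <- find_bin(tally$profile_edges, x)
  if (anyNA(i))
    stop("requested position outside the profile grid", call. = FALSE)
  data.frame(x_cm = x, dose = tally$profile_dose[i],
             se = sqrt(tally$profile_var[i]))
}
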