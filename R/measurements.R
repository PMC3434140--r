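#' Default point-dosimeter measurement layout
#'
#' Dual-radius, multi-angle layout emulating glass-dosimeter point
#' measurements around an HDR source: points at the given radii and polar
#' angles on the source plane.
#'
#' @param radii Measurement radii, cm.
#' @param angles Polar angles, degrees.
#' @return Data frame with columns `r_cm`, `theta_deg`.
#' @export
default_measurement_points <- function(radii = c(3, 5),
                                       angles = seq(10, 170, by = 10)) {
  expand.grid(r_cm = radii, theta_deg = angles, KEEP.OUT.ATTRS = FALSE)
}

#' Generate synthetic point-dose readings
#'
#' Stands in for physical point-dosimeter data: for each measurement point
#' the simulated dose is perturbed by `n_repeats` independent multiplicative
#' log-normal errors with coefficient of variation `noise_cv` (mean-one, so
#' the noise model is unbiased), and the averaged reading is reported.
#' Positive readings and multiplicative error are the natural model for
#' luminescent point dosimetry.
#'
#' @param tally A `dose_tally` supplying the underlying true doses.
#' @param points Data frame with columns `r_cm`, `theta_deg`.
#' @param noise_cv Coefficient of variation of a single reading (>= 0).
#' @param n_repeats Readings averaged per point (>= 1; physical protocols
#'   typically average three).
#' @param seed Integer seed; reproducible bit-exactly.
#' @return An object of class `measurement_set`: list with `points`,
#'   `readings` (per-point averages), `repeats` (matrix of individual
#'   readings), `true_dose`, `noise_cv`, `n_repeats`, `seed`.
#' @export
generate_readings <- function(tally, points = default_measurement_points(),
                              noise_cv = 0.03, n_repeats = 3, seed = 1L) {
  stopifnot(inherits(tally, "dose_tally"), noise_cv >= 0, n_repeats >= 1)
  true <- dose_at(tally, points$r_cm, points$theta_deg)$dose
  if (any(true <= 0))
    stop("tally has no score at a requested measurement point",
         call. = FALSE)
  np <- length(true)
  reps <- with_seed(seed, {
    if (noise_cv == 0) {
      matrix(rep(true, n_repeats), np, n_repeats)
    } else {
      sdlog <- sqrt(log(1 + noise_cv^2))
      matrix(rlnorm(np * n_repeats, meanlog = -sdlog^2 / 2, sdlog = sdlog),
             np, n_repeats) * true
    }
  })
  structure(list(points = points, readings = rowMeans(reps), repeats = reps,
                 true_dose = true, noise_cv = noise_cv,
                 n_repeats = as.integer(n_repeats), seed = seed),
            class = "measurement_set")
}

#' @export
print.measurement_set <- function(x, ...) {
  cat("synthetic measurement set:", nrow(x$points), "points,",
      x$n_repeats, "repeats, noise CV", x$noise_cv, "\n")
  invisible(x)
}

#' Dose-response linearity fit
#'
#' Ordinary least-squares line through reading-versus-delivered-dose pairs,
#' the standard linearity characterisation of a dosimeter over its design
#' dose range.
#'
#' @param doses Delivered dose levels (>= 3 distinct values).
#' @param readings Dosimeter readings, same length.
#' @return List with `slope`, `intercept` and `r_squared`.  A constant
#'   reading yields `r_squared = 0`.
#' @export
#' @examples
#' linearity_fit(c(3, 30, 60, 120), c(3.1, 29.7, 60.4, 119.8))
linearity_fit <- function(doses, readings) {
  stopifnot(length(doses) == length(readings))
  if (length(unique(doses)) < 3)
    stop("need at least 3 distinct dose levels", call. = FALSE)
  fit <- lm(readings ~ doses)
  sst <- sum((readings - mean(readings))^2)
  r2 <- if (sst == 0) 0 else 1 - sum(fit$residuals^2) / sst
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2)
}

#' Measurement-versus-simulation agreement report
#'
#' Per-point reading/simulation dose ratios with combined uncertainty
#' (the noise model's standard error of the averaged reading plus the
#' simulation bin's Monte Carlo standard error), and a summary of mean ratio and maximum
#' absolute deviation from unity.
#'
#' @param measurements A `measurement_set` from [generate_readings()].
#' @param sim A `dose_tally` to compare against.
#' @return An object of class `agreement_report`: list with `per_point`
#'   (data frame `r_cm`, `theta_deg`, `reading`, `sim_dose`, `ratio`,
#'   `se_ratio`) and `summary` (`mean_ratio`, `max_abs_deviation`).
#' @export
agreement_report <- function(measurements, sim) {
  stopifnot(inherits(measurements, "measurement_set"),
            inherits(sim, "dose_tally"))
  pts <- measurements$points
  simd <- dose_at(sim, pts$r_cm, pts$theta_deg)
  if (all(simd$dose <= 0))
    stop("no overlapping points with simulation score", call. = FALSE)
  reading <- measurements$readings
  # model-based standard error: the generator's CV is known, and with only a
  # handful of repeats the empirical spread would be a poor variance estimate
  se_read <- reading * measurements$noise_cv / sqrt(measurements$n_repeats)
  ratio <- reading / simd$dose
  se_ratio <- ratio * sqrt((se_read / reading)^2 +
                             (simd$se / simd$dose)^2)
  per_point <- data.frame(r_cm = pts$r_cm, theta_deg = pts$theta_deg,
                          reading = reading, sim_dose = simd$dose,
                          ratio = ratio, se_ratio = se_ratio)
  structure(list(per_point = per_point,
                 summary = list(
                   mean_ratio = mean(ratio),
                   max_abs_deviation = max(abs(ratio - 1)))),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("measurement/simulation agreement:", nrow(x$per_point), "points\n")
  cat("mean ratio", signif(x$summary$mean_ratio, 5),
      "| max |ratio - 1|", signif(x$summary$max_abs_deviation, 4), "\n")
  invisible(x)
}
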