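#' Dose-difference profile between two phantoms
#'
#' Compares the transverse-axis dose profiles of a homogeneous tally and an
#' interface tally at matched positions, in per cent.  Two normalisation
#' modes are provided because published interface comparisons are usually
#' normalised to the homogeneous dose at 1 cm:
#' `"normalized_at_r0"` (default) reports
#' 100 (D_homog(x) - D_interface(x)) / D_homog(r0);
#' `"pointwise_relative"` reports
#' 100 (D_homog(x) - D_interface(x)) / D_homog(x).
#' Both tallies must share the same grids (run with the same cube size).
#' Uncertainties are propagated from the per-bin Monte Carlo variances.
#'
#' @param homog,interface `dose_tally` objects on identical grids.
#' @param positions Positions along the transverse measurement axis, cm
#'   (positive x crosses the interface).
#' @param mode `"normalized_at_r0"` or `"pointwise_relative"`.
#' @param r0 Normalisation position for the default mode, cm.
#' @return A data frame of class `difference_profile` with columns
#'   `position_cm`, `rel_diff` (per cent), `se` (per cent); attribute
#'   `normalization_mode`.
#' @export
compare_profiles <- function(homog, interface,
                             positions = seq(1, 10, by = 1),
                             mode = c("normalized_at_r0",
                                      "pointwise_relative"),
                             r0 = 1) {
  stopifnot(inherits(homog, "dose_tally"), inherits(interface, "dose_tally"))
  mode <- match.arg(mode)
  if (!isTRUE(all.equal(homog$profile_edges, interface$profile_edges)) ||
      !isTRUE(all.equal(homog$r_edges, interface$r_edges)))
    stop("incompatible tallies: grids differ", call. = FALSE)
  if (is.unsorted(positions, strictly = TRUE))
    stop("positions must be strictly increasing", call. = FALSE)
  a <- profile_dose_at(homog, positions)
  b <- profile_dose_at(interface, positions)
  if (mode == "normalized_at_r0") {
    ref <- profile_dose_at(homog, r0)
    diff <- 100 * (a$dose - b$dose) / ref$dose
    v <- (100 / ref$dose)^2 * (a$se^2 + b$se^2) +
      (diff / ref$dose)^2 * ref$se^2
    se <- sqrt(v)
  } else {
    diff <- 100 * (a$dose - b$dose) / a$dose
    se <- 100 * (b$dose / a$dose) *
      sqrt((a$se / a$dose)^2 + (b$se / b$dose)^2)
  }
  structure(data.frame(position_cm = positions, rel_diff = diff, se = se),
            normalization_mode = mode,
            class = c("difference_profile", "data.frame"))
}

#' Dose-difference profile on the interface (film) plane
#'
#' Emulates the radiochromic-film comparison: dose is read from the "film"
#' tally, a thin slab just upstream of the default interface plane scored in
#' annular rings about the transverse axis, and the homogeneous and
#' interface phantoms are compared at matched distances from the source
#' center.  Points on this plane see the same primary fluence in both
#' phantoms (the ray from the source stays on the source side), so the
#' difference isolates the scatter the lung half fails to return; it is
#' small near the source and grows with distance as the scatter fraction
#' grows.
#'
#' @inheritParams compare_profiles
#' @param r_values Distances from the source center, cm; each is mapped to
#'   the annular film bin containing it.
#' @return A data frame of class `difference_profile` with columns
#'   `r_cm` (bin-center distance), `rel_diff` (per cent of the homogeneous
#'   dose at the same point) and `se`.
#' @export
interface_film_profile <- function(homog, interface, r_values = 1:10) {
  stopifnot(inherits(homog, "dose_tally"), inherits(interface, "dose_tally"))
  if (!isTRUE(all.equal(homog$film_rho_edges, interface$film_rho_edges)))
    stop("incompatible tallies: film grids differ", call. = FALSE)
  xm <- mean(homog$film_x_range)
  rho <- sqrt(pmax(r_values^2 - xm^2, 0))
  i <- find_bin(homog$film_rho_edges, rho)
  if (anyNA(i)) stop("requested distance outside the film grid", call. = FALSE)
  dh <- homog$film_dose[i]; di <- interface$film_dose[i]
  sh <- sqrt(homog$film_var[i]); si <- sqrt(interface$film_var[i])
  if (any(dh <= 0))
    stop("insufficient statistics in the film tally", call. = FALSE)
  diff <- 100 * (dh - di) / dh
  se <- 100 * (di / dh) * sqrt((sh / dh)^2 + (si / di)^2)
  structure(data.frame(
    r_cm = sqrt(xm^2 + homog$film_rho_centers[i]^2),
    rel_diff = diff, se = se),
    normalization_mode = "pointwise_relative",
    class = c("difference_profile", "data.frame"))
}

# marching-squares contour extraction on a regular grid (grDevices backend)
contour_polylines <- function(x, y, z, levels) {
  if (!length(levels) || any(!is.finite(levels)) || any(levels <= 0))
    stop("levels must be positive and non-empty", call. = FALSE)
  cl <- grDevices::contourLines(x = x, y = y, z = z, levels = levels)
  if (!length(cl))
    return(data.frame(level = numeric(0), polyline = integer(0),
                      vertex_index = integer(0), x_cm = numeric(0),
                      y_cm = numeric(0)))
  do.call(rbind, lapply(seq_along(cl), function(i) {
    data.frame(level = cl[[i]]$level, polyline = i,
               vertex_index = seq_along(cl[[i]]$x),
               x_cm = cl[[i]]$x, y_cm = cl[[i]]$y)
  }))
}

#' Isodose contours on the source plane
#'
#' Extracts isodose polylines from the planar tally grid (the plane
#' containing the source transverse axis) by marching squares.  Levels are
#' given as fractions of a reference dose, by default the tally's own
#' transverse-axis dose at x = -r0 (in interface phantoms the -x side is the
#' unperturbed one); pass `ref_dose` from a homogeneous companion tally to
#' normalise the way film measurements are, to the homogeneous dose at 1 cm.
#'
#' @param tally A `dose_tally`.
#' @param levels Contour levels as positive fractions of the reference dose.
#' @param ref_dose Reference dose in tally units, or `NULL` to use the
#'   profile dose at `x = -r0`.
#' @param r0 Reference radius used when `ref_dose` is `NULL`, cm.
#' @param smooth Apply one pass of 3 x 3 box smoothing to the plane grid
#'   before contouring.
#' @return Data frame with columns `level` (fraction), `level_dose`,
#'   `polyline`, `vertex_index`, `x_cm`, `z_cm`.
#' @export
isodose_contours <- function(tally, levels = c(0.5, 0.25, 0.1),
                             ref_dose = NULL, r0 = 1, smooth = FALSE) {
  stopifnot(inherits(tally, "dose_tally"))
  if (is.null(ref_dose)) ref_dose <- profile_dose_at(tally, -r0)$dose
  if (!is.finite(ref_dose) || ref_dose <= 0)
    stop("reference dose is not positive", call. = FALSE)
  z <- tally$plane_dose
  if (smooth) z <- box_smooth3(z)
  out <- contour_polylines(tally$plane_centers, tally$plane_centers, z,
                           levels * ref_dose)
  names(out)[names(out) == "y_cm"] <- "z_cm"
  out$level_dose <- out$level
  out$level <- out$level_dose / ref_dose
  out[, c("level", "level_dose", "polyline", "vertex_index", "x_cm", "z_cm")]
}

box_smooth3 <- function(m) {
  n <- nrow(m); p <- ncol(m)
  pad <- matrix(0, n + 2, p + 2)
  pad[2:(n + 1), 2:(p + 1)] <- m
  cnt <- matrix(0, n + 2, p + 2)
  cnt[2:(n + 1), 2:(p + 1)] <- 1
  acc <- matrix(0, n, p); den <- matrix(0, n, p)
  for (di in 0:2) for (dj in 0:2) {
    acc <- acc + pad[di + 1:n, dj + 1:p]
    den <- den + cnt[di + 1:n, dj + 1:p]
  }
  acc / den
}
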