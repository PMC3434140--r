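#' Phantom materials and photon interaction coefficients
#'
#' The package ships interaction-coefficient tables for the three phantom
#' materials: liquid water (1.00 g/cm3), ICRU-44 cortical bone (1.92 g/cm3)
#' and ICRU-44 inflated lung (0.26 g/cm3).  Each table holds, on a 31-node
#' energy grid covering 10-800 keV, the total mass attenuation coefficient,
#' its photoelectric / incoherent / coherent channel decomposition, and the
#' mass energy-absorption coefficient (all cm2/g).  Totals and
#' energy-absorption values follow the standard NIST compound tables; the
#' channel decomposition is a physically parameterised split (Klein-Nishina
#' incoherent with binding suppression, power-law photoelectric/coherent
#' partition) constrained to sum to the total at every node.  Lookups between
#' nodes use log-log interpolation, standard practice for photon cross
#' sections.
#'
#' @param name One of `"water"`, `"bone"` (alias `"bone_cortical"`),
#'   `"lung"` (alias `"lung_inflated"`).
#' @return `load_material()` returns an object of class `ir_material` with
#'   fields `name`, `density` (g/cm3), `zeff` and `table` (the coefficient
#'   data frame).  `material_library()` returns a named list of all three.
#' @export
#' @examples
#' w <- load_material("water")
#' w$density
#' mu_total(w, 317)
load_material <- function(name) {
  key <- resolve_material_name(name)
  meta <- material_meta()[[key]]
  file <- system.file("extdata", paste0(key, ".csv"), package = "irbrachy",
                      mustWork = TRUE)
  tab <- read.csv(file)
  structure(list(name = key, density = meta$density, zeff = meta$zeff,
                 table = tab),
            class = "ir_material")
}

#' @rdname load_material
#' @export
material_library <- function() {
  out <- lapply(c("water", "bone_cortical", "lung_inflated"), load_material)
  names(out) <- c("water", "bone_cortical", "lung_inflated")
  out
}

material_meta <- function() {
  list(
    water = list(density = 1.00, zeff = 7.42),
    bone_cortical = list(density = 1.92, zeff = 13.8),
    lung_inflated = list(density = 0.26, zeff = 7.49)
  )
}

#' Iridium linear attenuation coefficient
#'
#' Total linear attenuation of metallic iridium (Z = 77, 22.42 g/cm3), used
#' only for primary self-absorption in the source pellet.  The underlying
#' mass coefficients over 100-800 keV are approximate, interpolated in
#' atomic number from the standard tables of neighbouring high-Z elements;
#' energies outside the node range are clamped to the nearest node.
#'
#' @param energy_kev Photon energy, keV (vectorised).
#' @return Linear attenuation coefficient(s), 1/cm.
#' @export
iridium_mu <- function(energy_kev) {
  e <- c(100, 150, 200, 300, 400, 500, 600, 800)
  mu_rho <- c(4.86, 1.75, 0.90, 0.356, 0.210, 0.150, 0.117, 0.0842)
  22.42 * loglog_interp(pmin(pmax(energy_kev, min(e)), max(e)), e, mu_rho)
}

resolve_material_name <- function(name) {
  key <- switch(tolower(name),
                water = "water",
                bone = "bone_cortical", bone_cortical = "bone_cortical",
                lung = "lung_inflated", lung_inflated = "lung_inflated",
                stop("unknown material: ", name, call. = FALSE))
  key
}

#' @export
print.ir_material <- function(x, ...) {
  cat("material:", x$name, "| density", x$density, "g/cm3 |",
      nrow(x$table), "energy nodes",
      min(x$table$energy_keV), "-", max(x$table$energy_keV), "keV\n")
  invisible(x)
}

#' Linear attenuation coefficient
#'
#' Total linear attenuation coefficient, density times the log-log
#' interpolated mass attenuation coefficient.  Energies outside the
#' tabulated range signal an error.
#'
#' @param material An `ir_material` from [load_material()].
#' @param energy_kev Photon energy (keV), vectorised.
#' @return Linear attenuation coefficient(s), 1/cm.
#' @export
#' @examples
#' mu_total(load_material("water"), c(290, 317, 608))
mu_total <- function(material, energy_kev) {
  stopifnot(inherits(material, "ir_material"))
  material$density * loglog_interp(energy_kev, material$table$energy_keV,
                                   material$table$mu_over_rho_total)
}

#' Mass energy-absorption coefficient
#'
#' @inheritParams mu_total
#' @return mu_en/rho value(s), cm2/g.
#' @export
mu_en_mass <- function(material, energy_kev) {
  stopifnot(inherits(material, "ir_material"))
  loglog_interp(energy_kev, material$table$energy_keV,
                material$table$mu_en_over_rho)
}

#' Interaction channel probabilities
#'
#' Probability that a real collision at the given energy is photoelectric,
#' incoherent (Compton) or coherent (Rayleigh); proportional to the partial
#' attenuation coefficients, summing to one.
#'
#' @inheritParams mu_total
#' @return A data frame with columns `p_photoelectric`, `p_incoherent`,
#'   `p_coherent` (one row per energy).
#' @export
#' @examples
#' channel_probabilities(load_material("water"), 317)
channel_probabilities <- function(material, energy_kev) {
  stopifnot(inherits(material, "ir_material"))
  tab <- material$table
  pe <- loglog_interp(energy_kev, tab$energy_keV, tab$mu_over_rho_pe)
  ic <- loglog_interp(energy_kev, tab$energy_keV, tab$mu_over_rho_incoh)
  co <- loglog_interp(energy_kev, tab$energy_keV, tab$mu_over_rho_coh)
  tot <- pe + ic + co
  data.frame(p_photoelectric = pe / tot, p_incoherent = ic / tot,
             p_coherent = co / tot)
}
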