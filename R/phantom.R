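#' Phantom presets
#'
#' Builds a cubic phantom (default 25 x 25 x 25 cm3, i.e. half-size 12.5 cm)
#' centred on the source.  Homogeneous presets are `"water"`, `"bone"` and
#' `"lung"`.  Interface presets `"water_lung"` and `"bone_lung"` place a
#' planar interface perpendicular to the transverse measurement axis (+x) at
#' `interface_offset_cm` from the source center, with the denser material on
#' the source side and inflated lung beyond; the interface plane is parallel
#' to the source long axis (z).  A point exactly on the interface plane
#' belongs to the far (lung) region; a point exactly on the cube surface is
#' inside.
#'
#' @param name Preset name: `"water"`, `"bone"`, `"lung"`, `"water_lung"`,
#'   `"bone_lung"`.
#' @param interface_offset_cm Source-center-to-interface distance along +x,
#'   cm (interface presets only).
#' @param half_size_cm Cube half-size, cm.
#' @return An object of class `ir_phantom`.
#' @export
#' @examples
#' ph <- phantom_preset("water_lung")
#' region_at(ph, c(0, 0, 0))
#' region_at(ph, c(2, 0, 0))
phantom_preset <- function(name, interface_offset_cm = 1.0,
                           half_size_cm = 12.5) {
  stopifnot(half_size_cm > 0)
  name <- tolower(name)
  mats <- switch(name,
    water = list(load_material("water")),
    bone = list(load_material("bone")),
    lung = list(load_material("lung")),
    water_lung = list(load_material("water"), load_material("lung")),
    bone_lung = list(load_material("bone"), load_material("lung")),
    stop("unknown phantom preset: ", name, call. = FALSE))
  offset <- if (length(mats) == 2) interface_offset_cm else NULL
  if (!is.null(offset)) {
    stopifnot(is.numeric(offset), length(offset) == 1)
    if (offset <= 0 || offset >= half_size_cm)
      stop("interface_offset_cm must lie strictly between 0 and the cube ",
           "half-size so the source center sits inside region 1",
           call. = FALSE)
  }
  structure(list(name = name, half_size_cm = half_size_cm,
                 materials = mats, interface_offset_cm = offset,
                 interface_normal = c(1, 0, 0)),
            class = "ir_phantom")
}

#' @export
print.ir_phantom <- function(x, ...) {
  cat("phantom:", x$name, "| cube", 2 * x$half_size_cm, "cm")
  if (!is.null(x$interface_offset_cm))
    cat(" | interface at x =", x$interface_offset_cm, "cm")
  cat("\nmaterials:", paste(vapply(x$materials, `[[`, "", "name"),
                            collapse = " / "), "\n")
  invisible(x)
}

#' Locate a point in a phantom
#'
#' @param phantom An [phantom_preset()] object.
#' @param point Numeric length-3 position, cm.
#' @return The material name at the point, or `"ESCAPED"` if any coordinate
#'   magnitude exceeds the cube half-size.
#' @export
region_at <- function(phantom, point) {
  stopifnot(inherits(phantom, "ir_phantom"), length(point) == 3)
  if (any(abs(point) > phantom$half_size_cm)) return("ESCAPED")
  i <- 1L
  if (!is.null(phantom$interface_offset_cm) &&
      point[1] >= phantom$interface_offset_cm) i <- 2L
  phantom$materials[[i]]$name
}

#' Majorant attenuation coefficient over a phantom
#'
#' The maximum total linear attenuation coefficient over the phantom's
#' materials at the given energy; the rejection bound used by delta
#' (Woodcock) tracking.
#'
#' @inheritParams region_at
#' @param energy_kev Photon energy, keV (vectorised).
#' @return Majorant attenuation coefficient(s), 1/cm.
#' @export
max_majorant_mu <- function(phantom, energy_kev) {
  stopifnot(inherits(phantom, "ir_phantom"))
  mus <- vapply(phantom$materials, mu_total, numeric(length(energy_kev)),
                energy_kev = energy_kev)
  if (length(energy_kev) == 1) max(mus) else apply(mus, 1, max)
}
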