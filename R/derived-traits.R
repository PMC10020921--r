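#' Cross-sectional areas of a cylindrical bone
#'
#' Under the concentric-cylinder model the total and medullary cross-sections
#' are circles, so `area = diameter^2 * pi / 4`; the cortical area is their
#' difference. Diameters are taken in mm and areas returned in cm2.
#'
#' @param pd periosteal (outer) diameter, mm.
#' @param md medullary (inner) diameter, mm; `0 <= md < pd`.
#' @return A tibble with columns `total`, `medullary`, `cortical` (cm2).
#' @export
#' @examples
#' bone_areas(9.455, 4.025)
bone_areas <- function(pd, md) {
  check_geometry(pd, md, allow_equal = FALSE)
  total <- (pd / 10)^2 * pi / 4
  medullary <- (md / 10)^2 * pi / 4
  tibble::tibble(total = total, medullary = medullary,
                 cortical = total - medullary)
}

check_geometry <- function(pd, md, allow_equal = FALSE) {
  if (any(md < 0) || any(pd <= 0)) stop("non-physical geometry: negative diameter")
  bad <- if (allow_equal) md > pd else md >= pd
  if (any(bad)) stop("non-physical geometry: medullary diameter must be smaller than periosteal")
  invisible(TRUE)
}

#' Cortical thickness of a concentric-cylinder bone
#'
#' @inheritParams bone_areas
#' @param md medullary diameter, mm; `md <= pd`.
#' @return thickness in mm, `(pd - md) / 2`.
#' @export
cortical_thickness <- function(pd, md) {
  check_geometry(pd, md, allow_equal = TRUE)
  (pd - md) / 2
}

#' Cross-sectional moment of inertia of the cortical annulus
#'
#' `CSMI = ((pd/2)^4 - (md/2)^4) * pi / 4` with diameters converted to cm, so
#' the result is in cm4 (the scale on which the reference estimates for this
#' trait are printed).
#'
#' @inheritParams bone_areas
#' @return CSMI in cm4.
#' @export
#' @examples
#' csmi(9.455, 4.025)
csmi <- function(pd, md) {
  check_geometry(pd, md, allow_equal = FALSE)
  ((pd / 20)^4 - (md / 20)^4) * pi / 4
}

#' Section modulus
#'
#' CSMI divided by the outer radius (half the periosteal diameter, in cm);
#' an estimate of resistance to bending at the bone surface.
#'
#' @param csmi cross-sectional moment of inertia, cm4.
#' @param pd periosteal diameter, mm.
#' @return section modulus in cm3.
#' @export
section_modulus <- function(csmi, pd) {
  if (any(pd <= 0)) stop("periosteal diameter must be positive")
  csmi / (pd / 20)
}

#' Bone mineral apparent density
#'
#' BMC divided by the cortical cross-sectional area: a volumetric estimate of
#' the mineral density of the cortical shell.
#'
#' @param bmc linear bone mineral content, mg/cm.
#' @param cortical_area cortical area, cm2 (> 0).
#' @return BMAD in mg/cm3.
#' @export
bmad <- function(bmc, cortical_area) {
  if (any(cortical_area <= 0)) stop("cortical area must be positive")
  bmc / cortical_area
}

#' Strength index
#'
#' Product of the section modulus and BMAD; combines structural geometry and
#' tissue mineral density into one bone-strength surrogate.
#'
#' @param section_modulus cm3.
#' @param bmad mg/cm3.
#' @return strength index, (mg/cm3) x cm3.
#' @export
strength_index <- function(section_modulus, bmad) {
  if (any(section_modulus < 0) || any(bmad < 0)) stop("inputs must be non-negative")
  section_modulus * bmad
}

#' Areal bone mineral density from BMC and bone width
#'
#' BMC divided by the scanned bone width times a standardized 1 cm height.
#'
#' @param bmc mg/cm.
#' @param pd periosteal diameter, mm (> 0).
#' @return BMD in mg/cm2.
#' @export
compute_bmd <- function(bmc, pd) {
  if (any(pd <= 0)) stop("periosteal diameter must be positive")
  bmc / (pd / 10)
}

#' Derive the full trait panel from measured primitives
#'
#' Takes per-child (or per-bone) averaged primitives --- BMC, periosteal and
#' medullary diameter --- and computes the remaining traits: BMD, areas,
#' cortical thickness, CSMI, section modulus, BMAD, strength index. Derived
#' traits are computed from averaged primitives, not averaged over per-bone
#' derived values.
#'
#' @param data a data frame with columns `bmc` (mg/cm), `periosteal_diameter`
#'   and `medullary_diameter` (mm).
#' @return the input tibble with columns `bmd`, `total_area`,
#'   `medullary_area`, `cortical_area`, `cortical_thickness`, `csmi`,
#'   `section_modulus`, `bmad`, `strength_index` appended.
#' @export
#' @examples
#' derive_traits(tibble::tibble(bmc = 345.93,
#'                              periosteal_diameter = 9.455,
#'                              medullary_diameter = 4.025))
derive_traits <- function(data) {
  stopifnot(all(c("bmc", "periosteal_diameter", "medullary_diameter") %in% names(data)))
  ar <- bone_areas(data$periosteal_diameter, data$medullary_diameter)
  ci <- csmi(data$periosteal_diameter, data$medullary_diameter)
  bd <- bmad(data$bmc, ar$cortical)
  z <- section_modulus(ci, data$periosteal_diameter)
  dplyr::mutate(tibble::as_tibble(data),
    bmd = compute_bmd(.data$bmc, .data$periosteal_diameter),
    total_area = ar$total,
    medullary_area = ar$medullary,
    cortical_area = ar$cortical,
    cortical_thickness = cortical_thickness(.data$periosteal_diameter,
                                            .data$medullary_diameter),
    csmi = ci,
    section_modulus = z,
    bmad = bd,
    strength_index = strength_index(z, bd)
  )
}
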