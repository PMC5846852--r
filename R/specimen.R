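#' Specimen geometry
#'
#' Geometry of one bone-disc-bone specimen. The disc cross-section is a
#' circle of diameter `disc_diameter`; the nucleus core is concentric with
#' diameter `nucleus_diameter`, which defaults to half the disc diameter
#' (the 2:1 annulus:nucleus diameter ratio), so the nucleus occupies 25% of
#' the disc area and the annulus ring the remaining 75%.
#'
#' @param disc_diameter Disc diameter, mm.
#' @param disc_height Disc height, mm.
#' @param bone_length_sup,bone_length_inf Retained bone segment lengths above
#'   and below the disc, mm.
#' @param nucleus_diameter Nucleus core diameter, mm (default
#'   `disc_diameter / 2`).
#' @return An object of class `specimen_geometry` with derived areas
#'   `disc_area`, `nucleus_area`, `annulus_area` (mm^2).
#' @export
specimen_geometry <- function(disc_diameter = 30, disc_height = 8,
                              bone_length_sup = 15.72, bone_length_inf = 15.44,
                              nucleus_diameter = disc_diameter / 2) {
  stopifnot(disc_diameter > 0, disc_height > 0,
            bone_length_sup > 0, bone_length_inf > 0,
            nucleus_diameter > 0, nucleus_diameter < disc_diameter)
  disc_area <- pi * disc_diameter^2 / 4
  nucleus_area <- pi * nucleus_diameter^2 / 4
  structure(
    list(disc_diameter = disc_diameter, disc_height = disc_height,
         nucleus_diameter = nucleus_diameter,
         bone_length_sup = bone_length_sup, bone_length_inf = bone_length_inf,
         disc_area = disc_area, nucleus_area = nucleus_area,
         annulus_area = disc_area - nucleus_area),
    class = "specimen_geometry"
  )
}

#' Vertebra properties
#'
#' One vertebral segment collapsed to a single effective Young's modulus via
#' the greyscale calibration of its mean image greyscale.
#'
#' @param mean_greyscale Mean image greyscale of the segment, in `[0, 255]`.
#' @param length Segment length, mm.
#' @param map A [greyscale_map()] calibration.
#' @return An object of class `vertebra_props` with field `effective_modulus`
#'   (MPa).
#' @export
vertebra_props <- function(mean_greyscale, length, map = greyscale_map()) {
  stopifnot(length > 0)
  structure(
    list(mean_greyscale = mean_greyscale, length = length,
         effective_modulus = greyscale_to_modulus(mean_greyscale, map),
         map = map),
    class = "vertebra_props"
  )
}

#' Test groups
#' @keywords internal
fsu_groups <- c("CON", "BP", "NR", "PEP")

#' Construct a bone-disc-bone specimen
#'
#' The unit the forward model operates on: geometry, two vertebrae, annulus
#' and (unless nucleotomised) nucleus materials, a group label and the
#' group-modification factors.
#'
#' @param id Specimen identifier (character).
#' @param group One of `"CON"`, `"BP"`, `"NR"`, `"PEP"`.
#' @param geometry A [specimen_geometry()].
#' @param vertebra_sup,vertebra_inf [vertebra_props()] for the superior and
#'   inferior segments.
#' @param annulus A [holzapfel_params()] object.
#' @param nucleus A [mooney_rivlin_params()] object, or `NULL` for
#'   nucleotomised (NR) specimens.
#' @param plug_modulus_factor Multiplier on the superior vertebra modulus
#'   encoding the bone-plug modification (default 1).
#' @param annulus_collapse_factor Multiplier on the annulus stiffness
#'   parameters (c10, k1) encoding annulus collapse into the nucleotomy void
#'   (default 1).
#' @param endcap Optional list `list(material = linear_elastic_params(),
#'   length = <mm>)` adding a PMMA end-cap series element; `NULL` (default)
#'   disables it.
#' @return An object of class `fsu_specimen`.
#' @export
specimen <- function(id, group = "CON",
                     geometry = specimen_geometry(),
                     vertebra_sup = vertebra_props(113, 15.72),
                     vertebra_inf = vertebra_props(113, 15.44),
                     annulus = holzapfel_params(),
                     nucleus = mooney_rivlin_params(),
                     plug_modulus_factor = 1,
                     annulus_collapse_factor = 1,
                     endcap = NULL) {
  group <- match.arg(group, fsu_groups)
  stopifnot(inherits(geometry, "specimen_geometry"),
            inherits(vertebra_sup, "vertebra_props"),
            inherits(vertebra_inf, "vertebra_props"),
            inherits(annulus, "holzapfel_params"),
            plug_modulus_factor > 0, annulus_collapse_factor > 0)
  if (group == "NR" && !is.null(nucleus)) {
    rlang::abort("NR specimens have no nucleus", class = "fsuaxial_error_specimen")
  }
  if (group %in% c("CON", "BP") && is.null(nucleus)) {
    rlang::abort("CON/BP specimens must have a nucleus",
                 class = "fsuaxial_error_specimen")
  }
  if (!is.null(nucleus)) stopifnot(inherits(nucleus, "mooney_rivlin_params"))
  structure(
    list(id = as.character(id), group = group, geometry = geometry,
         vertebra_sup = vertebra_sup, vertebra_inf = vertebra_inf,
         annulus = annulus, nucleus = nucleus,
         plug_modulus_factor = plug_modulus_factor,
         annulus_collapse_factor = annulus_collapse_factor,
         endcap = endcap),
    class = "fsu_specimen"
  )
}

#' Quasi-static axial compression load protocol
#'
#' @param preload Preload, N (default 10). The reported displacement origin.
#' @param max_force Maximum applied load, N (default 2100, i.e. 2.1 kN).
#' @param n_points Number of force levels on the grid (>= 10).
#' @param rate Displacement rate, mm/min; metadata only (models are
#'   quasi-static).
#' @return An object of class `load_protocol`.
#' @export
load_protocol <- function(preload = 10, max_force = 2100, n_points = 60,
                          rate = 1) {
  stopifnot(preload >= 0, preload < max_force, n_points >= 10)
  structure(list(preload = preload, max_force = max_force,
                 n_points = as.integer(n_points), rate = rate),
            class = "load_protocol")
}

#' Apply a group modification to a control-configuration specimen
#'
#' Starting from a CON-configuration specimen: `"NR"` removes the nucleus and
#' applies an annulus collapse factor; `"BP"` applies a modulus factor to the
#' superior vertebra (bone plug), default 1; `"PEP"` replaces the nucleus
#' material by the hydrogel parameters (default equal to the native nucleus);
#' `"CON"` returns the specimen unchanged.
#'
#' @param spec An `fsu_specimen` in CON configuration.
#' @param group Target group label.
#' @param collapse_factor Annulus stiffness multiplier for NR specimens.
#' @param plug_modulus_factor Superior vertebra modulus multiplier for BP.
#' @param hydrogel A [mooney_rivlin_params()] for the PEP nucleus replacement;
#'   `NULL` keeps the native nucleus parameters.
#' @return A modified `fsu_specimen`.
#' @export
apply_group <- function(spec, group, collapse_factor = 1,
                        plug_modulus_factor = 1, hydrogel = NULL) {
  stopifnot(inherits(spec, "fsu_specimen"))
  group <- match.arg(group, fsu_groups)
  if (spec$group != "CON") {
    rlang::abort("apply_group expects a CON-configuration base specimen",
                 class = "fsuaxial_error_specimen")
  }
  out <- spec
  out$group <- group
  if (group == "NR") {
    out$nucleus <- NULL
    out$annulus_collapse_factor <- collapse_factor
  } else if (group == "BP") {
    out$plug_modulus_factor <- plug_modulus_factor
    out$vertebra_sup$effective_modulus <-
      out$vertebra_sup$effective_modulus * plug_modulus_factor
  } else if (group == "PEP") {
    if (!is.null(hydrogel)) {
      stopifnot(inherits(hydrogel, "mooney_rivlin_params"))
      out$nucleus <- hydrogel
    }
  }
  out
}

#' Bone-rigidity sensitivity variant of a specimen
#'
#' Mirrors the bone-rigidity sensitivity study: `"heterogeneous"` keeps the
#' specimen-specific vertebral moduli; `"homogeneous_average"` sets both
#' vertebrae to the modulus mapped from the cohort-average greyscale;
#' `"near_rigid"` sets both to the PMMA modulus (1500 MPa by default).
#'
#' @param spec An `fsu_specimen`.
#' @param mode One of `"heterogeneous"`, `"homogeneous_average"`,
#'   `"near_rigid"`.
#' @param cohort_mean_greyscale Mean greyscale across all vertebrae of the
#'   cohort (required for `"homogeneous_average"`).
#' @param rigid_modulus Modulus used by `"near_rigid"`, MPa (default 1500).
#' @return A modified `fsu_specimen`.
#' @export
sensitivity_variant <- function(spec, mode = c("heterogeneous",
                                               "homogeneous_average",
                                               "near_rigid"),
                                cohort_mean_greyscale = NULL,
                                rigid_modulus = 1500) {
  stopifnot(inherits(spec, "fsu_specimen"))
  mode <- match.arg(mode)
  if (mode == "heterogeneous") return(spec)
  out <- spec
  if (mode == "homogeneous_average") {
    if (is.null(cohort_mean_greyscale)) {
      rlang::abort("homogeneous_average needs cohort_mean_greyscale",
                   class = "fsuaxial_error_specimen")
    }
    E <- greyscale_to_modulus(cohort_mean_greyscale, spec$vertebra_sup$map)
    out$vertebra_sup$mean_greyscale <- cohort_mean_greyscale
    out$vertebra_inf$mean_greyscale <- cohort_mean_greyscale
    out$vertebra_sup$effective_modulus <- E
    out$vertebra_inf$effective_modulus <- E
  } else {
    out$vertebra_sup$effective_modulus <- rigid_modulus
    out$vertebra_inf$effective_modulus <- rigid_modulus
  }
  out
}
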