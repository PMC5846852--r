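# Reduced-order forward model: the disc is a parallel annulus-ring /
# nucleus-core column under homogeneous axial compression, in series with
# two linear-elastic bone segments (and an optional PMMA end-cap).

# Effective annulus parameters after the collapse factor (NR modification):
# the factor scales the matrix stiffness c10 and the fibre recruitment
# coupling. Scaling only stiffness coefficients would leave the terminal
# stress/strain slope at a fixed peak stress unchanged (for an exponential
# fibre response the tangent at stress level s is ~ d(log sigma)/d(eps) * s,
# independent of a multiplicative prefactor); reduced fibre recruitment is
# what makes a collapsing ring softer throughout the loading range.
effective_annulus <- function(spec) {
  a <- spec$annulus
  f <- spec$annulus_collapse_factor
  if (f != 1) {
    a$c10 <- a$c10 * f
    a$k2 <- a$k2 * f
    a$fiber_coupling <- a$fiber_coupling * f
  }
  a
}

# Lateral stretch of the annulus at fixed axial stretch such that the mean
# lateral Cauchy stress vanishes (traction-free lateral surface). With equal
# lateral stretches this is equivalent to d/dlat W(lat, lat, lz) = 0.
annulus_lateral_stretch <- function(annulus, axial_stretch) {
  g <- function(lat) {
    dW <- holzapfel_energy_gradient(c(lat, lat, axial_stretch), annulus)$dW
    dW[1] + dW[2]
  }
  guess <- axial_stretch^(-1 / 2)
  sol <- tryCatch(
    stats::uniroot(g, interval = guess * c(0.98, 1.02), extendInt = "yes",
                   tol = 1e-12, maxiter = 200),
    error = function(e) {
      rlang::abort(
        paste0("lateral traction solve failed at axial stretch ",
               signif(axial_stretch, 6), ": ", conditionMessage(e)),
        class = "fsuaxial_error_numeric")
    }
  )
  sol$root
}

#' Axial force carried by the disc at a given axial stretch
#'
#' Compressive axial force (N, positive in compression) transmitted by the
#' disc at axial stretch `axial_stretch`. The annulus ring deforms
#' homogeneously with its lateral stretch set by a traction-free mean lateral
#' Cauchy stress (`lateral = "unconfined"`, default) or shared with the
#' incompressible nucleus (`"confined"`, lateral stretch
#' \eqn{\lambda_z^{-1/2}}); the nucleus (if present) acts in parallel as an
#' incompressible Mooney-Rivlin column. For NR specimens the nucleus term is
#' zero and the annulus stiffness is scaled by the collapse factor.
#'
#' @param spec An `fsu_specimen`.
#' @param axial_stretch Axial stretch of the disc, in `(0, 1]`.
#' @param lateral Lateral boundary condition for the annulus.
#' @return Axial force, N (0 at `axial_stretch = 1`).
#' @export
disc_force <- function(spec, axial_stretch,
                       lateral = c("unconfined", "confined")) {
  stopifnot(inherits(spec, "fsu_specimen"))
  lateral <- match.arg(lateral)
  if (!is.finite(axial_stretch) || axial_stretch <= 0 || axial_stretch > 1) {
    rlang::abort("axial stretch must lie in (0, 1]",
                 class = "fsuaxial_error_kinematics")
  }
  if (axial_stretch == 1) return(0) # reference state carries no load
  ann <- effective_annulus(spec)
  lat <- if (lateral == "unconfined") {
    annulus_lateral_stretch(ann, axial_stretch)
  } else {
    axial_stretch^(-1 / 2)
  }
  # axial tension force per reference area equals dW/dlambda_z
  # (sigma_z * current area = A0 * dW/dlambda_z)
  dWz <- holzapfel_energy_gradient(c(lat, lat, axial_stretch), ann)$dW[3]
  f_tension <- spec$geometry$annulus_area * dWz
  if (!is.null(spec$nucleus)) {
    sig_n <- uniaxial_stress_mr(axial_stretch, spec$nucleus)
    f_tension <- f_tension +
      sig_n * spec$geometry$nucleus_area / axial_stretch
  }
  -f_tension
}

# Invert disc_force: the axial stretch at which the disc carries `force` N.
disc_stretch_at_force <- function(spec, force, lateral = "unconfined",
                                  lower = 0.3) {
  if (force == 0) return(1)
  h <- function(lz) disc_force(spec, lz, lateral = lateral) - force
  sol <- tryCatch(
    stats::uniroot(h, interval = c(lower, 1), tol = 1e-12, maxiter = 200),
    error = function(e) {
      rlang::abort(
        paste0("disc force inversion failed at F = ", signif(force, 6),
               " N: ", conditionMessage(e)),
        class = "fsuaxial_error_numeric")
    }
  )
  sol$root
}

#' Force-displacement curve container
#'
#' A tibble with columns `displacement_mm` and `force_N`. Displacement must
#' be strictly increasing; for forward-model (noise-free) curves the force
#' must also be non-decreasing (`strict = TRUE`); measured/noisy curves relax
#' the force monotonicity.
#'
#' @param displacement_mm,force_N Numeric vectors of equal length.
#' @param strict Enforce non-decreasing force (default `TRUE`).
#' @return A tibble of class `fd_curve`.
#' @export
fd_curve <- function(displacement_mm, force_N, strict = TRUE) {
  stopifnot(length(displacement_mm) == length(force_N),
            all(is.finite(displacement_mm)), all(is.finite(force_N)))
  if (any(diff(displacement_mm) <= 0)) {
    rlang::abort("displacement must be strictly increasing",
                 class = "fsuaxial_error_curve")
  }
  if (strict && any(diff(force_N) < 0)) {
    rlang::abort("force must be non-decreasing on a quasi-static curve",
                 class = "fsuaxial_error_curve")
  }
  structure(tibble::tibble(displacement_mm = displacement_mm,
                           force_N = force_N),
            class = c("fd_curve", "tbl_df", "tbl", "data.frame"))
}

# Component displacements (mm) at a single force level.
component_displacements <- function(spec, force, lateral = "unconfined") {
  lz <- disc_stretch_at_force(spec, force, lateral = lateral)
  disc <- (1 - lz) * spec$geometry$disc_height
  A <- spec$geometry$disc_area
  bone <- force * (spec$vertebra_sup$length / spec$vertebra_sup$effective_modulus +
                   spec$vertebra_inf$length / spec$vertebra_inf$effective_modulus) / A
  endcap <- 0
  if (!is.null(spec$endcap)) {
    endcap <- force * spec$endcap$length / (spec$endcap$material$youngs_E * A)
  }
  list(disc = disc, bone = bone, endcap = endcap,
       total = disc + bone + endcap, axial_stretch = lz)
}

#' Simulate the axial compression response of a specimen
#'
#' For each force level on a grid from the preload to the maximum load, the
#' total axial displacement is the disc displacement (inverting
#' [disc_force()]) plus the linear bone segment displacements
#' \eqn{F L / (E A)} (and an optional end-cap term). The curve is re-zeroed
#' at the preload point, mirroring the experimental displacement origin.
#'
#' @param spec An `fsu_specimen`.
#' @param protocol A [load_protocol()].
#' @param lateral Lateral boundary condition, see [disc_force()].
#' @return An [fd_curve()] with `protocol$n_points` rows, starting at
#'   displacement 0 / force `protocol$preload` and ending at
#'   `protocol$max_force`.
#' @export
specimen_response <- function(spec, protocol = load_protocol(),
                              lateral = "unconfined") {
  stopifnot(inherits(spec, "fsu_specimen"), inherits(protocol, "load_protocol"))
  forces <- seq(protocol$preload, protocol$max_force,
                length.out = protocol$n_points)
  comp <- purrr::map(forces, function(f)
    component_displacements(spec, f, lateral = lateral))
  total <- purrr::map_dbl(comp, "total")
  fd_curve(total - total[1], forces, strict = TRUE)
}

#' Fraction of the applied deformation carried by the bone
#'
#' Bone displacement divided by total displacement at the maximum load of the
#' protocol. In `[0, 1)`; decreases as the bone modulus increases and tends
#' to 0 in the rigid-bone limit.
#'
#' @inheritParams specimen_response
#' @return Dimensionless fraction.
#' @export
bone_strain_contribution <- function(spec, protocol = load_protocol(),
                                     lateral = "unconfined") {
  stopifnot(inherits(spec, "fsu_specimen"), inherits(protocol, "load_protocol"))
  comp <- component_displacements(spec, protocol$max_force, lateral = lateral)
  comp$bone / comp$total
}
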