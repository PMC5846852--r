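#' Holzapfel-type annulus fibrosus material parameters
#'
#' Parameter set for the anisotropic hyperelastic (Holzapfel-type) model of
#' the annulus fibrosus: an isochoric neo-Hookean matrix, two symmetric
#' tension-only collagen fibre families, and a volumetric penalty calibrated
#' to the compressibility of water. Defaults are the values used for the
#' annulus throughout the package: `c10 = 0.32` MPa, `bulk_K = 2200` MPa,
#' `k1 = 2.45` MPa, `k2 = 2.11`, fibre families at +/-20 degrees measured
#' from the circumferential (hoop) direction in the circumferential-axial
#' plane, and no fibre dispersion.
#'
#' @param c10 Matrix stiffness, MPa. Must be positive.
#' @param bulk_K Initial bulk modulus of the volumetric law, MPa.
#' @param k1 Fibre stiffness, MPa. Non-negative.
#' @param k2 Dimensionless fibre exponent. Positive.
#' @param fiber_angle_deg Angle of the two symmetric fibre families,
#'   degrees from the circumferential direction.
#' @param dispersion_kappa Fibre dispersion parameter, in `[0, 1/3]`.
#' @param fiber_coupling Kinematic efficiency of fibre recruitment, in
#'   `(0, 1]`: the fibre strain measure is scaled by this factor before
#'   entering the exponential. 1 (default) is an intact annulus ring; values
#'   below 1 represent a ring that partly collapses inward (e.g. into a
#'   nucleotomy void) so that less fibre stretch develops per axial strain.
#'
#' @return An object of class `holzapfel_params`.
#' @seealso [energy_holzapfel()], [cauchy_stress()], [initial_bulk_modulus()]
#' @export
#' @examples
#' p <- holzapfel_params()
#' initial_bulk_modulus(p)
holzapfel_params <- function(c10 = 0.32, bulk_K = 2200, k1 = 2.45, k2 = 2.11,
                             fiber_angle_deg = 20, dispersion_kappa = 0,
                             fiber_coupling = 1) {
  stopifnot(c10 > 0, bulk_K > 0, k1 >= 0, k2 > 0,
            dispersion_kappa >= 0, dispersion_kappa <= 1 / 3,
            fiber_coupling > 0, fiber_coupling <= 1)
  structure(
    list(c10 = c10, bulk_K = bulk_K, k1 = k1, k2 = k2,
         fiber_angle_deg = fiber_angle_deg,
         dispersion_kappa = dispersion_kappa,
         fiber_coupling = fiber_coupling),
    class = "holzapfel_params"
  )
}

#' Mooney-Rivlin nucleus pulposus material parameters
#'
#' Incompressible two-term Mooney-Rivlin model for the nucleus pulposus.
#' Defaults `c10 = 0.07` MPa, `c01 = 0.02` MPa.
#'
#' @param c10,c01 Mooney-Rivlin coefficients, MPa; their sum must be positive.
#' @return An object of class `mooney_rivlin_params`.
#' @seealso [uniaxial_stress_mr()]
#' @export
mooney_rivlin_params <- function(c10 = 0.07, c01 = 0.02) {
  stopifnot(c10 + c01 > 0)
  structure(list(c10 = c10, c01 = c01), class = "mooney_rivlin_params")
}

#' Linear elastic material parameters
#'
#' Isotropic linear elasticity; the default is the PMMA end-cap cement
#' (E = 1500 MPa = 1.5 GPa, nu = 0.3).
#'
#' @param youngs_E Young's modulus, MPa. Positive.
#' @param poisson_nu Poisson ratio, in `[0, 0.5)`.
#' @return An object of class `linear_elastic_params`.
#' @export
linear_elastic_params <- function(youngs_E = 1500, poisson_nu = 0.3) {
  stopifnot(youngs_E > 0, poisson_nu >= 0, poisson_nu < 0.5)
  structure(list(youngs_E = youngs_E, poisson_nu = poisson_nu),
            class = "linear_elastic_params")
}

#' Greyscale-to-modulus calibration for vertebral bone
#'
#' Linear map from an 8-bit image greyscale value to a bone Young's modulus,
#' `E = intercept + slope * gs`. The default calibration
#' (`intercept = 10` MPa, `slope = 900/255` MPa per greyscale unit) spans the
#' admissible greyscale range `[0, 255]` onto moduli from 10 to 910 MPa.
#'
#' @param slope MPa per greyscale unit.
#' @param intercept MPa; modulus at greyscale 0.
#' @param poisson_nu Poisson ratio carried alongside the modulus (default 0.3).
#' @return An object of class `greyscale_map`.
#' @seealso [greyscale_to_modulus()]
#' @export
greyscale_map <- function(slope = 900 / 255, intercept = 10, poisson_nu = 0.3) {
  stopifnot(is.finite(slope), is.finite(intercept))
  # mapped modulus must stay positive over the whole admissible range
  if (intercept <= 0 || intercept + slope * 255 <= 0) {
    rlang::abort("greyscale map must give positive moduli on [0, 255]",
                 class = "fsuaxial_error_domain")
  }
  structure(list(slope = slope, intercept = intercept, poisson_nu = poisson_nu),
            class = "greyscale_map")
}

#' Homogeneous deformation state in principal stretches
#'
#' Kinematic carrier for homogeneous triaxial deformations: the three
#' principal stretches along the radial, circumferential (hoop/transverse)
#' and axial directions, plus the volume ratio `J`.
#'
#' @param lambda_r,lambda_t,lambda_z Principal stretches (dimensionless,
#'   positive).
#' @return An object of class `deformation_state` with fields `lambda`
#'   (length-3 vector, order r, t, z) and `J`.
#' @export
deformation_state <- function(lambda_r, lambda_t, lambda_z) {
  lam <- c(lambda_r, lambda_t, lambda_z)
  if (length(lam) != 3 || !all(is.finite(lam)) || any(lam <= 0)) {
    rlang::abort("principal stretches must be finite and positive",
                 class = "fsuaxial_error_kinematics")
  }
  structure(list(lambda = lam, J = prod(lam)), class = "deformation_state")
}

# Energy density and its stretch-gradient for the Holzapfel-type law.
# Returns list(W, dW) with dW = dW/dlambda (length 3, order r, t, z).
holzapfel_energy_gradient <- function(lam, p) {
  J <- prod(lam)
  Jm23 <- J^(-2 / 3)
  I1b <- Jm23 * sum(lam^2)
  theta <- p$fiber_angle_deg * pi / 180
  c2 <- cos(theta)^2
  s2 <- sin(theta)^2
  # fibre families +/-theta in the t-z plane have identical pseudo-invariant
  Tq <- lam[2]^2 * c2 + lam[3]^2 * s2
  I4b <- Jm23 * Tq
  kap <- p$dispersion_kappa
  fc <- if (is.null(p$fiber_coupling)) 1 else p$fiber_coupling
  Ebar <- fc * (kap * (I1b - 3) + (1 - 3 * kap) * (I4b - 1))

  dI1 <- (2 / lam) * (Jm23 * lam^2 - I1b / 3)
  dTq <- c(0, 2 * lam[2] * c2, 2 * lam[3] * s2)
  dI4 <- Jm23 * dTq - (2 / 3) * I4b / lam

  W <- p$c10 * (I1b - 3) + (p$bulk_K / 2) * log(J)^2
  dW <- p$c10 * dI1 + p$bulk_K * log(J) / lam
  if (Ebar > 0 && p$k1 > 0) {
    # two identical families: 2 * k1/(2 k2) * (exp(k2 E^2) - 1)
    W <- W + (p$k1 / p$k2) * (exp(p$k2 * Ebar^2) - 1)
    dE <- fc * (kap * dI1 + (1 - 3 * kap) * dI4)
    dW <- dW + 2 * p$k1 * Ebar * exp(p$k2 * Ebar^2) * dE
  }
  list(W = W, dW = dW)
}

#' Strain-energy density of the annulus material
#'
#' Evaluates the Holzapfel-type strain-energy density
#' \deqn{W = c_{10}(\bar I_1 - 3) + \frac{k_1}{2k_2}\sum_{i=1,2}
#'   \left[e^{k_2 \langle \bar E_i\rangle^2} - 1\right] + \frac{K}{2}(\ln J)^2}
#' with \eqn{\bar E_i = \kappa(\bar I_1 - 3) + (1 - 3\kappa)(\bar I_4^{(i)} - 1)}
#' and the Macaulay bracket \eqn{\langle\cdot\rangle}: fibres only store energy
#' in tension (\eqn{\bar E_i > 0}). The volumetric law is
#' \eqn{U(J) = (K/2)(\ln J)^2}, whose initial bulk modulus \eqn{U''(1)} equals
#' `bulk_K` exactly.
#'
#' @param state A [deformation_state()].
#' @param p A [holzapfel_params()] object.
#' @return Energy density, MPa.
#' @export
energy_holzapfel <- function(state, p) {
  stopifnot(inherits(state, "deformation_state"), inherits(p, "holzapfel_params"))
  holzapfel_energy_gradient(state$lambda, p)$W
}

#' Principal Cauchy stresses under a homogeneous deformation
#'
#' Evaluates the three principal Cauchy stresses (order: radial, hoop, axial;
#' MPa) as the analytic stretch-derivative of the material's strain energy,
#' \eqn{\sigma_i = (\lambda_i / J)\, \partial W / \partial \lambda_i}.
#' For the incompressible Mooney-Rivlin material the deformation must be
#' isochoric (`J = 1`) and the indeterminate hydrostatic pressure is resolved
#' by declaring one traction-free principal direction.
#'
#' @param state A [deformation_state()].
#' @param material A [holzapfel_params()], [mooney_rivlin_params()] or
#'   [linear_elastic_params()] object.
#' @param ... Passed to methods. For Mooney-Rivlin, `zero_traction` names the
#'   traction-free direction (`"r"`, `"t"` or `"z"`, default `"r"`).
#' @return Numeric length-3 vector of principal Cauchy stresses, MPa.
#' @export
cauchy_stress <- function(state, material, ...) {
  UseMethod("cauchy_stress", material)
}

#' @export
cauchy_stress.holzapfel_params <- function(state, material, ...) {
  stopifnot(inherits(state, "deformation_state"))
  eg <- holzapfel_energy_gradient(state$lambda, material)
  as.numeric(state$lambda * eg$dW / state$J)
}

#' @export
cauchy_stress.mooney_rivlin_params <- function(state, material,
                                               zero_traction = c("r", "t", "z"),
                                               ...) {
  stopifnot(inherits(state, "deformation_state"))
  zero_traction <- match.arg(zero_traction)
  if (abs(state$J - 1) > 1e-8) {
    rlang::abort("Mooney-Rivlin material is incompressible: state must have J = 1",
                 class = "fsuaxial_error_constraint")
  }
  lam <- state$lambda
  I1 <- sum(lam^2)
  dW <- 2 * material$c10 * lam + 2 * material$c01 * lam * (I1 - lam^2)
  d <- match(zero_traction, c("r", "t", "z"))
  p_hyd <- lam[d] * dW[d]
  as.numeric(lam * dW - p_hyd)
}

#' @export
cauchy_stress.linear_elastic_params <- function(state, material, ...) {
  stopifnot(inherits(state, "deformation_state"))
  eps <- state$lambda - 1
  E <- material$youngs_E
  nu <- material$poisson_nu
  mu <- E / (2 * (1 + nu))
  la <- E * nu / ((1 + nu) * (1 - 2 * nu))
  as.numeric(la * sum(eps) + 2 * mu * eps)
}

#' Uniaxial Cauchy stress of the incompressible Mooney-Rivlin material
#'
#' Closed-form axial Cauchy stress under incompressible uniaxial loading with
#' traction-free lateral faces (lateral stretches \eqn{\lambda^{-1/2}}):
#' \deqn{\sigma = 2(\lambda^2 - \lambda^{-1})(c_{10} + c_{01}/\lambda).}
#'
#' @param lambda_z Axial stretch (positive; < 1 in compression). Vectorised.
#' @param p A [mooney_rivlin_params()] object.
#' @return Axial Cauchy stress, MPa (negative in compression).
#' @export
#' @examples
#' uniaxial_stress_mr(1.1, mooney_rivlin_params())
uniaxial_stress_mr <- function(lambda_z, p = mooney_rivlin_params()) {
  stopifnot(inherits(p, "mooney_rivlin_params"))
  if (any(!is.finite(lambda_z)) || any(lambda_z <= 0)) {
    rlang::abort("axial stretch must be finite and positive",
                 class = "fsuaxial_error_kinematics")
  }
  2 * (lambda_z^2 - 1 / lambda_z) * (p$c10 + p$c01 / lambda_z)
}

#' Map an image greyscale value to a bone Young's modulus
#'
#' @param gs Greyscale value(s) in `[0, 255]`.
#' @param map A [greyscale_map()] calibration.
#' @return Young's modulus, MPa.
#' @export
#' @examples
#' greyscale_to_modulus(255, greyscale_map())
greyscale_to_modulus <- function(gs, map = greyscale_map()) {
  stopifnot(inherits(map, "greyscale_map"))
  if (any(!is.finite(gs)) || any(gs < 0) || any(gs > 255)) {
    rlang::abort("greyscale values must lie in [0, 255]",
                 class = "fsuaxial_error_domain")
  }
  map$intercept + map$slope * gs
}

#' Initial bulk modulus of the annulus volumetric law
#'
#' Second derivative at `J = 1` of the implemented volumetric strain energy
#' `U(J) = (bulk_K / 2) (ln J)^2`; analytically `U''(1) = bulk_K`.
#'
#' @param p A [holzapfel_params()] object.
#' @return Initial bulk modulus, MPa.
#' @export
initial_bulk_modulus <- function(p = holzapfel_params()) {
  stopifnot(inherits(p, "holzapfel_params"))
  # U(J) = K/2 (ln J)^2; U''(J) = K (1 - ln J) / J^2, so U''(1) = K exactly
  p$bulk_K
}

#' Volumetric strain energy of the annulus material
#'
#' `U(J) = (bulk_K / 2) (ln J)^2`; exposed so the calibration of
#' [initial_bulk_modulus()] can be verified by finite differences.
#'
#' @param J Volume ratio(s), positive.
#' @param p A [holzapfel_params()] object.
#' @return Energy density, MPa.
#' @export
volumetric_energy <- function(J, p = holzapfel_params()) {
  stopifnot(inherits(p, "holzapfel_params"), all(J > 0))
  (p$bulk_K / 2) * log(J)^2
}
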