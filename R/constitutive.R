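# Constitutive layer: strain measures, strain-energy densities, stresses /
# membrane tensions, and initial tangent moduli for the three hyperelastic
# laws used to model artery ring segments.
#
# Conventions used throughout:
#  * lam_theta = r/R is the circumferential stretch, lam_z0 = l/L the fixed
#    axial pre-stretch, lam_r = h/H the radial stretch; incompressibility
#    ties them together, lam_theta * lam_r * lam_z0 = 1.
#  * The Skalak law is a 2-D membrane law (energy per reference area,
#    tensions in N/m); Hariton and Mooney-Rivlin are 3-D laws (energy per
#    volume, Cauchy stresses in Pa).
#  * All *_energy / *_stress helpers return quantities normalized by the
#    law's stress-like modulus (C, a, or mu), as the dimensionless problem
#    requires; dimensional values are recovered downstream.

#' Artery segment reference geometry
#'
#' Bundles the reference (unloaded) geometry of a short artery segment:
#' thickness-averaged radius, wall thickness, wall density, and the fixed
#' longitudinal pre-stretch imposed before pressurization.
#'
#' @param R Reference thickness-averaged radius in metres.
#' @param H Reference wall thickness in metres.
#' @param rho0 Wall density in kg/m^3 (incompressibility keeps it constant).
#' @param lam_z0 Longitudinal pre-stretch l/L (dimensionless, typically
#'   1-1.9 for human arteries).
#' @return An object of class `artery_geometry`.
#' @examples
#' artery_geometry(R = 3.46e-3, H = 0.68e-3, rho0 = 1160, lam_z0 = 1.53)
#' @export
artery_geometry <- function(R, H, rho0 = 1160, lam_z0 = 1) {
  stopifnot(is.numeric(R), is.numeric(H), is.numeric(rho0), is.numeric(lam_z0))
  if (R <= 0 || H <= 0 || rho0 <= 0 || lam_z0 <= 0) {
    stop("artery_geometry: R, H, rho0 and lam_z0 must all be positive", call. = FALSE)
  }
  if (H >= R) {
    warning("artery_geometry: H >= R violates the thin-wall regime the ring model assumes",
            call. = FALSE)
  }
  structure(list(R = R, H = H, rho0 = rho0, lam_z0 = lam_z0),
            class = "artery_geometry")
}

#' Material parameter records for the three hyperelastic laws
#'
#' `skalak_params()` holds the two membrane moduli `B` and `C` (N/m) of the
#' Skalak membrane law (healthy, hardening walls; requires `C >= B >= 0`).
#' `hariton_params()` holds the stress-like parameter `a` (Pa) and the
#' dimensionless exponent `b` of the exponential law (atherosclerotic,
#' strongly hardening walls). `mooney_rivlin_params()` holds the shear
#' modulus `mu` (Pa) and the invariant-mixing parameter `beta` in
#' \[-1/2, 1/2\] (aneurysmatic, softening walls; `beta = 1/2` is
#' neo-Hookean).
#'
#' @param B,C Skalak membrane moduli in N/m.
#' @param a Stress-like parameter in Pa.
#' @param b Dimensionless exponent parameter.
#' @param mu Shear modulus in Pa.
#' @param beta Dimensionless mixing parameter in \[-1/2, 1/2\].
#' @return A classed parameter record.
#' @export
skalak_params <- function(B, C) {
  if (C <= 0 || B < 0 || B > C) {
    stop("skalak_params: need C >= B >= 0 and C > 0", call. = FALSE)
  }
  structure(list(B = B, C = C, law = "skalak"), class = c("skalak_params", "ring_params"))
}

#' @rdname skalak_params
#' @export
hariton_params <- function(a, b) {
  if (a <= 0 || b <= 0) stop("hariton_params: need a > 0 and b > 0", call. = FALSE)
  structure(list(a = a, b = b, law = "hariton"), class = c("hariton_params", "ring_params"))
}

#' @rdname skalak_params
#' @export
mooney_rivlin_params <- function(mu, beta) {
  if (mu <= 0 || beta < -0.5 || beta > 0.5) {
    stop("mooney_rivlin_params: need mu > 0 and beta in [-1/2, 1/2]", call. = FALSE)
  }
  structure(list(mu = mu, beta = beta, law = "mooney_rivlin"),
            class = c("mooney_rivlin_params", "ring_params"))
}

# Cap on the argument of exp() in the Hariton law; the exponent grows
# quartically in stretch and silently overflowing to Inf hides the real
# problem (an unphysical state), so raise a diagnostic instead.
.hariton_exp_cap <- 700

.check_stretch <- function(lam_theta, lam_z0) {
  if (any(!is.finite(lam_theta)) || any(!is.finite(lam_z0)) ||
      any(lam_theta <= 0) || any(lam_z0 <= 0)) {
    stop("stretches must be positive and finite", call. = FALSE)
  }
  invisible(TRUE)
}

#' Green strains of a biaxially stretched membrane
#'
#' e = (lambda^2 - 1)/2 in the circumferential and longitudinal directions.
#'
#' @param lam_theta Circumferential stretch r/R.
#' @param lam_z0 Longitudinal stretch l/L.
#' @return A tibble with columns `e_thetatheta` and `e_zz`.
#' @export
green_strains <- function(lam_theta, lam_z0) {
  .check_stretch(lam_theta, lam_z0)
  tibble::tibble(
    e_thetatheta = (lam_theta^2 - 1) / 2,
    e_zz = (lam_z0^2 - 1) / 2
  )
}

#' Membrane strain invariants of the Skalak law
#'
#' I = lam_theta^2 + lam_z0^2 - 2 and II = lam_theta^2 * lam_z0^2 - 1, the
#' two invariants the Skalak membrane energy depends on.
#'
#' @inheritParams green_strains
#' @return A tibble with columns `I` and `II`.
#' @export
skalak_invariants <- function(lam_theta, lam_z0) {
  .check_stretch(lam_theta, lam_z0)
  tibble::tibble(
    I = lam_theta^2 + lam_z0^2 - 2,
    II = lam_theta^2 * lam_z0^2 - 1
  )
}

#' Skalak membrane strain energy, normalized by C
#'
#' W/C = (B/4C) (I^2/2 + I - II) + II^2 / 8. Zero at the reference state
#' and non-negative over the physiological stretch range.
#'
#' @param B_over_C Modulus ratio B/C in \[0, 1\].
#' @inheritParams green_strains
#' @return Numeric vector W/C (dimensionless; energy per reference area in
#'   units of C).
#' @export
skalak_energy <- function(B_over_C, lam_theta, lam_z0) {
  if (any(B_over_C < 0) || any(B_over_C > 1)) {
    stop("skalak_energy: B_over_C must lie in [0, 1]", call. = FALSE)
  }
  inv <- skalak_invariants(lam_theta, lam_z0)
  (B_over_C / 4) * (inv$I^2 / 2 + inv$I - inv$II) + inv$II^2 / 8
}

#' Skalak membrane tensions, normalized by C
#'
#' Circumferential and longitudinal membrane tensions (Cauchy stress times
#' current thickness, N/m) of the Skalak law:
#' T_theta/C = (lam_theta/lam_z0)\[(B/2C)(lam_theta^2 - 1) +
#' (lam_z0^2/2)(lam_theta^2 lam_z0^2 - 1)\], and T_z/C with the roles of the
#' two stretches exchanged. For B/C = 0 the two tensions coincide.
#'
#' @inheritParams skalak_energy
#' @return A tibble with columns `T_theta_over_C` and `T_z_over_C`.
#' @export
skalak_tensions <- function(B_over_C, lam_theta, lam_z0) {
  if (any(B_over_C < 0) || any(B_over_C > 1)) {
    stop("skalak_tensions: B_over_C must lie in [0, 1]", call. = FALSE)
  }
  .check_stretch(lam_theta, lam_z0)
  II <- lam_theta^2 * lam_z0^2 - 1
  tibble::tibble(
    T_theta_over_C = (lam_theta / lam_z0) *
      ((B_over_C / 2) * (lam_theta^2 - 1) + (lam_z0^2 / 2) * II),
    T_z_over_C = (lam_z0 / lam_theta) *
      ((B_over_C / 2) * (lam_z0^2 - 1) + (lam_theta^2 / 2) * II)
  )
}

#' Isochoric strain invariants of an incompressible biaxial state
#'
#' I1 = lam_theta^2 + lam_z0^2 + 1/(lam_theta^2 lam_z0^2) and
#' I2 = lam_theta^2 lam_z0^2 + 1/lam_z0^2 + 1/lam_theta^2, with the radial
#' stretch eliminated through incompressibility. Both are >= 3 with equality
#' only at the undeformed state.
#'
#' @inheritParams green_strains
#' @return A tibble with columns `I1` and `I2`.
#' @export
iso_invariants <- function(lam_theta, lam_z0) {
  .check_stretch(lam_theta, lam_z0)
  tibble::tibble(
    I1 = lam_theta^2 + lam_z0^2 + 1 / (lam_theta^2 * lam_z0^2),
    I2 = lam_theta^2 * lam_z0^2 + 1 / lam_z0^2 + 1 / lam_theta^2
  )
}

#' Hariton exponential strain energy, normalized by a
#'
#' W/a = (1/b) \[exp((b/2)(I1 - 3)^2) - 1\]. The quadratic exponent makes
#' this law very stiff at large stretch; arguments of exp() beyond an
#' internal cap raise an error rather than overflowing.
#'
#' @param b Dimensionless exponent parameter (> 0).
#' @inheritParams green_strains
#' @return Numeric vector W/a (dimensionless; energy per current volume in
#'   units of a).
#' @export
hariton_energy <- function(b, lam_theta, lam_z0) {
  if (any(b <= 0)) stop("hariton_energy: b must be positive", call. = FALSE)
  I1 <- iso_invariants(lam_theta, lam_z0)$I1
  z <- (b / 2) * (I1 - 3)^2
  if (any(z > .hariton_exp_cap)) {
    stop("hariton_energy: exponent argument exceeds overflow cap (state far outside the law's range)",
         call. = FALSE)
  }
  (exp(z) - 1) / b
}

#' Hariton Cauchy stresses, normalized by a
#'
#' With the thin-wall, stress-free-outer-surface assumption the hydrostatic
#' pressure vanishes and
#' sigma_theta/a = 2 (lam_theta^2 - 1/(lam_theta^2 lam_z0^2)) (I1 - 3)
#' exp((b/2)(I1 - 3)^2); sigma_z/a has lam_z0^2 in place of lam_theta^2 in
#' the leading factor.
#'
#' @inheritParams hariton_energy
#' @return A tibble with columns `sigma_theta_over_a` and `sigma_z_over_a`.
#' @export
hariton_stresses <- function(b, lam_theta, lam_z0) {
  if (any(b <= 0)) stop("hariton_stresses: b must be positive", call. = FALSE)
  I1 <- iso_invariants(lam_theta, lam_z0)$I1
  z <- (b / 2) * (I1 - 3)^2
  if (any(z > .hariton_exp_cap)) {
    stop("hariton_stresses: exponent argument exceeds overflow cap", call. = FALSE)
  }
  lr2 <- 1 / (lam_theta^2 * lam_z0^2)   # lam_r^2 by incompressibility
  common <- 2 * (I1 - 3) * exp(z)
  tibble::tibble(
    sigma_theta_over_a = (lam_theta^2 - lr2) * common,
    sigma_z_over_a = (lam_z0^2 - lr2) * common
  )
}

#' Mooney-Rivlin strain energy, normalized by mu
#'
#' W/mu = (1/2) \[(1/2 + beta)(I1 - 3) + (1/2 - beta)(I2 - 3)\]. When either
#' stretch equals one, I1 = I2 and beta drops out.
#'
#' @param beta Mixing parameter in \[-1/2, 1/2\].
#' @inheritParams green_strains
#' @return Numeric vector W/mu.
#' @export
mr_energy <- function(beta, lam_theta, lam_z0) {
  if (any(beta < -0.5) || any(beta > 0.5)) {
    stop("mr_energy: beta must lie in [-1/2, 1/2]", call. = FALSE)
  }
  inv <- iso_invariants(lam_theta, lam_z0)
  0.5 * ((0.5 + beta) * (inv$I1 - 3) + (0.5 - beta) * (inv$I2 - 3))
}

#' Mooney-Rivlin Cauchy stresses, normalized by mu
#'
#' With sigma_rr = 0 under the thin-wall assumption:
#' sigma_theta/mu = (1/2 + beta)(lam_theta^2 - 1/(lam_theta^2 lam_z0^2)) +
#'                  (1/2 - beta)(lam_theta^2 lam_z0^2 - 1/lam_theta^2),
#' sigma_z/mu   = (1/2 + beta)(lam_z0^2 - 1/(lam_theta^2 lam_z0^2)) +
#'                (1/2 - beta)(lam_theta^2 lam_z0^2 - 1/lam_z0^2).
#' Without longitudinal pre-stretch (lam_z0 = 1) beta has no effect.
#'
#' @inheritParams mr_energy
#' @return A tibble with columns `sigma_theta_over_mu` and `sigma_z_over_mu`.
#' @export
mr_stresses <- function(beta, lam_theta, lam_z0) {
  if (any(beta < -0.5) || any(beta > 0.5)) {
    stop("mr_stresses: beta must lie in [-1/2, 1/2]", call. = FALSE)
  }
  .check_stretch(lam_theta, lam_z0)
  lr2 <- 1 / (lam_theta^2 * lam_z0^2)
  tibble::tibble(
    sigma_theta_over_mu = (0.5 + beta) * (lam_theta^2 - lr2) +
      (0.5 - beta) * (lam_theta^2 * lam_z0^2 - 1 / lam_theta^2),
    sigma_z_over_mu = (0.5 + beta) * (lam_z0^2 - lr2) +
      (0.5 - beta) * (lam_theta^2 * lam_z0^2 - 1 / lam_z0^2)
  )
}

#' Current-to-reference thickness ratio
#'
#' h/H = 1/(lam_theta * lam_z0) from incompressibility.
#'
#' @inheritParams green_strains
#' @return Numeric vector h/H.
#' @export
thickness_ratio <- function(lam_theta, lam_z0) {
  .check_stretch(lam_theta, lam_z0)
  1 / (lam_theta * lam_z0)
}

#' Initial tangent circumferential Young's modulus
#'
#' Slope of the circumferential Cauchy stress vs. circumferential stretch at
#' lam_theta = 1, used to build the equivalent linear ring model. Closed
#' forms:
#' * Skalak: E_theta = (B + 2 C lam_z0^4 - C lam_z0^2) / H (the membrane law
#'   carries units of modulus x thickness, hence the division by H);
#' * Hariton: E_theta = 4 a exp((b/2) D^2) \[(1 + 1/lam_z0^2) D +
#'   (1 - 1/lam_z0^2)^2 (1 + b D^2)\] with D = lam_z0^2 + 1/lam_z0^2 - 2,
#'   which vanishes without pre-stretch;
#' * Mooney-Rivlin: E_theta = 2 mu \[(1/2 + beta)(1 + 1/lam_z0^2) +
#'   (1/2 - beta)(1 + lam_z0^2)\].
#'
#' @param params A `skalak_params`, `hariton_params` or
#'   `mooney_rivlin_params` record.
#' @param H Wall thickness in metres (required for the Skalak membrane law).
#' @param lam_z0 Longitudinal pre-stretch.
#' @return Tangent modulus in Pa.
#' @export
tangent_modulus <- function(params, H = NULL, lam_z0 = 1) {
  stopifnot(inherits(params, "ring_params"))
  .check_stretch(1, lam_z0)
  switch(params$law,
    skalak = {
      if (is.null(H) || H <= 0) {
        stop("tangent_modulus: the Skalak membrane law needs a positive thickness H",
             call. = FALSE)
      }
      (params$B + 2 * params$C * lam_z0^4 - params$C * lam_z0^2) / H
    },
    hariton = {
      D <- lam_z0^2 + 1 / lam_z0^2 - 2
      4 * params$a * exp((params$b / 2) * D^2) *
        ((1 + 1 / lam_z0^2) * D + (1 - 1 / lam_z0^2)^2 * (1 + params$b * D^2))
    },
    mooney_rivlin = {
      2 * params$mu * ((0.5 + params$beta) * (1 + 1 / lam_z0^2) +
                         (0.5 - params$beta) * (1 + lam_z0^2))
    },
    stop("tangent_modulus: unknown law ", params$law, call. = FALSE)
  )
}

# Dimensional circumferential Cauchy stress as a function of lam_theta, used
# by the finite-difference cross-checks of the tangent modulus.
sigma_theta_dimensional <- function(params, lam_theta, lam_z0, H = NULL) {
  switch(params$law,
    skalak = {
      Tth <- skalak_tensions(params$B / params$C, lam_theta, lam_z0)$T_theta_over_C *
        params$C
      Tth * lam_theta * lam_z0 / H
    },
    hariton = hariton_stresses(params$b, lam_theta, lam_z0)$sigma_theta_over_a * params$a,
    mooney_rivlin = mr_stresses(params$beta, lam_theta, lam_z0)$sigma_theta_over_mu *
      params$mu,
    stop("unknown law", call. = FALSE)
  )
}
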