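# Dimensionless equations of motion for the hyperelastic ring models.
#
# With x = u_r/R and tau = t/t_char, every model takes the form
#
#     x'' = load(x, p_hat(tau)) - g(x)
#
# where g is the dimensionless restoring force derived from the law's
# circumferential tension and load is (1 + x) * p_hat for the full nonlinear
# models (the pressure acts on the current radius). The Skalak g is an exact
# cubic polynomial in x, which yields the zero/first/second/third-order
# truncation hierarchy; the zero-order model additionally drops the
# p_hat * x coupling, making it linear. The equivalent linear model uses the
# initial tangent modulus as stiffness and drops the radius coupling too.
#
# The inertia coefficient rho0 * h * r = rho0 * H * R / lam_z0 is constant in
# time by incompressibility, which is what makes the printed characteristic
# times exact.

#' Dimensionless parameter groups of a ring model
#'
#' The normalized problem a simulation runs on: which law, its dimensionless
#' material ratio (B/C for Skalak, b for Hariton, beta for Mooney-Rivlin,
#' the mimicked law's ratio for the linear model), the normalized systolic
#' pressure (ps R / C, ps R / (a H), or ps R / (mu H)), the axial
#' pre-stretch, and the waveform in characteristic-time units.
#'
#' @param law One of `"skalak"`, `"hariton"`, `"mooney_rivlin"`, `"linear"`.
#' @param material_ratio Law-dependent dimensionless material parameter.
#' @param p_hat_s Normalized systolic pressure (> 0).
#' @param lam_z0 Longitudinal pre-stretch.
#' @param time_ratio Cardiac-cycle duration over characteristic time,
#'   tcp / t_char (> 0); this is also the cycle period in tau units.
#' @param duty Systolic fraction ts / tcp of the cycle (default 0.35).
#' @param pressure_ratio Diastolic over systolic pressure pd / ps
#'   (default 10.66/16).
#' @param order Truncation order 0-3 of the Skalak restoring polynomial
#'   (3 = exact cubic; ignored by the other laws, which are always full).
#' @param base_law For `law = "linear"`, the hyperelastic law whose initial
#'   tangent modulus sets the linear stiffness.
#' @return An object of class `ring_groups`.
#' @examples
#' ring_groups("skalak", material_ratio = 0, p_hat_s = 0.16,
#'             lam_z0 = 1, time_ratio = 2000)
#' @export
ring_groups <- function(law = c("skalak", "hariton", "mooney_rivlin", "linear"),
                        material_ratio, p_hat_s, lam_z0 = 1, time_ratio,
                        duty = 0.35, pressure_ratio = 10.66 / 16,
                        order = 3L, base_law = "skalak") {
  law <- match.arg(law)
  if (p_hat_s <= 0) stop("ring_groups: p_hat_s must be positive", call. = FALSE)
  if (time_ratio <= 0) stop("ring_groups: time_ratio must be positive", call. = FALSE)
  if (duty <= 0 || duty >= 1) stop("ring_groups: duty must lie in (0, 1)", call. = FALSE)
  if (pressure_ratio < 0 || pressure_ratio > 1) {
    stop("ring_groups: pressure_ratio must lie in [0, 1]", call. = FALSE)
  }
  .check_stretch(1, lam_z0)
  order <- as.integer(order)
  if (law == "skalak" && !(order %in% 0:3)) {
    stop("ring_groups: Skalak truncation order must be 0, 1, 2 or 3", call. = FALSE)
  }
  .validate_ratio(law, material_ratio)
  if (law == "linear") .validate_ratio(base_law, material_ratio)
  structure(list(law = law, material_ratio = material_ratio, p_hat_s = p_hat_s,
                 lam_z0 = lam_z0, time_ratio = time_ratio, duty = duty,
                 pressure_ratio = pressure_ratio,
                 order = if (law == "skalak") order else 3L,
                 base_law = if (law == "linear") base_law else law),
            class = "ring_groups")
}

.validate_ratio <- function(law, ratio) {
  ok <- switch(law,
    skalak = ratio >= 0 && ratio <= 1,
    hariton = ratio > 0,
    mooney_rivlin = ratio >= -0.5 && ratio <= 0.5,
    linear = TRUE,
    FALSE)
  if (!ok) stop("invalid material_ratio for law '", law, "'", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.ring_groups <- function(x, ...) {
  cat("<ring_groups> law:", x$law,
      if (x$law == "skalak") paste0("(order ", x$order, ")"),
      if (x$law == "linear") paste0("(tangent of ", x$base_law, ")"), "\n")
  cat(sprintf("  material_ratio = %g, p_hat_s = %g, lam_z0 = %g\n",
              x$material_ratio, x$p_hat_s, x$lam_z0))
  cat(sprintf("  time_ratio = %g, duty = %g, pressure_ratio = %g\n",
              x$time_ratio, x$duty, x$pressure_ratio))
  invisible(x)
}

#' Characteristic time of a ring model
#'
#' The natural time scale of the dimensionless equation of motion:
#' t_Sk = sqrt(rho0 R^2 H / (C lam_z0)) for the Skalak membrane law,
#' t_H = sqrt(rho0 R^2 / (a lam_z0)) for the Hariton law, and
#' t_MR = sqrt(rho0 R^2 / (mu lam_z0)) for Mooney-Rivlin.
#'
#' @param params A material parameter record (see [skalak_params()]).
#' @param geometry An [artery_geometry()].
#' @return Characteristic time in seconds.
#' @export
characteristic_time <- function(params, geometry) {
  stopifnot(inherits(params, "ring_params"), inherits(geometry, "artery_geometry"))
  with(geometry, switch(params$law,
    skalak = sqrt(rho0 * R^2 * H / (params$C * lam_z0)),
    hariton = sqrt(rho0 * R^2 / (params$a * lam_z0)),
    mooney_rivlin = sqrt(rho0 * R^2 / (params$mu * lam_z0)),
    stop("characteristic_time: unknown law", call. = FALSE)
  ))
}

#' Dimensionless restoring force of a ring model
#'
#' The non-pressure, non-inertia side g(x) of the equation of motion
#' x'' = (1 + x) p_hat - g(x), with lam = 1 + x:
#' * Skalak: g = (lam/lam_z0)\[(B/2C)(lam^2 - 1) +
#'   (lam_z0^2/2)(lam^2 lam_z0^2 - 1)\] (exactly cubic in x);
#' * Hariton: g = (2/lam_z0)(lam - 1/(lam^3 lam_z0^2))(I1 - 3)
#'   exp((b/2)(I1 - 3)^2);
#' * Mooney-Rivlin: g = (1/lam_z0)\[(1/2 + beta)(lam - 1/(lam^3 lam_z0^2)) +
#'   (1/2 - beta)(lam lam_z0^2 - 1/lam^3)\].
#' In every case g is the derivative of the normalized strain energy with
#' respect to x, divided by lam_z0.
#'
#' @param law `"skalak"`, `"hariton"` or `"mooney_rivlin"`.
#' @param material_ratio B/C, b, or beta.
#' @param lam_z0 Longitudinal pre-stretch.
#' @param x Normalized radial displacement u_r/R (vectorized; needs
#'   1 + x > 0).
#' @param order Skalak truncation order (0-3; 3 = exact).
#' @return g(x), dimensionless.
#' @export
restoring_term <- function(law, material_ratio, lam_z0, x, order = 3L) {
  if (any(1 + x <= 0)) {
    stop("restoring_term: ring collapsed (1 + x <= 0)", call. = FALSE)
  }
  lam <- 1 + x
  switch(law,
    skalak = {
      # order-k truncation keeps powers up to x^k (k = 3 is the exact
      # cubic); the zero-order model keeps the linear stiffness and instead
      # drops the p_hat * x load coupling, so its g equals order 1's
      k <- max(as.integer(order), 1L)
      cf <- skalak_polynomial_coeffs(material_ratio, lam_z0)
      g <- cf[["c0"]] + cf[["c1"]] * x
      if (k >= 2) g <- g + cf[["c2"]] * x^2
      if (k >= 3) g <- g + cf[["c3"]] * x^3
      g
    },
    hariton = {
      b <- material_ratio
      I1 <- lam^2 + lam_z0^2 + 1 / (lam^2 * lam_z0^2)
      z <- (b / 2) * (I1 - 3)^2
      if (any(z > .hariton_exp_cap)) {
        stop("restoring_term: Hariton exponent argument exceeds overflow cap", call. = FALSE)
      }
      (2 / lam_z0) * (lam - 1 / (lam^3 * lam_z0^2)) * (I1 - 3) * exp(z)
    },
    mooney_rivlin = {
      beta <- material_ratio
      (1 / lam_z0) * ((0.5 + beta) * (lam - 1 / (lam^3 * lam_z0^2)) +
                        (0.5 - beta) * (lam * lam_z0^2 - 1 / lam^3))
    },
    stop("restoring_term: unknown law ", law, call. = FALSE)
  )
}

#' Polynomial coefficients of the Skalak restoring force
#'
#' g(x) = c0 + c1 x + c2 x^2 + c3 x^3 exactly, with
#' c0 = (lam_z0^3 - lam_z0)/2,
#' c1 = B/(C lam_z0) + (3/2) lam_z0^3 - lam_z0/2,
#' c2 = (3/2)(B/(C lam_z0) + lam_z0^3),
#' c3 = (1/2)(B/(C lam_z0) + lam_z0^3).
#'
#' @param B_over_C Modulus ratio B/C.
#' @param lam_z0 Longitudinal pre-stretch.
#' @return Named numeric vector `c(c0, c1, c2, c3)`.
#' @export
skalak_polynomial_coeffs <- function(B_over_C, lam_z0) {
  .check_stretch(1, lam_z0)
  r <- B_over_C / lam_z0
  c(c0 = (lam_z0^3 - lam_z0) / 2,
    c1 = r + 1.5 * lam_z0^3 - lam_z0 / 2,
    c2 = 1.5 * (r + lam_z0^3),
    c3 = 0.5 * (r + lam_z0^3))
}

# Derivative g'(x) of the restoring force at arbitrary x (used for
# linearized small-oscillation frequencies about a static state and for the
# adaptive output grid).
restoring_slope <- function(law, material_ratio, lam_z0, x, order = 3L) {
  lam <- 1 + x
  switch(law,
    skalak = {
      cf <- skalak_polynomial_coeffs(material_ratio, lam_z0)
      k <- max(as.integer(order), 1L)
      s <- cf[["c1"]] + 0 * x
      if (k >= 2) s <- s + 2 * cf[["c2"]] * x
      if (k >= 3) s <- s + 3 * cf[["c3"]] * x^2
      s
    },
    hariton = {
      b <- material_ratio
      I1 <- lam^2 + lam_z0^2 + 1 / (lam^2 * lam_z0^2)
      dI1 <- 2 * lam - 2 / (lam^3 * lam_z0^2)
      d2I1 <- 2 + 6 / (lam^4 * lam_z0^2)
      E <- exp((b / 2) * (I1 - 3)^2)
      # g = (1/lam_z0) d/dlam [ (1/b)(E - 1) ] = (1/lam_z0) (I1-3) dI1 E
      (1 / lam_z0) * E * (dI1^2 * (1 + b * (I1 - 3)^2) + (I1 - 3) * d2I1)
    },
    mooney_rivlin = {
      beta <- material_ratio
      (1 / lam_z0) * ((0.5 + beta) * (1 + 3 / (lam^4 * lam_z0^2)) +
                        (0.5 - beta) * (lam_z0^2 + 3 / lam^4))
    },
    stop("restoring_slope: unknown law ", law, call. = FALSE)
  )
}

# Dimensionless stiffness of the equivalent linear model:
# k_hat = E_theta * H / (scale * lam_z0) where scale is C (Skalak),
# a*H (Hariton) or mu*H (Mooney-Rivlin). Equals the zero-order stiffness
# only at lam_z0 = 1.
linear_khat <- function(base_law, material_ratio, lam_z0) {
  switch(base_law,
    skalak = (material_ratio + 2 * lam_z0^4 - lam_z0^2) / lam_z0,
    hariton = {
      b <- material_ratio
      D <- lam_z0^2 + 1 / lam_z0^2 - 2
      4 * exp((b / 2) * D^2) *
        ((1 + 1 / lam_z0^2) * D + (1 - 1 / lam_z0^2)^2 * (1 + b * D^2)) / lam_z0
    },
    mooney_rivlin = 2 * ((0.5 + material_ratio) * (1 + 1 / lam_z0^2) +
                           (0.5 - material_ratio) * (1 + lam_z0^2)) / lam_z0,
    stop("linear_khat: unknown base law ", base_law, call. = FALSE)
  )
}

# Internal bundle of the functions a ring model needs: the dynamic restoring
# force g and its potential V (integral of g, V(0) = 0 for the truncations;
# for full laws V(x) = (W_norm(1+x) - W_norm(1)) / lam_z0), whether the
# pressure couples to the current radius, and the constitutive reporting
# functions (always the full law, regardless of dynamic truncation).
ring_fns <- function(groups) {
  law <- groups$law
  mr <- groups$material_ratio
  lz <- groups$lam_z0
  ord <- groups$order

  if (law == "linear") {
    kh <- linear_khat(groups$base_law, mr, lz)
    g <- function(x) kh * x
    dg <- function(x) rep(kh, length(x))
    V <- function(x) kh * x^2 / 2
    load_coupled <- FALSE
    load_scale <- 1 / lz
    # report linear-model quantities normalized by the base law's 3-D
    # stress scale: sigma/scale = k_hat * lam_z0 * x, W = integral sigma deps
    W_norm <- function(lam) 0.5 * kh * lz * (lam - 1)^2
    s_th <- function(lam) kh * lz * (lam - 1)
    s_z <- s_th
  } else {
    g <- function(x) restoring_term(law, mr, lz, x, order = ord)
    dg <- function(x) restoring_slope(law, mr, lz, x, order = ord)
    if (law == "skalak" && ord < 3L) {
      cf <- skalak_polynomial_coeffs(mr, lz)
      V <- function(x) {
        v <- cf[["c0"]] * x + cf[["c1"]] * x^2 / 2
        if (ord >= 2) v <- v + cf[["c2"]] * x^3 / 3
        v
      }
    } else {
      W0 <- switch(law,
        skalak = skalak_energy(mr, 1, lz),
        hariton = hariton_energy(mr, 1, lz),
        mooney_rivlin = mr_energy(mr, 1, lz))
      Wfun <- switch(law,
        skalak = function(lam) skalak_energy(mr, lam, lz),
        hariton = function(lam) hariton_energy(mr, lam, lz),
        mooney_rivlin = function(lam) mr_energy(mr, lam, lz))
      V <- function(x) (Wfun(1 + x) - W0) / lz
    }
    load_coupled <- !(law == "skalak" && ord == 0L)
    load_scale <- 1
    W_norm <- switch(law,
      skalak = function(lam) skalak_energy(mr, lam, lz),
      hariton = function(lam) hariton_energy(mr, lam, lz),
      mooney_rivlin = function(lam) mr_energy(mr, lam, lz))
    s_th <- switch(law,
      skalak = function(lam) skalak_tensions(mr, lam, lz)$T_theta_over_C,
      hariton = function(lam) hariton_stresses(mr, lam, lz)$sigma_theta_over_a,
      mooney_rivlin = function(lam) mr_stresses(mr, lam, lz)$sigma_theta_over_mu)
    s_z <- switch(law,
      skalak = function(lam) skalak_tensions(mr, lam, lz)$T_z_over_C,
      hariton = function(lam) hariton_stresses(mr, lam, lz)$sigma_z_over_a,
      mooney_rivlin = function(lam) mr_stresses(mr, lam, lz)$sigma_z_over_mu)
  }

  load_fun <- if (load_coupled) {
    function(x, p_hat) (1 + x) * p_hat
  } else {
    function(x, p_hat) rep(p_hat * load_scale, length(x))
  }
  work_fun <- if (load_coupled) {
    function(x, p_hat) p_hat * (x + x^2 / 2)
  } else {
    function(x, p_hat) p_hat * load_scale * x
  }

  # parameter block for the compiled deSolve model (law code + 4 numbers)
  if (law == "linear") {
    law_code <- 3; law_par <- c(linear_khat(groups$base_law, mr, lz), 0, 0, 0)
  } else if (law == "skalak") {
    cf <- skalak_polynomial_coeffs(mr, lz)
    if (ord < 3L) cf[(max(ord, 1L) + 2L):4L] <- 0
    law_code <- 0; law_par <- unname(cf)
  } else if (law == "hariton") {
    law_code <- 1; law_par <- c(mr, lz, 0, 0)
  } else {
    law_code <- 2; law_par <- c(mr, lz, 0, 0)
  }

  list(g = g, dg = dg, V = V,
       load_coupled = load_coupled, load_scale = load_scale,
       load_fun = load_fun, work_fun = work_fun,
       W_norm = W_norm, stress_theta_norm = s_th, stress_z_norm = s_z,
       law_code = law_code, law_par = law_par)
}

#' Right-hand side of the dimensionless ring equation of motion
#'
#' Evaluates (dx/dtau, dv/dtau) for a given state and instantaneous
#' normalized pressure: dv/dtau = (1 + x) p_hat - g(x) for the full
#' nonlinear models; the Skalak zero-order truncation and the linear model
#' drop the p_hat x coupling.
#'
#' @param groups A [ring_groups()].
#' @param x Normalized radial displacement.
#' @param v dx/dtau.
#' @param p_hat Instantaneous normalized pressure.
#' @return A list with elements `dx` and `dv`.
#' @export
ring_deriv <- function(groups, x, v, p_hat) {
  stopifnot(inherits(groups, "ring_groups"))
  fns <- ring_fns(groups)
  if (any(1 + x <= 0)) stop("ring_deriv: ring collapsed (1 + x <= 0)", call. = FALSE)
  list(dx = v, dv = fns$load_fun(x, p_hat) - fns$g(x))
}

#' Zero-order (small-oscillation) natural frequency
#'
#' Linearizes the restoring force about the reference state x = 0:
#' omega0 = sqrt(g'(0)) / t_char. For the Skalak law
#' g'(0) = B/(C lam_z0) + (3/2) lam_z0^3 - lam_z0/2, so with no pre-stretch
#' and B/C = 0 a characteristic time of 0.5 ms gives 2000 s^-1. For
#' Mooney-Rivlin at lam_z0 = 1 this reduces to Knowles' classical
#' omega0 = 2/t_MR. The Hariton restoring force has zero initial slope at
#' lam_z0 = 1, so its zero-order frequency vanishes there. A negative
#' linearized stiffness (possible for Skalak with lam_z0 < 1 and C > 24 B,
#' a material-instability regime) is returned as a flagged non-oscillatory
#' result instead of an error.
#'
#' @param law `"skalak"`, `"hariton"` or `"mooney_rivlin"`.
#' @param material_ratio B/C, b, or beta.
#' @param lam_z0 Longitudinal pre-stretch.
#' @param t_char Characteristic time in seconds (default 1: returns the
#'   dimensionless product omega0 * t_char).
#' @return A tibble with columns `omega0` (rad/s), `omega0_tchar`
#'   (dimensionless), and `oscillatory` (FALSE when the linearized stiffness
#'   is negative, in which case `omega0` is `NA`).
#' @export
natural_frequency <- function(law, material_ratio, lam_z0 = 1, t_char = 1) {
  if (t_char <= 0) stop("natural_frequency: t_char must be positive", call. = FALSE)
  gp0 <- restoring_slope(law, material_ratio, lam_z0, 0)
  if (gp0 < 0) {
    tibble::tibble(omega0 = NA_real_, omega0_tchar = NA_real_, oscillatory = FALSE)
  } else {
    tibble::tibble(omega0 = sqrt(gp0) / t_char, omega0_tchar = sqrt(gp0),
                   oscillatory = TRUE)
  }
}

#' Static equilibrium of a ring under constant normalized pressure
#'
#' Solves g(x) = (1 + x) p_hat (or the uncoupled analogue for the
#' zero-order/linear models) for the equilibrium displacement. For the
#' Mooney-Rivlin law at lam_z0 = 1 this reduces to (1 - p_hat) lam^4 = 1,
#' which has a solution only for p_hat < 1 — the bounded-response limit.
#'
#' @param groups A [ring_groups()].
#' @param p_hat Constant normalized pressure (default the systolic level).
#' @param upper Search upper bound for x.
#' @return The equilibrium x, or `NA` (with a warning) if none exists below
#'   `upper`.
#' @export
static_equilibrium <- function(groups, p_hat = groups$p_hat_s, upper = 19) {
  stopifnot(inherits(groups, "ring_groups"))
  fns <- ring_fns(groups)
  f <- function(x) fns$g(x) - fns$load_fun(x, p_hat)
  # exponential laws overflow far outside the physical range; a huge
  # restoring force just means f > 0 there
  safe_f <- function(x) tryCatch(f(x), error = function(e) Inf)
  f0 <- safe_f(0)
  if (f0 == 0) return(0)
  if (f0 > 0) {
    # equilibrium is inward: expand the bracket towards collapse
    a <- 0; step <- 0.05; b <- -step
    while (b > -1 + 1e-9 && safe_f(b) > 0) {
      a <- b; step <- step * 2; b <- max(b - step, -1 + 1e-9)
    }
    if (safe_f(b) > 0) {
      warning("static_equilibrium: no equilibrium above collapse", call. = FALSE)
      return(NA_real_)
    }
    lo <- b; hi <- a
  } else {
    a <- 0; step <- 0.05; b <- step
    while (b < upper && safe_f(b) < 0) {
      a <- b; step <- step * 2; b <- min(b + step, upper)
    }
    while (!is.finite(safe_f(b))) b <- (a + b) / 2
    if (safe_f(b) < 0) {
      warning("static_equilibrium: no equilibrium below the stretch cap (unbounded regime)",
              call. = FALSE)
      return(NA_real_)
    }
    lo <- a; hi <- b
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
}
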