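# Worked validation examples on published artery data, plus the pulse-wave
# helper relations: the distension exponent alpha of the exponential
# pressure-area law p = pd exp(alpha (A/Ad - 1)), and the axial-to-radial
# displacement ratio of the travelling wall wave.

# Registry of the two published example cases. Pressures are stored in Pa
# after subtracting the residual-stress offset; the `time_ratio` entries are
# the published dimensionless groups, which are taken as the simulation
# inputs (the published cycle ratios are normalized with tcp_norm = 1 s even
# when the example's own cycle is shorter).
example_registry <- function() {
  list(
    demiray = list(
      label = "Demiray-Vito dog abdominal aorta",
      geometry = artery_geometry(R = 3.46e-3, H = 0.68e-3, rho0 = 1160, lam_z0 = 1.53),
      pulse = pressure_pulse(ps = 9892, pd = 3466, ts = 0.35, tcp = 1, n_cycles = 1L),
      residual_offset = 0,
      tcp_norm = 1,
      n_cycles = 1L,
      laws = list(
        skalak = list(material_ratio = 1, p_hat_s = 1.16, time_ratio = 2187),
        hariton = list(material_ratio = 1.5, p_hat_s = 4.19, time_ratio = 1143)
      )
    ),
    humphrey = list(
      label = "Humphrey-Na artery (residual stress as 50 mmHg pressure offset)",
      geometry = artery_geometry(R = 1.69e-3, H = 0.6e-3, rho0 = 1160, lam_z0 = 1.832),
      # raw 105/91 mmHg minus the 50 mmHg compressive residual offset
      pulse = pressure_pulse(ps = 7333, pd = 5466, ts = 0.3, tcp = 0.8, n_cycles = 2L),
      residual_offset = mmHg_to_Pa(50),
      tcp_norm = 1,
      n_cycles = 2L,
      laws = list(
        skalak = list(material_ratio = 0.5, p_hat_s = 4.04, time_ratio = 1679),
        hariton = list(material_ratio = 1.5, p_hat_s = 111.9, time_ratio = 319)
      )
    )
  )
}

#' Published example cases
#'
#' Returns the input record for one of the two published validation
#' examples: `"demiray"` (dog abdominal aorta under a 74.2/26 mmHg pulse,
#' strong pre-stretch 1.53) or `"humphrey"` (artery with residual
#' circumferential stress modeled as a constant 50 mmHg compressive
#' pressure offset, leaving an effective 55/41 mmHg pulse, pre-stretch
#' 1.832, two cardiac cycles).
#'
#' @param name `"demiray"` or `"humphrey"`.
#' @return A list with the geometry, effective pulse, residual offset and
#'   the published per-law dimensionless parameter blocks.
#' @export
example_case <- function(name) {
  reg <- example_registry()
  if (!name %in% names(reg)) {
    stop("example_case: unknown case '", name, "'; available: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  }
  reg[[name]]
}

#' Dimensionless groups of an example case, recomputed from its data
#'
#' Recovers the material constant from the published normalized systolic
#' pressure (C = ps R / (ps R / C), and analogously a and mu), computes the
#' characteristic time and cycle ratio from the case data, and tabulates
#' them next to the published values. The cycle ratio is normalized with
#' `tcp_norm` (1 s), the convention the published groups follow.
#'
#' @param case Case name or a record from [example_case()].
#' @param law `"skalak"` or `"hariton"`.
#' @return A tibble with columns `group`, `published`, `computed`.
#' @export
example_groups <- function(case, law) {
  if (is.character(case)) case <- example_case(case)
  if (!law %in% names(case$laws)) {
    stop("example_groups: law '", law, "' has no published block for this case",
         call. = FALSE)
  }
  blk <- case$laws[[law]]
  geo <- case$geometry
  psR <- case$pulse$ps * geo$R
  params <- switch(law,
    skalak = skalak_params(B = blk$material_ratio * psR / blk$p_hat_s,
                           C = psR / blk$p_hat_s),
    hariton = hariton_params(a = psR / (blk$p_hat_s * geo$H), b = blk$material_ratio),
    mooney_rivlin = mooney_rivlin_params(mu = psR / (blk$p_hat_s * geo$H),
                                         beta = blk$material_ratio))
  t_char <- characteristic_time(params, geo)
  tibble::tibble(
    group = c("material_ratio", "p_hat_s", "time_ratio", "duty", "pressure_ratio"),
    published = c(blk$material_ratio, blk$p_hat_s, blk$time_ratio,
                  case$pulse$ts / case$pulse$tcp, case$pulse$pd / case$pulse$ps),
    computed = c(blk$material_ratio, blk$p_hat_s, case$tcp_norm / t_char,
                 case$pulse$ts / case$pulse$tcp, case$pulse$pd / case$pulse$ps)
  )
}

#' Run a published example case
#'
#' Simulates a case from its published dimensionless parameter block
#' (material ratio, normalized systolic pressure, cycle ratio), then
#' converts the peak response back to physical units with the material
#' constant implied by the normalized pressure. Warns when a law is used
#' far outside its validated pre-stretch range (the Mooney-Rivlin softening
#' law is not suited to the large pre-stretches of these examples).
#'
#' @param case `"demiray"` or `"humphrey"` (or an [example_case()] record).
#' @param law `"skalak"` or `"hariton"`.
#' @param settings A [solver_settings()].
#' @return A list with elements `groups` (the [ring_groups()] simulated),
#'   `params`, `trace`, `summary` (normalized peaks) and `report` (physical
#'   peaks from [dimensionalise()]).
#' @examples
#' \donttest{run_example("demiray", "hariton")$report}
#' @export
run_example <- function(case, law, settings = solver_settings()) {
  if (is.character(case)) case <- example_case(case)
  if (!law %in% names(case$laws)) {
    stop("run_example: law '", law, "' has no published block for this case",
         call. = FALSE)
  }
  blk <- case$laws[[law]]
  geo <- case$geometry
  if (law == "mooney_rivlin" && geo$lam_z0 > 1.35) {
    warning("run_example: Mooney-Rivlin is outside its validated pre-stretch range here",
            call. = FALSE)
  }
  gr <- ring_groups(law, material_ratio = blk$material_ratio, p_hat_s = blk$p_hat_s,
                    lam_z0 = geo$lam_z0, time_ratio = blk$time_ratio,
                    duty = case$pulse$ts / case$pulse$tcp,
                    pressure_ratio = case$pulse$pd / case$pulse$ps)
  tr <- simulate_ring(gr, n_cycles = case$n_cycles, settings = settings,
                      tcp = case$tcp_norm)
  sm <- summarise_response(tr)
  psR <- case$pulse$ps * geo$R
  params <- switch(law,
    skalak = skalak_params(B = blk$material_ratio * psR / blk$p_hat_s,
                           C = psR / blk$p_hat_s),
    hariton = hariton_params(a = psR / (blk$p_hat_s * geo$H), b = blk$material_ratio),
    mooney_rivlin = mooney_rivlin_params(mu = psR / (blk$p_hat_s * geo$H),
                                         beta = blk$material_ratio))
  list(groups = gr, params = params, trace = tr, summary = sm,
       report = dimensionalise(sm, params, geo))
}

#' Systolic and diastolic distension stretches of a ring model
#'
#' The quasi-static circumferential stretch the artery holds at the
#' systolic pressure level is taken as the midpoint of the first radial
#' oscillation under a suddenly applied constant systolic load from rest —
#' i.e. half the first dynamic peak, computed exactly from the energy
#' balance V(x) = p_hat (x + x^2/2). The diastolic stretch scales the
#' systolic excursion by pd/ps (small-signal proportionality of displacement
#' to pressure). These are the stretches the distension exponent
#' [alpha_from_stretches()] is built from.
#'
#' @param groups A [ring_groups()] (its `p_hat_s` and `pressure_ratio` set
#'   the two pressure levels).
#' @return A one-row tibble with `x_peak` (first dynamic peak), `lam_s`,
#'   `lam_d`.
#' @export
distension_stretches <- function(groups) {
  stopifnot(inherits(groups, "ring_groups"))
  fns <- ring_fns(groups)
  p <- groups$p_hat_s
  Phi <- function(x) fns$V(x) - fns$work_fun(x, p)
  dPhi <- function(x) fns$g(x) - fns$load_fun(x, p)
  turns <- turning_points(Phi, dPhi, 0, 0, cap = 20)
  x_peak <- turns[["hi"]]
  if (!is.finite(x_peak)) {
    stop("distension_stretches: unbounded response at this pressure level", call. = FALSE)
  }
  mid <- x_peak / 2
  tibble::tibble(x_peak = x_peak,
                 lam_s = 1 + mid,
                 lam_d = 1 + mid * groups$pressure_ratio)
}

#' Distension exponent from systolic/diastolic stretches
#'
#' alpha = ln(ps/pd) / \[(lam_s/lam_d)^2 - 1\], the exponent of the
#' empirical exponential pressure-area relation p = pd exp(alpha (A/Ad - 1))
#' evaluated from the circumferential stretches held at the two pressure
#' levels.
#'
#' @param ps_over_pd Systolic over diastolic pressure (> 0).
#' @param lam_s,lam_d Systolic and diastolic circumferential stretches
#'   (`lam_s > lam_d` strictly).
#' @return alpha (dimensionless, positive for ps > pd).
#' @export
alpha_from_stretches <- function(ps_over_pd, lam_s, lam_d) {
  if (any(ps_over_pd <= 0) || any(lam_s <= 0) || any(lam_d <= 0)) {
    stop("alpha_from_stretches: inputs must be positive", call. = FALSE)
  }
  if (any(lam_s <= lam_d)) {
    stop("alpha_from_stretches: need lam_s > lam_d (equal stretches make the denominator zero)",
         call. = FALSE)
  }
  log(ps_over_pd) / ((lam_s / lam_d)^2 - 1)
}

#' Carotid distension exponent as a function of age
#'
#' The empirical ageing trend alpha = 0.42 (1 + 0.0602 age), with age in
#' years; alpha grows from 0.42 at birth towards the upper end of the
#' measured 1-8 range in old age.
#'
#' @param age_years Age in years (>= 0).
#' @return alpha (dimensionless).
#' @export
alpha_from_age <- function(age_years) {
  if (any(age_years < 0)) stop("alpha_from_age: age must be non-negative", call. = FALSE)
  0.42 * (1 + 0.0602 * age_years)
}

#' Axial-to-radial wall displacement ratio of the travelling pulse
#'
#' Thin-shell estimate u_z^s / u_r^s = (nu lambda / (2 pi R)) (1 - c^2/cp^2)
#' relating the systolic axial wall displacement to the radial one through
#' the Poisson ratio, the longitudinal wavelength, the vessel radius, and
#' the ratio of the phase velocity c to the plate velocity cp.
#'
#' @param nu Poisson ratio in \[0, 1/2\].
#' @param wavelength Longitudinal wavelength in metres.
#' @param R Vessel radius in metres.
#' @param c Phase velocity in m/s.
#' @param cp Plate velocity in m/s (> 0).
#' @return The dimensionless ratio u_z^s / u_r^s.
#' @export
axial_ratio <- function(nu, wavelength, R, c, cp) {
  if (any(nu < 0) || any(nu > 0.5)) stop("axial_ratio: nu must lie in [0, 1/2]", call. = FALSE)
  if (any(wavelength <= 0) || any(R <= 0) || any(c < 0)) {
    stop("axial_ratio: lengths and speeds must be positive", call. = FALSE)
  }
  if (any(cp <= 0)) stop("axial_ratio: cp must be positive", call. = FALSE)
  (nu * wavelength / (2 * pi * R)) * (1 - c^2 / cp^2)
}

#' Distension-exponent benchmark parameter sets
#'
#' The three published benchmark configurations for the distension exponent
#' (soft, medium-stiff and stiff Skalak walls under a 16 kPa systolic /
#' ps/pd = 1.51 pulse) together with their published stretches and alpha
#' values, as a tibble ready to drive [distension_stretches()].
#'
#' @return A tibble with columns `p_hat_s`, `material_ratio`, `lam_z0`,
#'   `ps_over_pd`, `alpha_published`.
#' @export
alpha_benchmarks <- function() {
  tibble::tibble(
    p_hat_s = c(0.80, 0.16, 0.16),
    material_ratio = c(0.5, 0.5, 1),
    lam_z0 = c(1.1, 1, 1),
    ps_over_pd = 1.51,
    alpha_published = c(2.37, 6.59, 8.49)
  )
}
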