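# Pressure loading: the rectangular systole/diastole approximation of the
# aortic pulse. The idealized square wave (instantaneous rise and fall) is
# the most conservative loading for the ring, and the dynamic overshoot seen
# in the response tables is consistent only with a step; the waveform's jump
# times are reported to the integrator as restart points rather than being
# smoothed.

#' Rectangular arterial pressure pulse
#'
#' A periodic two-level waveform: systolic plateau `ps` for the first `ts`
#' seconds of each cardiac cycle of length `tcp`, diastolic plateau `pd` for
#' the remainder. Defaults are the nominal aortic values 120/80 mmHg with a
#' 0.35 s systolic phase in a 1 s cycle.
#'
#' @param ps Systolic pressure in Pa (default 16 kPa = 120 mmHg).
#' @param pd Diastolic pressure in Pa (default 10.66 kPa = 80 mmHg).
#' @param ts Systolic-phase duration in seconds.
#' @param tcp Cardiac-cycle duration in seconds.
#' @param n_cycles Number of cycles the waveform covers.
#' @return An object of class `pressure_pulse`.
#' @examples
#' p <- pressure_pulse()
#' pressure_at(p, c(0.2, 0.5))
#' @export
pressure_pulse <- function(ps = 16000, pd = 10660, ts = 0.35, tcp = 1, n_cycles = 1L) {
  if (!(ps >= pd && pd >= 0)) stop("pressure_pulse: need ps >= pd >= 0", call. = FALSE)
  if (!(ts > 0 && ts < tcp)) stop("pressure_pulse: need 0 < ts < tcp", call. = FALSE)
  if (n_cycles < 1) stop("pressure_pulse: n_cycles must be >= 1", call. = FALSE)
  structure(list(ps = ps, pd = pd, ts = ts, tcp = tcp, n_cycles = as.integer(n_cycles)),
            class = "pressure_pulse")
}

#' Evaluate the pressure pulse at given times
#'
#' Periodic extension of the rectangular waveform: `ps` for
#' (t mod tcp) in \[0, ts\], `pd` otherwise.
#'
#' @param pulse A [pressure_pulse()].
#' @param t Times in seconds (non-negative).
#' @return Pressures in Pa.
#' @export
pressure_at <- function(pulse, t) {
  stopifnot(inherits(pulse, "pressure_pulse"))
  if (any(t < 0)) stop("pressure_at: t must be non-negative", call. = FALSE)
  phase <- t %% pulse$tcp
  ifelse(phase <= pulse$ts, pulse$ps, pulse$pd)
}

#' Convert millimetres of mercury to pascal
#'
#' @param x Pressure in mmHg.
#' @return Pressure in Pa (1 mmHg = 133.322 Pa).
#' @export
mmHg_to_Pa <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  x * 133.322
}

#' Dimensionless pressure profile in characteristic-time units
#'
#' Collapses a physical pulse into the two-level periodic function the
#' dimensionless ring equation is driven by: high level `p_hat_s` (the
#' normalized systolic pressure, e.g. ps R / C), low level
#' `p_hat_s * pd/ps`, period `tcp / t_char`, duty fraction `ts / tcp`.
#'
#' @param pulse A [pressure_pulse()].
#' @param p_hat_s The normalized systolic plateau (pressure divided by the
#'   law's pressure scale, e.g. ps R / C).
#' @param t_char Characteristic time of the ring model in seconds.
#' @return A function `p_hat(tau)` of dimensionless time, with attributes
#'   `period`, `duty`, `levels`.
#' @export
normalized_profile <- function(pulse, p_hat_s, t_char) {
  stopifnot(inherits(pulse, "pressure_pulse"))
  if (p_hat_s <= 0 || t_char <= 0) {
    stop("normalized_profile: p_hat_s and t_char must be positive", call. = FALSE)
  }
  period <- pulse$tcp / t_char
  duty <- pulse$ts / pulse$tcp
  lo <- p_hat_s * pulse$pd / pulse$ps
  f <- function(tau) {
    if (any(tau < 0)) stop("normalized_profile: tau must be non-negative", call. = FALSE)
    phase <- tau %% period
    ifelse(phase <= duty * period, p_hat_s, lo)
  }
  structure(f, period = period, duty = duty, levels = c(systolic = p_hat_s, diastolic = lo))
}
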