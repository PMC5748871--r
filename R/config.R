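# YAML run configuration, output writers, and the end-to-end runner the
# command-line script wraps. All internal computation is SI; the config
# declares units explicitly (the source literature mixes mmHg, kPa and mm
# freely, so unit hygiene lives here and nowhere else).

.pressure_to_Pa <- function(x, units) {
  switch(units,
    Pa = x,
    kPa = x * 1000,
    mmHg = mmHg_to_Pa(x),
    stop("config: unknown pressure units '", units, "' (use Pa, kPa or mmHg)",
         call. = FALSE))
}

.length_to_m <- function(x, units) {
  switch(units,
    m = x,
    mm = x / 1000,
    stop("config: unknown length units '", units, "' (use m or mm)", call. = FALSE))
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration describing one simulation. Two modes:
#' `dimensionless` supplies the normalized groups directly (`groups:` block
#' with `material_ratio`, `p_hat_s`, `time_ratio`, optional `lam_z0`,
#' `duty`, `pressure_ratio`, `order`); `physical` supplies `geometry:`
#' (R, H, rho0, lam_z0, optional `units: m|mm`), `material:` (law-specific
#' constants with optional `units: Pa|kPa` for stress-like ones), and
#' `pulse:` (ps, pd, ts, tcp, n_cycles, optional `units: Pa|kPa|mmHg`),
#' from which the groups are derived. A `solver:` block overrides
#' [solver_settings()] fields. Missing waveform entries default to the
#' nominal 120/80 mmHg, 0.35 s / 1 s pulse.
#'
#' @param path Path to the YAML file.
#' @return A `run_config` list with elements `mode`, `law`, `groups`,
#'   `params`, `geometry`, `pulse`, `settings`, `n_cycles`, `tcp`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("load_run_config: no such file: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  for (key in c("mode", "law")) {
    if (is.null(cfg[[key]])) stop("config: missing required key '", key, "'", call. = FALSE)
  }
  mode <- match.arg(cfg$mode, c("dimensionless", "physical"))
  law <- match.arg(cfg$law, c("skalak", "hariton", "mooney_rivlin", "linear"))
  if (mode == "dimensionless" && !is.null(cfg$geometry)) {
    stop("config: dimensionless mode must not carry a 'geometry' block", call. = FALSE)
  }
  if (mode == "physical" && !is.null(cfg$groups)) {
    stop("config: physical mode must not carry a 'groups' block", call. = FALSE)
  }

  sv <- cfg$solver %||% list()
  settings <- solver_settings(
    method = sv$method %||% "lsodar",
    rtol = sv$rtol %||% 1e-11, atol = sv$atol %||% 1e-13,
    samples_per_cycle = sv$samples_per_cycle %||% 5000,
    stretch_cap = sv$stretch_cap %||% 20)

  if (mode == "dimensionless") {
    g <- cfg$groups
    if (is.null(g)) stop("config: dimensionless mode needs a 'groups' block", call. = FALSE)
    for (key in c("material_ratio", "p_hat_s", "time_ratio")) {
      if (is.null(g[[key]])) stop("config: missing groups key '", key, "'", call. = FALSE)
    }
    groups <- ring_groups(law, material_ratio = g$material_ratio, p_hat_s = g$p_hat_s,
                          lam_z0 = g$lam_z0 %||% 1, time_ratio = g$time_ratio,
                          duty = g$duty %||% 0.35,
                          pressure_ratio = g$pressure_ratio %||% (10.66 / 16),
                          order = g$order %||% 3L,
                          base_law = g$base_law %||% "skalak")
    out <- list(mode = mode, law = law, groups = groups, params = NULL,
                geometry = NULL, pulse = NULL, settings = settings,
                n_cycles = cfg$n_cycles %||% 1L, tcp = cfg$tcp %||% 1)
  } else {
    geo_cfg <- cfg$geometry
    if (is.null(geo_cfg)) stop("config: physical mode needs a 'geometry' block", call. = FALSE)
    lu <- geo_cfg$units %||% "m"
    geometry <- artery_geometry(R = .length_to_m(geo_cfg$R, lu),
                                H = .length_to_m(geo_cfg$H, lu),
                                rho0 = geo_cfg$rho0 %||% 1160,
                                lam_z0 = geo_cfg$lam_z0 %||% 1)
    pu_cfg <- cfg$pulse %||% list()
    pun <- pu_cfg$units %||% "Pa"
    pulse <- pressure_pulse(
      ps = .pressure_to_Pa(pu_cfg$ps %||% 16000, if (is.null(pu_cfg$ps)) "Pa" else pun),
      pd = .pressure_to_Pa(pu_cfg$pd %||% 10660, if (is.null(pu_cfg$pd)) "Pa" else pun),
      ts = pu_cfg$ts %||% 0.35, tcp = pu_cfg$tcp %||% 1,
      n_cycles = pu_cfg$n_cycles %||% 1L)
    m <- cfg$material
    if (is.null(m)) stop("config: physical mode needs a 'material' block", call. = FALSE)
    mu_units <- m$units %||% "Pa"
    params <- switch(law,
      skalak = skalak_params(B = m$B, C = m$C),  # already N/m
      hariton = hariton_params(a = .pressure_to_Pa(m$a, mu_units), b = m$b),
      mooney_rivlin = mooney_rivlin_params(mu = .pressure_to_Pa(m$mu, mu_units),
                                           beta = m$beta),
      stop("config: physical mode supports the three hyperelastic laws", call. = FALSE))
    groups <- dimensionless_groups(params, geometry, pulse, order = cfg$order %||% 3L)
    out <- list(mode = mode, law = law, groups = groups, params = params,
                geometry = geometry, pulse = pulse, settings = settings,
                n_cycles = pulse$n_cycles, tcp = pulse$tcp)
  }
  structure(out, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Dimensionless groups from physical inputs
#'
#' Normalizes a physical problem: p_hat_s = ps R / C (Skalak),
#' ps R / (a H) (Hariton) or ps R / (mu H) (Mooney-Rivlin); the cycle ratio
#' is tcp over the law's characteristic time; duty and pressure ratio come
#' from the waveform.
#'
#' @param params A material parameter record.
#' @param geometry An [artery_geometry()].
#' @param pulse A [pressure_pulse()].
#' @param order Skalak truncation order.
#' @return A [ring_groups()] with attribute `t_char` (seconds).
#' @export
dimensionless_groups <- function(params, geometry, pulse, order = 3L) {
  stopifnot(inherits(params, "ring_params"), inherits(geometry, "artery_geometry"),
            inherits(pulse, "pressure_pulse"))
  psR <- pulse$ps * geometry$R
  p_hat_s <- switch(params$law,
    skalak = psR / params$C,
    hariton = psR / (params$a * geometry$H),
    mooney_rivlin = psR / (params$mu * geometry$H))
  mr <- switch(params$law,
    skalak = params$B / params$C,
    hariton = params$b,
    mooney_rivlin = params$beta)
  t_char <- characteristic_time(params, geometry)
  gr <- ring_groups(params$law, material_ratio = mr, p_hat_s = p_hat_s,
                    lam_z0 = geometry$lam_z0, time_ratio = pulse$tcp / t_char,
                    duty = pulse$ts / pulse$tcp,
                    pressure_ratio = pulse$pd / pulse$ps, order = order)
  attr(gr, "t_char") <- t_char
  gr
}

#' Run a simulation described by a configuration file
#'
#' @param config A path to a YAML file or a `run_config` from
#'   [load_run_config()].
#' @return A list with `trace`, `summary`, and (physical mode) `report` in
#'   physical units.
#' @export
run_from_config <- function(config) {
  if (is.character(config)) config <- load_run_config(config)
  stopifnot(inherits(config, "run_config"))
  trace <- simulate_ring(config$groups, n_cycles = config$n_cycles,
                         settings = config$settings, tcp = config$tcp)
  summary <- summarise_response(trace)
  report <- if (!is.null(config$params) && config$law != "linear") {
    dimensionalise(summary, config$params, config$geometry)
  }
  list(trace = trace, summary = summary, report = report)
}

#' Write simulation outputs to disk
#'
#' Writes the trace as RFC-4180 CSV, the summary as JSON
#' (quantity -> peak / t_peak_s), and a plain-text provenance log (law,
#' groups, solver settings, package version).
#'
#' @param trace A `ring_trace`.
#' @param summary A `ring_summary`.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Invisibly, the three file paths.
#' @export
write_outputs <- function(trace, summary, dir, prefix = "run") {
  stopifnot(inherits(trace, "ring_trace"), inherits(summary, "ring_summary"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  trace_path <- file.path(dir, paste0(prefix, "_trace.csv"))
  summary_path <- file.path(dir, paste0(prefix, "_summary.json"))
  log_path <- file.path(dir, paste0(prefix, "_log.txt"))

  utils::write.csv(as.data.frame(trace), trace_path, row.names = FALSE)

  sm <- stats::setNames(
    lapply(seq_len(nrow(summary)), function(i)
      list(peak = summary$peak[i], t_peak_s = summary$t_peak[i])),
    summary$quantity)
  jsonlite::write_json(sm, summary_path, auto_unbox = TRUE, digits = NA)

  g <- attr(trace, "groups")
  st <- attr(trace, "settings")
  lines <- c(
    paste0("arteryring ", as.character(utils::packageVersion("arteryring"))),
    paste0("law: ", g$law, if (g$law == "skalak") paste0(" (order ", g$order, ")") else ""),
    sprintf("groups: material_ratio=%g p_hat_s=%g lam_z0=%g time_ratio=%g duty=%g pressure_ratio=%g",
            g$material_ratio, g$p_hat_s, g$lam_z0, g$time_ratio, g$duty, g$pressure_ratio),
    sprintf("solver: %s rtol=%g atol=%g samples_per_cycle=%d stretch_cap=%g",
            st$method, st$rtol, st$atol, st$samples_per_cycle, st$stretch_cap),
    sprintf("samples: %d; diverged: %s; collapsed: %s",
            nrow(trace), attr(trace, "diverged"), attr(trace, "collapsed")))
  writeLines(lines, log_path)
  invisible(c(trace = trace_path, summary = summary_path, log = log_path))
}
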