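# Response spectra: peak response vs. a swept problem parameter. Each grid
# point is an independent simulation from identical initial conditions, so
# rows are order-independent by construction.

#' Sweep ring simulations over a table of conditions
#'
#' Runs one simulation per row of `conditions`, a data frame whose columns
#' override fields of the `base` [ring_groups()] (any of `law`,
#' `material_ratio`, `p_hat_s`, `lam_z0`, `time_ratio`, `duty`,
#' `pressure_ratio`, `order`), and binds the per-quantity peak responses to
#' the conditions. This is the engine behind the response-spectrum figures
#' and the peak strain-energy tables.
#'
#' @param conditions A data frame of parameter overrides, one row per run.
#' @param base A [ring_groups()] supplying every field not present in
#'   `conditions`.
#' @param settings A [solver_settings()].
#' @param n_cycles Cardiac cycles per run.
#' @param tcp Cycle duration in seconds for reporting peak times.
#' @param linear_comparison If `TRUE`, adds `x_peak_linear`: the peak
#'   normalized displacement of the equivalent linear model (same initial
#'   tangent modulus, initial displacement lam_z0 - 1).
#' @return A `ring_sweep` tibble: the conditions plus columns
#'   `<quantity>_peak`, `<quantity>_t_peak` for the six response quantities,
#'   a `diverged` flag and an `error` message column (`NA` when the run
#'   succeeded; failures do not stop the sweep).
#' @examples
#' base <- ring_groups("skalak", 0, p_hat_s = 0.16, lam_z0 = 1, time_ratio = 2000)
#' sweep_response(data.frame(material_ratio = c(0, 0.5, 1)), base)
#' @export
sweep_response <- function(conditions, base, settings = solver_settings(),
                           n_cycles = 1L, tcp = 1, linear_comparison = FALSE) {
  stopifnot(is.data.frame(conditions), inherits(base, "ring_groups"))
  if (nrow(conditions) == 0) stop("sweep_response: empty conditions grid", call. = FALSE)
  allowed <- c("law", "material_ratio", "p_hat_s", "lam_z0", "time_ratio",
               "duty", "pressure_ratio", "order")
  bad <- setdiff(names(conditions), allowed)
  if (length(bad)) {
    stop("sweep_response: unknown condition column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }

  run_one <- function(row) {
    spec <- utils::modifyList(unclass(base), as.list(row))
    gr <- ring_groups(law = spec$law, material_ratio = spec$material_ratio,
                      p_hat_s = spec$p_hat_s, lam_z0 = spec$lam_z0,
                      time_ratio = spec$time_ratio, duty = spec$duty,
                      pressure_ratio = spec$pressure_ratio, order = spec$order,
                      base_law = spec$base_law)
    tr <- simulate_ring(gr, n_cycles = n_cycles, settings = settings, tcp = tcp)
    sm <- summarise_response(tr)
    out <- tibble::tibble(
      !!!stats::setNames(as.list(sm$peak), paste0(sm$quantity, "_peak")),
      !!!stats::setNames(as.list(sm$t_peak), paste0(sm$quantity, "_t_peak")),
      diverged = attr(sm, "diverged"), error = NA_character_
    )
    if (linear_comparison) {
      lgr <- ring_groups("linear", material_ratio = spec$material_ratio,
                         p_hat_s = spec$p_hat_s, lam_z0 = spec$lam_z0,
                         time_ratio = spec$time_ratio, duty = spec$duty,
                         pressure_ratio = spec$pressure_ratio,
                         base_law = spec$law)
      lsm <- summarise_response(
        simulate_ring(lgr, n_cycles = n_cycles, settings = settings, tcp = tcp))
      out$x_peak_linear <- lsm$peak[lsm$quantity == "x"]
    }
    out
  }

  rows <- purrr::map(seq_len(nrow(conditions)), function(i) {
    row <- conditions[i, , drop = FALSE]
    tryCatch(run_one(row), error = function(e) {
      tibble::tibble(diverged = NA, error = conditionMessage(e))
    })
  })
  res <- dplyr::bind_cols(tibble::as_tibble(conditions), dplyr::bind_rows(rows))
  class(res) <- c("ring_sweep", class(res))
  attr(res, "base") <- base
  attr(res, "varying") <- names(conditions)
  res
}

# Registry of the figure/table parameter sets. Each entry is a function so
# grids are built lazily; `time ratios` for the tables are the figure-caption
# values (the tables do not restate them), which the fixture records in
# `assumed`.
fixture_registry <- function() {
  lamz_grid <- seq(1, 1.3, by = 0.05)
  sk <- function(material_ratio = 0, p_hat_s = 0.16, lam_z0 = 1, time_ratio = 2000)
    ring_groups("skalak", material_ratio, p_hat_s, lam_z0, time_ratio)
  ha <- function(material_ratio = 16.7, p_hat_s = 3.2, lam_z0 = 1, time_ratio = 1 / 3e-4)
    ring_groups("hariton", material_ratio, p_hat_s, lam_z0, time_ratio)
  mr <- function(material_ratio = 0, p_hat_s = 0.64, lam_z0 = 1, time_ratio = 1000)
    ring_groups("mooney_rivlin", material_ratio, p_hat_s, lam_z0, time_ratio)
  list(
    fig4a = function() list(base = sk(), conditions = tibble::tibble(lam_z0 = lamz_grid),
      description = "Skalak displacement spectrum vs pre-stretch (B/C=0, psR/C=0.16, tcp/tSk=2000)"),
    fig4b = function() list(base = sk(), conditions = tibble::tibble(material_ratio = seq(0, 1, by = 0.1)),
      description = "Skalak displacement spectrum vs B/C (lam_z0=1, psR/C=0.16, tcp/tSk=2000)"),
    fig5a = function() list(base = sk(), conditions = tibble::tibble(p_hat_s = seq(0.16, 1.28, length.out = 8)),
      description = "Skalak displacement spectrum vs normalized systolic pressure"),
    fig5b = function() list(base = sk(), conditions = tibble::tibble(time_ratio = seq(1000, 10000, length.out = 10)),
      description = "Skalak displacement spectrum vs tcp/tSk"),
    fig6 = function() list(base = sk(),
      conditions = tidyr::expand_grid(material_ratio = seq(0, 1, by = 0.25),
                                      p_hat_s = c(0.16, 0.32, 0.48)),
      description = "Skalak response spectra vs B/C for three pressure levels"),
    fig7a = function() list(base = ha(), conditions = tibble::tibble(lam_z0 = lamz_grid),
      description = "Hariton displacement spectrum vs pre-stretch (b=16.7, psR/aH=3.2)"),
    fig7b = function() list(base = ha(lam_z0 = 1.25),
      conditions = tibble::tibble(material_ratio = seq(2, 26, length.out = 9)),
      description = "Hariton displacement spectrum vs b (lam_z0=1.25)"),
    fig8a = function() list(base = ha(lam_z0 = 1.25),
      conditions = tibble::tibble(p_hat_s = seq(0.5, 2.3, length.out = 7)),
      description = "Hariton displacement spectrum vs normalized systolic pressure"),
    fig8b = function() list(base = ha(lam_z0 = 1.25),
      conditions = tibble::tibble(time_ratio = seq(500, 5000, length.out = 10)),
      description = "Hariton displacement spectrum vs tcp/tH"),
    fig9 = function() list(base = ha(),
      conditions = tidyr::expand_grid(material_ratio = seq(5, 25, by = 5),
                                      p_hat_s = c(0.8, 2.4, 4)),
      description = "Hariton response spectra vs b for three pressure levels"),
    fig10a = function() list(base = mr(), conditions = tibble::tibble(lam_z0 = lamz_grid),
      description = "Mooney-Rivlin displacement spectrum vs pre-stretch (beta=0, psR/muH=0.64)"),
    fig10b = function() list(base = mr(lam_z0 = 1.1),
      conditions = tibble::tibble(material_ratio = seq(-0.5, 0.5, by = 0.1)),
      description = "Mooney-Rivlin displacement spectrum vs beta (lam_z0=1.1)"),
    fig11a = function() list(base = mr(),
      conditions = tibble::tibble(p_hat_s = seq(0.08, 0.8, by = 0.08)),
      description = "Mooney-Rivlin displacement spectrum vs normalized systolic pressure"),
    fig11b = function() list(base = mr(),
      conditions = tibble::tibble(time_ratio = seq(1000, 5000, length.out = 9)),
      description = "Mooney-Rivlin displacement spectrum vs tcp/tMR"),
    fig12 = function() list(base = mr(lam_z0 = 1.1),
      conditions = tidyr::expand_grid(material_ratio = seq(-0.5, 0.5, by = 0.25),
                                      p_hat_s = c(0.16, 0.32, 0.48)),
      description = "Mooney-Rivlin response spectra vs beta for three pressure levels"),
    table1 = function() list(base = sk(),
      conditions = tidyr::expand_grid(lam_z0 = lamz_grid, material_ratio = c(0, 0.5, 1)),
      description = "Peak W/C vs (lam_z0, B/C) at psR/C=0.16",
      assumed = "tcp/tSk = 2000 (figure-caption value; not restated by the table)"),
    table2 = function() list(base = ha(),
      conditions = tidyr::expand_grid(lam_z0 = lamz_grid, material_ratio = c(5, 15, 25)),
      description = "Peak W/a vs (lam_z0, b) at psR/aH=3.2",
      assumed = "tcp/tH = 1/3e-4 (figure-caption value)"),
    table3 = function() list(base = ha(material_ratio = 15),
      conditions = tidyr::expand_grid(lam_z0 = lamz_grid, p_hat_s = c(0.8, 2.4, 4)),
      description = "Peak W/a vs (lam_z0, psR/aH) at b=15",
      assumed = "tcp/tH = 1/3e-4 (figure-caption value)"),
    table4 = function() list(base = mr(p_hat_s = 0.32),
      conditions = tidyr::expand_grid(lam_z0 = lamz_grid, material_ratio = c(-0.5, 0, 0.5)),
      description = "Peak W/mu vs (lam_z0, beta) at psR/muH=0.32",
      assumed = "tcp/tMR = 1000 (figure-caption value)"),
    table5 = function() list(base = mr(p_hat_s = 0.32),
      conditions = tidyr::expand_grid(lam_z0 = lamz_grid, p_hat_s = c(0.16, 0.32, 0.48)),
      description = "Peak W/mu vs (lam_z0, psR/muH) at beta=0",
      assumed = "tcp/tMR = 1000 (figure-caption value)")
  )
}

#' Built-in sweep specifications for the response-spectrum figures and tables
#'
#' Returns the fully populated sweep specification (base dimensionless
#' groups plus conditions grid) for one of the documented figure/table
#' parameter sets: `fig4a`-`fig12` and `table1`-`table5`. Grid resolutions
#' inside figure ranges are 7-11 evenly spaced points; the peak-energy
#' tables do not restate their time-scale ratios, so the fixtures carry the
#' figure-caption values and record the assumption in `$assumed`.
#'
#' @param name Fixture name (see above).
#' @return A list with elements `base` (a [ring_groups()]), `conditions`
#'   (a tibble), `description`, and optionally `assumed`.
#' @examples
#' fx <- builtin_fixture("table1")
#' \donttest{sweep_response(fx$conditions, fx$base)}
#' @export
builtin_fixture <- function(name) {
  reg <- fixture_registry()
  if (!name %in% names(reg)) {
    stop("builtin_fixture: unknown fixture '", name, "'; available: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  }
  reg[[name]]()
}
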