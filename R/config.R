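#' Scenario presets
#'
#' Contractility metrics of the two mouse lines and the three knock-out
#' directionality cases:
#' * `WT`  - wild type: conduction speed 0.98 cm/s, 10 sites/cm,
#'   frequency 8.3 /min, period 7.23 s, all signals antegrade.
#' * `KO1` - Connexin-45 knock-out, all signals antegrade.
#' * `KO2` - knock-out, every other pacemaker retrograde (alternating).
#' * `KO3` - knock-out, all signals retrograde.
#'
#' The three KO cases share the knock-out metrics (0.063 cm/s, 11
#' sites/cm, 15.8 /min, 3.80 s) and differ only in signal directionality.
#'
#' @param name Preset name.
#' @return A list with the activation metrics and directionality pattern.
#' @examples
#' scenario_preset("WT")
#' @export
scenario_preset <- function(name = c("WT", "KO1", "KO2", "KO3")) {
  if (!is.character(name) || length(name) != 1 || !(name %in% c("WT", "KO1", "KO2", "KO3"))) {
    abort("unknown scenario; expected one of 'WT', 'KO1', 'KO2', 'KO3'",
      class = "lymphchain_invalid_parameter"
    )
  }
  ko <- list(
    sites_per_cm = 11, conduction_speed_cm_s = 0.063,
    frequency_per_min = 15.8, period_s = 3.80
  )
  act <- switch(name,
    WT = list(
      sites_per_cm = 10, conduction_speed_cm_s = 0.98,
      frequency_per_min = 8.3, period_s = 7.23, pattern = "antegrade"
    ),
    KO1 = c(ko, list(pattern = "antegrade")),
    KO2 = c(ko, list(pattern = "alternating")),
    KO3 = c(ko, list(pattern = "retrograde"))
  )
  c(list(name = name), act)
}

#' Full simulation configuration
#'
#' Assembles the complete, validated configuration for
#' [simulate_chain()]: geometry, boundary pressures, fluid, wall and valve
#' parameters, activation metrics and run control. Defaults reproduce the
#' reference setup (three 1 mm lymphangions, dz = 50 um, dt = 5 ms,
#' Pin = 3.5 / Pout = 4 cmH2O, D0 = 255 um) with the chosen scenario's
#' contractility metrics.
#'
#' @param scenario Preset name (`"WT"`, `"KO1"`, `"KO2"`, `"KO3"`) or
#'   `"passive"` for a run without contractions.
#' @param ... Named blocks (`chain`, `boundary`, `fluid`, `wall`, `valve`,
#'   `activation`, `run`) whose entries override the defaults, e.g.
#'   `run = list(max_cycles = 3)`.
#' @return An object of class `lymph_config` (nested named list).
#' @examples
#' cfg <- lymph_config("WT", run = list(max_cycles = 2, min_cycles = 1))
#' @export
lymph_config <- function(scenario = "WT", ...) {
  cfg <- default_config(scenario)
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(cfg))
  if (length(bad)) {
    abort(paste0("unknown configuration block(s): ", paste(bad, collapse = ", ")),
      class = "lymphchain_config_error"
    )
  }
  for (blk in names(overrides)) {
    bad_keys <- setdiff(names(overrides[[blk]]), names(cfg[[blk]]))
    if (length(bad_keys)) {
      abort(
        paste0("unknown key(s) in `", blk, "`: ", paste(bad_keys, collapse = ", ")),
        class = "lymphchain_config_error"
      )
    }
    cfg[[blk]] <- modifyList(cfg[[blk]], overrides[[blk]])
  }
  validate_config(cfg)
}

default_config <- function(scenario = "WT") {
  if (identical(scenario, "passive")) {
    act <- list(
      sites_per_cm = 10, conduction_speed_cm_s = 0.98,
      frequency_per_min = 60, period_s = 1, pattern = "none",
      rho_max = 0.99, n_images = 1L
    )
  } else {
    ps <- scenario_preset(scenario)
    act <- c(ps[-1], list(rho_max = 0.99, n_images = 1L))
  }
  structure(
    list(
      scenario = scenario,
      chain = list(n_lymphangions = 3L, lymphangion_length_cm = 0.1, dz_cm = 0.005),
      boundary = list(pin_cmh2o = 3.5, pout_cmh2o = 4),
      fluid = list(viscosity = 1e-5, density = 1070e-6, zeta = 2, delta_s = NULL),
      wall = list(
        d0_um = 255, anchor_pressure = 3.75, peak_fraction = 0.45,
        pre_floor_frac = 0.55, pre_ceiling_frac = 1.03, peak_floor_frac = 0.16,
        k_peak = NULL
      ),
      valve = list(rv_min = 600, rv_max = 3.5e5, s_o = 15, p_o = 0.01, s_f = 4, p_f = -6),
      activation = act,
      run = list(
        dt_ms = 5, min_cycles = 5L, max_cycles = 12L, steady_tol = 0.01,
        picard_tol = 1e-8, picard_max_iter = 300L, d_floor_frac = 0.05
      )
    ),
    class = "lymph_config"
  )
}

validate_config <- function(cfg) {
  pos <- function(x, nm) {
    if (!is.function(x) && (!is.numeric(x) || !is.finite(x) || x <= 0)) {
      abort(paste0("`", nm, "` must be positive"), class = "lymphchain_config_error")
    }
  }
  pos(cfg$run$dt_ms, "run$dt_ms")
  pos(cfg$chain$dz_cm, "chain$dz_cm")
  pos(cfg$chain$lymphangion_length_cm, "chain$lymphangion_length_cm")
  pos(cfg$fluid$viscosity, "fluid$viscosity")
  pos(cfg$fluid$density, "fluid$density")
  pos(cfg$wall$d0_um, "wall$d0_um")
  pos(cfg$valve$rv_min, "valve$rv_min")
  pos(cfg$valve$rv_max, "valve$rv_max")
  if (!identical(cfg$activation$pattern, "none")) {
    pos(cfg$activation$sites_per_cm, "activation$sites_per_cm")
    pos(cfg$activation$conduction_speed_cm_s, "activation$conduction_speed_cm_s")
    pos(cfg$activation$frequency_per_min, "activation$frequency_per_min")
  }
  if (cfg$run$min_cycles < 1 || cfg$run$max_cycles < cfg$run$min_cycles) {
    abort("require 1 <= min_cycles <= max_cycles", class = "lymphchain_config_error")
  }
  cfg
}

#' Read and write configurations
#'
#' `load_config()` reads a YAML (or JSON, a YAML subset) file, validates it
#' against the configuration schema (unknown keys are rejected with the
#' offending names) and fills unspecified entries with the defaults of the
#' file's `scenario` (WT if absent). An empty file yields the full WT
#' default. `save_config()` writes a configuration so the pair round-trips.
#'
#' @param path File path.
#' @param config A `lymph_config`.
#' @return `load_config()`: a validated `lymph_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path), class = "lymphchain_config_error")
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  scenario <- raw$scenario %||% "WT"
  raw$scenario <- NULL
  do.call(lymph_config, c(list(scenario = scenario), raw))
}

#' @rdname load_config
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "lymph_config"))
  out <- unclass(config)
  out <- rapply(out, function(x) x, how = "replace")
  yaml::write_yaml(drop_nulls(out), path)
  invisible(path)
}

drop_nulls <- function(x) {
  if (!is.list(x)) {
    return(x)
  }
  x <- x[!vapply(x, is.null, logical(1))]
  lapply(x, drop_nulls)
}

#' @export
print.lymph_config <- function(x, ...) {
  cat("<lymph_config> scenario:", x$scenario, "\n")
  cat(sprintf(
    "  chain: %d x %g cm (dz %g cm), Pin %g / Pout %g cmH2O, dt %g ms\n",
    x$chain$n_lymphangions, x$chain$lymphangion_length_cm, x$chain$dz_cm,
    if (is.function(x$boundary$pin_cmh2o)) NA else x$boundary$pin_cmh2o,
    if (is.function(x$boundary$pout_cmh2o)) NA else x$boundary$pout_cmh2o,
    x$run$dt_ms
  ))
  if (!identical(x$activation$pattern, "none")) {
    cat(sprintf(
      "  activation: %g sites/cm, %g cm/s, %g /min (period %g s), %s\n",
      x$activation$sites_per_cm, x$activation$conduction_speed_cm_s,
      x$activation$frequency_per_min,
      x$activation$period_s %||% (60 / x$activation$frequency_per_min),
      x$activation$pattern
    ))
  } else {
    cat("  activation: none (passive run)\n")
  }
  invisible(x)
}
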