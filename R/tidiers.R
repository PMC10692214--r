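#' Tidy an activation field
#'
#' @param x An `activation_field`.
#' @param ... Unused.
#' @return A tibble with columns `z` (cm), `t` (s) and `activation`.
#' @export
tidy.activation_field <- function(x, ...) {
  tibble(
    z = rep(x$z, times = length(x$t)),
    t = rep(x$t, each = length(x$z)),
    activation = as.numeric(x$values)
  )
}

#' Tidy a chain simulation
#'
#' @param x A `lymph_sim`.
#' @param what `"nodes"` for the per-node state history, `"valves"` for the
#'   per-valve history, `"cycles"` for per-cycle mean outflows.
#' @param ... Unused.
#' @return A tibble. For `"nodes"`: `time`, `node`, `z`, `lymphangion`,
#'   `pressure`, `flow`, `area`, `diameter`, `compliance`, `activation`
#'   (diameters in cm, flows in cm^3/s). For `"valves"`: `time`, `valve`,
#'   `resistance`, `flow`. For `"cycles"`: `cycle`, `mean_outflow_ulh`.
#' @export
tidy.lymph_sim <- function(x, what = c("nodes", "valves", "cycles"), ...) {
  what <- match.arg(what)
  g <- x$geometry
  if (what == "nodes") {
    ns <- ncol(x$P)
    qn <- node_flow_matrix(x)
    tibble(
      time = rep(x$time, each = g$n_nodes),
      node = rep(seq_len(g$n_nodes), times = ns),
      z = rep(g$node_z, times = ns),
      lymphangion = rep(g$node_seg, times = ns),
      pressure = as.numeric(x$P),
      flow = as.numeric(qn),
      area = as.numeric(pi / 4 * x$d^2),
      diameter = as.numeric(x$d),
      compliance = as.numeric(x$C),
      activation = as.numeric(x$t_act)
    )
  } else if (what == "valves") {
    ns <- ncol(x$Qv)
    tibble(
      time = rep(x$time, each = g$n_valves),
      valve = rep(seq_len(g$n_valves), times = ns),
      resistance = as.numeric(x$Rv),
      flow = as.numeric(x$Qv)
    )
  } else {
    tibble(
      cycle = seq_along(x$cycle_mean_outflow),
      mean_outflow_ulh = x$cycle_mean_outflow * CM3S_TO_UL_H
    )
  }
}

#' One-row summary of a chain simulation
#'
#' @param x A `lymph_sim`.
#' @param ... Unused.
#' @return A one-row tibble: scenario, cycle count, convergence flag, last
#'   cycle's mean outflow (uL/h) and the mass-conservation residual.
#' @export
glance.lymph_sim <- function(x, ...) {
  tibble(
    scenario = x$config$scenario %||% NA_character_,
    cycles = x$cycles_run,
    converged = x$converged,
    mean_outflow_ulh = tail(x$cycle_mean_outflow, 1) * CM3S_TO_UL_H,
    mass_residual = check_mass_conservation(x),
    picard_failures = x$picard_failures
  )
}

#' Tidy a metrics report
#'
#' @param x A `lymph_metrics`.
#' @param ... Unused.
#' @return A long tibble with columns `metric`, `value`, `unit`.
#' @export
tidy.lymph_metrics <- function(x, ...) {
  rows <- list(
    c("mean_flow", x$mean_flow_ulh, "uL/h"),
    c("peak_flow", x$peak_flow_ulh, "uL/h"),
    c("ef", x$ef, ""),
    c("fpf", x$fpf_per_min, "1/min"),
    c("area_reduction", x$area_reduction, ""),
    c("wss_mean", x$wss_mean, "dyn/cm^2"),
    c("wss_peak_systolic", x$wss_peak_systolic, "dyn/cm^2"),
    c("wss_peak_diastolic", x$wss_peak_diastolic, "dyn/cm^2"),
    c("wss_snr", x$wss_snr, ""),
    c("contraction_velocity_peak", x$contraction_velocity_peak_ums, "um/s"),
    c("velocity_peak_forward", x$velocity_peak_forward_mms, "mm/s"),
    c("velocity_peak_reverse", x$velocity_peak_reverse_mms, "mm/s"),
    c("activation_integration", as.numeric(x$activation_integration), ""),
    c("mass_residual", x$mass_residual, "")
  )
  mp <- x$mean_pressure_per_lymphangion
  for (i in seq_along(mp)) {
    rows[[length(rows) + 1]] <- c(paste0("mean_pressure_L", i), mp[i], "cmH2O")
  }
  el <- x$energy_loss
  for (i in seq_len(nrow(el))) {
    rows[[length(rows) + 1]] <- c(
      paste0("energy_loss_valve", el$valve[i]), el$loss_magnitude[i], "cmH2O"
    )
  }
  tibble(
    metric = vapply(rows, `[`, character(1), 1),
    value = as.numeric(vapply(rows, `[`, character(1), 2)),
    unit = vapply(rows, `[`, character(1), 3)
  )
}

#' One-row (wide) metrics summary
#'
#' @param x A `lymph_metrics`.
#' @param ... Unused.
#' @return A one-row tibble of the headline metrics.
#' @export
glance.lymph_metrics <- function(x, ...) {
  out <- tibble(
    scenario = x$scenario,
    mean_flow_ulh = x$mean_flow_ulh,
    peak_flow_ulh = x$peak_flow_ulh,
    ef = x$ef,
    fpf_per_min = x$fpf_per_min,
    area_reduction = x$area_reduction,
    wss_mean = x$wss_mean,
    wss_snr = x$wss_snr,
    contraction_velocity_peak_ums = x$contraction_velocity_peak_ums,
    velocity_peak_forward_mms = x$velocity_peak_forward_mms,
    activation_integration = as.numeric(x$activation_integration),
    mass_residual = x$mass_residual,
    converged = x$converged
  )
  out
}
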