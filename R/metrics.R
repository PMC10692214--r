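#' Ejection fraction from a lumen-area series
#'
#' `EF = (A_EDA - A_ESA) / A_EDA` with end-diastolic and end-systolic
#' areas taken as the maximum and minimum of the chain-averaged area over
#' one contraction cycle. A matrix input (nodes x steps) is averaged over
#' nodes first, optionally with control-volume weights.
#'
#' @param area Area series: vector (already chain-averaged) or nodes x
#'   steps matrix, cm^2 (> 0 at end-diastole).
#' @param weights Optional node weights for the chain average.
#' @return Ejection fraction in `[0, 1]`.
#' @examples
#' ejection_fraction(c(1, 0.5, 0.25, 0.6, 1))
#' @export
ejection_fraction <- function(area, weights = NULL) {
  if (is.matrix(area)) {
    if (is.null(weights)) weights <- rep(1, nrow(area))
    area <- as.numeric(crossprod(weights, area) / sum(weights))
  }
  a_eda <- max(area)
  a_esa <- min(area)
  if (!is.finite(a_eda) || a_eda <= 0) {
    abort("end-diastolic area must be positive", class = "lymphchain_invalid_parameter")
  }
  (a_eda - a_esa) / a_eda
}

#' Fractional pump function
#'
#' `FPF = frequency x EF`, a throughput index combining how often and how
#' completely the chain empties.
#'
#' @param ef Ejection fraction in `[0, 1]`.
#' @param frequency Contraction frequency, 1/min (> 0).
#' @return FPF, 1/min.
#' @export
fractional_pump_function <- function(ef, frequency) {
  if (any(ef < 0) || any(ef > 1)) {
    abort("`ef` must lie in [0, 1]", class = "lymphchain_invalid_parameter")
  }
  if (any(frequency <= 0)) {
    abort("`frequency` must be positive", class = "lymphchain_invalid_parameter")
  }
  frequency * ef
}

#' Wall shear stress from flow and diameter
#'
#' The wall traction of the power-law profile divided by the lumen
#' perimeter: `WSS = tau / (pi d) = -2 (zeta + 2) mu Q / (A d)`, converted
#' to dyn/cm^2. For `zeta = 2` this is the Hagen-Poiseuille wall shear
#' `32 mu Q / (pi d^3)` in magnitude. Sign convention: negative during
#' forward (antegrade) flow.
#'
#' @param Q Flow(s), cm^3/s.
#' @param d Lumen diameter(s), cm (> 0).
#' @param fluid A [fluid_params()] object.
#' @return WSS, dyn/cm^2.
#' @export
wall_shear_stress <- function(Q, d, fluid = fluid_params()) {
  if (any(d <= 0)) {
    abort("`d` must be positive", class = "lymphchain_invalid_parameter")
  }
  A <- pi / 4 * d^2
  (-2 * (fluid$zeta + 2) * fluid$mu * Q / (A * d)) * CMH2O_TO_DYN_CM2
}

#' Signal-to-noise ratio of a wall-shear-stress series
#'
#' Denoises the series with a trailing moving average of `window_size`
#' samples (truncated to the available samples at the start), then forms
#' the root-mean-square error between the series and its filtered version
#' (`MSE`), the root mean square of the raw series (`MSE0`), and
#' `SNR = log((MSE0 / MSE)^2)` (natural log). Scale-invariant; smooth
#' series give large SNR, noisy series small SNR.
#'
#' @param x Numeric series.
#' @param window_size Moving-average window length (>= 1 and <= length(x)).
#' @return SNR (dimensionless); `Inf` if the series equals its filtered
#'   version.
#' @examples
#' wss_snr(c(1, -1, 1, -1), 2) # log(4/3)
#' @export
wss_snr <- function(x, window_size = 5) {
  n <- length(x)
  if (window_size < 1 || window_size > n) {
    abort("require 1 <= window_size <= length(x)", class = "lymphchain_invalid_parameter")
  }
  xf <- moving_average_trailing(x, window_size)
  mse0 <- sqrt(mean(x^2))
  if (mse0 == 0) {
    abort("all-zero series: SNR undefined", class = "lymphchain_invalid_parameter")
  }
  mse <- sqrt(mean((x - xf)^2))
  if (mse == 0) {
    return(Inf)
  }
  log((mse0 / mse)^2)
}

moving_average_trailing <- function(x, w) {
  cs <- cumsum(x)
  n <- length(x)
  out <- numeric(n)
  i <- seq_len(n)
  lead <- pmin(i, w)
  out <- (cs - c(rep(0, min(w, n)), cs[seq_len(max(n - w, 0))])) / lead
  out
}

#' Radial contraction velocity
#'
#' Time derivative of the lumen radius `v = dr/dt` by central differences
#' (one-sided at the series ends), with `r = d/2`.
#'
#' @param d Diameter series, cm (uniformly sampled).
#' @param dt Sampling interval, s.
#' @return Velocity series, cm/s (same length as `d`).
#' @export
radial_velocity <- function(d, dt) {
  n <- length(d)
  if (n < 3) {
    abort("need at least 3 samples", class = "lymphchain_invalid_parameter")
  }
  r <- d / 2
  v <- numeric(n)
  v[2:(n - 1)] <- (r[3:n] - r[1:(n - 2)]) / (2 * dt)
  v[1] <- (r[2] - r[1]) / dt
  v[n] <- (r[n] - r[n - 1]) / dt
  v
}

#' Total-mechanical-energy loss across a valve
#'
#' `Phi = P + rho u^2 / 2` per unit volume; the loss is the difference of
#' `Phi` immediately upstream and downstream of the valve.
#'
#' @param p_up,p_down Pressures, cmH2O.
#' @param u_up,u_down Axial velocities, cm/s.
#' @param rho Lymph density, cmH2O s^2/cm^2.
#' @return `delta Phi = Phi_up - Phi_down`, cmH2O.
#' @export
valve_energy_loss <- function(p_up, u_up, p_down, u_down, rho = 1070e-6) {
  (p_up + 0.5 * rho * u_up^2) - (p_down + 0.5 * rho * u_down^2)
}

#' Activation integration
#'
#' A dimensionless index of the contractile input: the space-time mean of
#' the normalized activation field over one period, scaled by 1000
#' ("per-mille activation duty"). The integral is taken on the normalized
#' domain `(z / L, t / T)`, so the index does not depend on the grid
#' resolution; the convention is recorded in the `"convention"` attribute.
#'
#' @param field An `activation_field`, or a numeric matrix of `t_act`
#'   values.
#' @return AI (dimensionless).
#' @export
activation_integration <- function(field) {
  vals <- if (inherits(field, "activation_field")) field$values else field
  structure(mean(vals) * 1000,
    convention = "mean of t_act over the normalized (z/L, t/T) domain x 1000"
  )
}

#' Bottleneck trace of the flow field
#'
#' The "bottleneck" of a lymphangion at a time step is the node carrying
#' the largest flow magnitude. A stationary bottleneck indicates an
#' organised, wave-like propulsion; a wandering one indicates opposing
#' internal momentum. Ties are broken towards the upstream node.
#'
#' @param Q Node-flow matrix (nodes x steps).
#' @param segments Integer vector assigning each row of `Q` to a
#'   lymphangion.
#' @return A list with `trace` (tibble: `lymphangion`, `step`, `node` -
#'   node index within the lymphangion) and `stationarity` (tibble:
#'   `lymphangion`, `modal_node`, `score` = fraction of steps spent at the
#'   modal node).
#' @export
bottleneck_trace <- function(Q, segments) {
  stopifnot(nrow(Q) == length(segments))
  segs <- sort(unique(segments))
  traces <- lapply(segs, function(s) {
    rows <- which(segments == s)
    idx <- apply(abs(Q[rows, , drop = FALSE]), 2, which.max)
    tibble(lymphangion = s, step = seq_len(ncol(Q)), node = as.integer(idx))
  })
  trace <- dplyr::bind_rows(traces)
  stationarity <- trace |>
    dplyr::group_by(.data$lymphangion) |>
    dplyr::summarise(
      modal_node = as.integer(names(which.max(table(.data$node)))),
      score = max(table(.data$node)) / dplyr::n(),
      .groups = "drop"
    )
  list(trace = trace, stationarity = stationarity)
}

# node flows of a simulation history: mean of adjacent face/valve flows
node_flow_matrix <- function(sim) {
  g <- sim$geometry
  q_in <- matrix(0, g$n_nodes, ncol(sim$Qf))
  q_out <- q_in
  fi <- g$node_in_face > 0L
  fo <- g$node_out_face > 0L
  q_in[fi, ] <- sim$Qf[g$node_in_face[fi], , drop = FALSE]
  q_out[fo, ] <- sim$Qf[g$node_out_face[fo], , drop = FALSE]
  vi <- g$node_in_valve > 0L
  vo <- g$node_out_valve > 0L
  q_in[vi, ] <- sim$Qv[g$node_in_valve[vi], , drop = FALSE]
  q_out[vo, ] <- sim$Qv[g$node_out_valve[vo], , drop = FALSE]
  (q_in + q_out) / 2
}

#' Derived metrics of a chain simulation
#'
#' Computes the full report of pumping metrics over the last complete
#' contraction cycle of a simulation: cycle-averaged and peak flows,
#' ejection fraction and fractional pump function, lumen-area reduction,
#' wall shear stress statistics and signal-to-noise ratio, radial
#' contraction velocity, lymph velocity extrema, per-lymphangion mean
#' pressures, per-valve energy losses, activation integration and the
#' bottleneck stationarity scores.
#'
#' @param sim A `lymph_sim` from [simulate_chain()].
#' @param wss_window Moving-average window (samples) used in the WSS SNR.
#' @return An object of class `lymph_metrics`; use [tidy()] or [glance()]
#'   for tabular access.
#' @export
lymph_metrics <- function(sim, wss_window = 5) {
  g <- sim$geometry
  idx <- last_cycle_index(sim)
  w <- g$h
  freq <- sim$config$activation$frequency_per_min %||% (60 / sim$period)

  A <- pi / 4 * sim$d[, idx, drop = FALSE]^2
  area_series <- as.numeric(crossprod(w, A) / sum(w))
  ef <- ejection_fraction(area_series)
  area_reduction <- (max(area_series) - min(area_series)) / max(area_series)
  fpf <- fractional_pump_function(ef, freq)

  ef_per_lymphangion <- vapply(seq_len(g$n_lymphangions), function(s) {
    rows <- g$node_seg == s
    ejection_fraction(A[rows, , drop = FALSE], w[rows])
  }, numeric(1))

  qn <- node_flow_matrix(sim)[, idx, drop = FALSE]
  mean_flow <- mean(sim$Qv[g$n_valves, idx]) * CM3S_TO_UL_H
  peak_flow <- max(qn) * CM3S_TO_UL_H

  dmat <- sim$d[, idx, drop = FALSE]
  wss <- wall_shear_stress(qn, dmat, sim$fluid)
  wss_mean <- sum(crossprod(w, wss)) / (sum(w) * length(idx))
  mid_node <- (g$n_nodes + 1L) %/% 2L
  snr <- wss_snr(wss[mid_node, ], wss_window)

  u <- qn / (pi / 4 * dmat^2)
  rad_v <- t(apply(dmat, 1, radial_velocity, dt = sim$dt))

  mean_pressure <- vapply(seq_len(g$n_lymphangions), function(s) {
    rows <- g$node_seg == s
    sum(crossprod(w[rows], sim$P[rows, idx, drop = FALSE])) / (sum(w[rows]) * length(idx))
  }, numeric(1))

  # energy loss per valve: Phi = P + rho u^2/2 immediately up/downstream;
  # reservoir sides of the boundary valves are taken quiescent (u = 0)
  nv <- g$n_valves
  t_idx <- sim$time[idx]
  dphi <- matrix(NA_real_, nv, length(idx))
  for (v in seq_len(nv)) {
    un <- g$valve_up[v]
    dn <- g$valve_dn[v]
    qv <- sim$Qv[v, idx]
    if (un > 0L) {
      p_up <- sim$P[un, idx]
      u_up <- qv / (pi / 4 * dmat[un, ]^2)
    } else {
      p_up <- vapply(t_idx, sim$boundary$pin, numeric(1))
      u_up <- 0
    }
    if (dn > 0L) {
      p_dn <- sim$P[dn, idx]
      u_dn <- qv / (pi / 4 * dmat[dn, ]^2)
    } else {
      p_dn <- vapply(t_idx, sim$boundary$pout, numeric(1))
      u_dn <- 0
    }
    dphi[v, ] <- valve_energy_loss(p_up, u_up, p_dn, u_dn, sim$fluid$rho)
  }
  energy_loss <- tibble(
    valve = seq_len(nv),
    dphi_mean = rowMeans(dphi),
    dphi_mean_abs = rowMeans(abs(dphi)),
    loss_magnitude = abs(rowMeans(dphi))
  )

  ai <- if (!is.null(sim$field)) activation_integration(sim$field) else activation_integration(sim$t_act[, idx, drop = FALSE])

  bt <- bottleneck_trace(qn, g$node_seg)

  structure(
    list(
      scenario = sim$config$scenario %||% NA_character_,
      mean_flow_ulh = mean_flow,
      peak_flow_ulh = peak_flow,
      ef = ef,
      ef_per_lymphangion = ef_per_lymphangion,
      fpf_per_min = fpf,
      area_reduction = area_reduction,
      wss_mean = wss_mean,
      wss_peak_systolic = min(wss),
      wss_peak_diastolic = max(wss),
      wss_snr = snr,
      wss_snr_window = wss_window,
      contraction_velocity_peak_ums = max(abs(rad_v)) * 1e4,
      velocity_peak_forward_mms = max(u) * 10,
      velocity_peak_reverse_mms = min(u) * 10,
      mean_pressure_per_lymphangion = mean_pressure,
      energy_loss = energy_loss,
      activation_integration = ai,
      bottleneck = bt,
      mass_residual = check_mass_conservation(sim),
      frequency_per_min = freq,
      cycles_run = sim$cycles_run,
      converged = sim$converged
    ),
    class = "lymph_metrics"
  )
}

#' @export
print.lymph_metrics <- function(x, ...) {
  cat("<lymph_metrics>", if (!is.na(x$scenario)) paste0(" scenario: ", x$scenario), "\n", sep = "")
  cat(sprintf(
    "  mean flow: %.3g uL/h   peak flow: %.3g uL/h\n",
    x$mean_flow_ulh, x$peak_flow_ulh
  ))
  cat(sprintf(
    "  EF: %.3f   FPF: %.2f /min   area reduction: %.1f%%\n",
    x$ef, x$fpf_per_min, 100 * x$area_reduction
  ))
  cat(sprintf(
    "  WSS mean: %.3g dyn/cm^2 (peaks %.3g / %.3g)   SNR: %.3g\n",
    x$wss_mean, x$wss_peak_systolic, x$wss_peak_diastolic, x$wss_snr
  ))
  cat(sprintf(
    "  mean pressures: %s cmH2O\n",
    paste(sprintf("%.2f", x$mean_pressure_per_lymphangion), collapse = ", ")
  ))
  cat(sprintf(
    "  AI: %.3g   mass residual: %.2g\n",
    as.numeric(x$activation_integration), x$mass_residual
  ))
  invisible(x)
}
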