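#' Kymograph of an activation field
#'
#' Time-space map of the normalized activation, the standard way to
#' visualize contraction-wave propagation along a vessel.
#'
#' @param object An `activation_field`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.activation_field <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$z, fill = .data$activation)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "t_act") +
    ggplot2::labs(x = "time (s)", y = "axial position (cm)") +
    ggplot2::theme_minimal()
}

#' Plot a simulation result
#'
#' @param object A `lymph_sim`.
#' @param type One of `"activation"`, `"diameter"` (kymographs over the
#'   last cycle), `"pressure"`, `"flow"`, `"wss"` (traces at the middle
#'   node of each lymphangion), `"pd_loop"`, `"cd_loop"` (loops at the
#'   middle nodes), or `"valves"` (valve resistance traces).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lymph_sim <- function(object, type = c(
                                 "activation", "diameter", "pressure",
                                 "flow", "wss", "pd_loop", "cd_loop", "valves"
                               ), ...) {
  type <- match.arg(type)
  g <- object$geometry
  idx <- last_cycle_index(object)
  tt <- object$time[idx] - object$time[idx[1]]
  mid <- (g$nodes_per_segment + 1L) %/% 2L
  mids <- (seq_len(g$n_lymphangions) - 1L) * g$nodes_per_segment + mid

  if (type %in% c("activation", "diameter")) {
    vals <- if (type == "activation") object$t_act[, idx] else cm_to_um(object$d[, idx])
    df <- tibble(
      t = rep(tt, each = g$n_nodes),
      z = rep(g$node_z, times = length(idx)),
      value = as.numeric(vals)
    )
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$z, fill = .data$value)) +
        ggplot2::geom_raster() +
        ggplot2::scale_fill_viridis_c(name = if (type == "activation") "t_act" else "d (um)") +
        ggplot2::labs(x = "time in cycle (s)", y = "axial position (cm)") +
        ggplot2::theme_minimal()
    )
  }
  if (type == "valves") {
    df <- tibble(
      t = rep(tt, each = g$n_valves),
      valve = factor(rep(seq_len(g$n_valves), times = length(idx))),
      resistance = as.numeric(object$Rv[, idx])
    )
    return(
      ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$resistance, colour = .data$valve)) +
        ggplot2::geom_line() +
        ggplot2::scale_y_log10() +
        ggplot2::labs(x = "time in cycle (s)", y = "valve resistance (cmH2O s/cm^3)") +
        ggplot2::theme_minimal()
    )
  }

  qn <- node_flow_matrix(object)[, idx, drop = FALSE]
  per_mid <- function(values, name) {
    tibble(
      t = rep(tt, times = length(mids)),
      lymphangion = factor(rep(seq_along(mids), each = length(tt))),
      value = as.numeric(t(values[mids, , drop = FALSE]))
    )
  }
  df <- switch(type,
    pressure = per_mid(object$P[, idx], "pressure"),
    flow = per_mid(qn * CM3S_TO_UL_H, "flow"),
    wss = per_mid(wall_shear_stress(qn, object$d[, idx], object$fluid), "wss"),
    pd_loop = ,
    cd_loop = NULL
  )
  if (type %in% c("pressure", "flow", "wss")) {
    ylab <- switch(type,
      pressure = "pressure (cmH2O)",
      flow = "flow (uL/h)", wss = "WSS (dyn/cm^2)"
    )
    return(
      ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$value, colour = .data$lymphangion)) +
        ggplot2::geom_line() +
        ggplot2::labs(x = "time in cycle (s)", y = ylab) +
        ggplot2::theme_minimal()
    )
  }
  # loops at the middle nodes
  d_um <- cm_to_um(object$d[mids, idx, drop = FALSE])
  other <- if (type == "pd_loop") object$P[mids, idx, drop = FALSE] else object$C[mids, idx, drop = FALSE]
  df <- tibble(
    lymphangion = factor(rep(seq_along(mids), times = length(idx))),
    diameter = as.numeric(d_um),
    value = as.numeric(other)
  )
  ylab <- if (type == "pd_loop") "pressure (cmH2O)" else "compliance (cm^2/cmH2O)"
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$diameter, .data$value, colour = .data$lymphangion)) +
    ggplot2::geom_path() +
    ggplot2::labs(x = "diameter (um)", y = ylab) +
    ggplot2::theme_minimal()
  if (type == "pd_loop") {
    pg <- seq(0, 6, by = 0.05)
    ref <- dplyr::bind_rows(
      tibble(
        diameter = cm_to_um(diameter_at(object$curves$pre, pg)),
        value = pg, state = "pre-twitch"
      ),
      tibble(
        diameter = cm_to_um(diameter_at(object$curves$peak, pg)),
        value = pg, state = "peak-twitch"
      )
    )
    p <- p + ggplot2::geom_path(
      data = ref,
      ggplot2::aes(.data$diameter, .data$value, linetype = .data$state),
      colour = "grey30", inherit.aes = FALSE
    )
  }
  p
}

#' @export
autoplot.lymph_run <- function(object, ...) {
  autoplot(object$sim, ...)
}
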