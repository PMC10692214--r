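# Implicit finite-difference solver for the 1D lymphangion-chain equations.
#
# Unknowns per time step: nodal pressures P (one per node) and face flows Q
# (staggered between nodes), plus the four lumped valve flows. Backward
# Euler in time, central differences in space. The wall is explicit: area
# and compliance are evaluated at the previous step's pressure and the new
# step's activation, then the area is advanced by the linearization
# A^{n+1} = A_act + C (P^{n+1} - P^n), which makes the discrete mass
# balance telescope exactly over a cycle. Eliminating Q from the momentum
# equation leaves a tridiagonal pressure system solved by the Thomas
# algorithm; valve resistances and the (small) convective term are lagged
# and Picard-iterated to tolerance.

thomas_solve <- function(lower, diag, upper, rhs) {
  n <- length(diag)
  cp <- numeric(n)
  dp <- numeric(n)
  cp[1] <- upper[1] / diag[1]
  dp[1] <- rhs[1] / diag[1]
  for (i in 2:n) {
    m <- diag[i] - lower[i - 1] * cp[i - 1]
    if (i < n) cp[i] <- upper[i] / m
    dp[i] <- (rhs[i] - lower[i - 1] * dp[i - 1]) / m
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

#' Simulate a lymphangion chain to periodic steady state
#'
#' Runs the coupled 1D fluid-wall-valve model. The simulation advances in
#' contraction cycles and stops once the cycle-averaged outflow changes by
#' less than `steady_tol` (relative) between successive cycles, after at
#' least `min_cycles` cycles, or at `max_cycles`.
#'
#' @param config A `lymph_config` (see [lymph_config()]) or a scenario name
#'   (`"WT"`, `"KO1"`, `"KO2"`, `"KO3"`).
#' @param quiet Suppress per-cycle progress messages.
#' @return An object of class `lymph_sim` holding the full state history
#'   (`P`, `d`, `A`, `C` per node and step; face flows `Qf`; per-valve
#'   flows `Qv` and resistances `Rv`), the grids, the activation field,
#'   the configuration and convergence metadata. Use [tidy()] to get the
#'   history as a tibble and [lymph_metrics()] for the derived quantities.
#' @examples
#' \donttest{
#' sim <- simulate_chain(lymph_config("WT", run = list(max_cycles = 2, min_cycles = 1)))
#' glance(sim)
#' }
#' @export
simulate_chain <- function(config, quiet = TRUE) {
  if (is.character(config)) config <- lymph_config(config)
  stopifnot(inherits(config, "lymph_config"))
  geom <- chain_geometry(
    config$chain$n_lymphangions, config$chain$lymphangion_length_cm,
    config$chain$dz_cm
  )
  fluid <- fluid_params(
    config$fluid$viscosity, config$fluid$density, config$fluid$zeta,
    config$fluid$delta_s %||% (1 / (config$fluid$zeta + 1))
  )
  curves <- calibrate_default_curves(
    d0_um = config$wall$d0_um, anchor_pressure = config$wall$anchor_pressure,
    peak_fraction = config$wall$peak_fraction,
    pre_floor_frac = config$wall$pre_floor_frac,
    pre_ceiling_frac = config$wall$pre_ceiling_frac,
    peak_floor_frac = config$wall$peak_floor_frac,
    k_peak = config$wall$k_peak
  )
  vp <- valve_params(
    config$valve$rv_min, config$valve$rv_max, config$valve$s_o,
    config$valve$p_o, config$valve$s_f, config$valve$p_f
  )
  dt <- config$run$dt_ms / 1000
  act <- config$activation
  period <- act$period_s %||% (60 / act$frequency_per_min)
  n_per <- period / dt
  if (abs(n_per - round(n_per)) > 1e-6) {
    abort("`dt` must divide the contraction period exactly",
      class = "lymphchain_invalid_parameter"
    )
  }
  n_per <- as.integer(round(n_per))

  # activation field on the solver grid (zero field for passive runs)
  if (identical(act$pattern, "none")) {
    field <- NULL
    ta_mat <- matrix(0, geom$n_nodes, n_per)
  } else {
    ap <- activation_params(
      act$sites_per_cm, act$conduction_speed_cm_s, act$frequency_per_min,
      period, act$rho_max %||% 0.99
    )
    sites <- place_pacemakers(geom$chain_length, act$sites_per_cm, act$pattern, period)
    field <- build_activation_field(
      sites, ap, geom$node_z, dt * (0:(n_per - 1)),
      n_images = act$n_images %||% 1L
    )
    ta_mat <- field$values
  }

  pin <- config$boundary$pin_cmh2o
  pout <- config$boundary$pout_cmh2o
  pin_fun <- if (is.function(pin)) pin else function(t) pin
  pout_fun <- if (is.function(pout)) pout else function(t) pout

  min_cycles <- config$run$min_cycles
  max_cycles <- config$run$max_cycles
  steady_tol <- config$run$steady_tol
  tol <- config$run$picard_tol
  max_iter <- config$run$picard_max_iter
  d_floor <- (config$run$d_floor_frac %||% 0.05) * um_to_cm(config$wall$d0_um)
  a_floor <- pi / 4 * d_floor^2

  np <- geom$n_nodes
  nf <- geom$n_faces
  nv <- geom$n_valves
  fup <- geom$face_up
  fdn <- geom$face_dn
  vup <- geom$valve_up
  vdn <- geom$valve_dn
  h <- geom$h
  dz <- geom$dz
  kmu <- 2 * (fluid$zeta + 2) * fluid$mu * pi
  one_ds <- 1 + fluid$delta_s

  n_steps <- max_cycles * n_per
  P_hist <- matrix(NA_real_, np, n_steps + 1L)
  d_hist <- matrix(NA_real_, np, n_steps + 1L)
  C_hist <- matrix(NA_real_, np, n_steps + 1L)
  Qf_hist <- matrix(NA_real_, nf, n_steps + 1L)
  Qv_hist <- matrix(NA_real_, nv, n_steps + 1L)
  Rv_hist <- matrix(NA_real_, nv, n_steps + 1L)
  ta_hist <- matrix(NA_real_, np, n_steps + 1L)

  # initial state: uniform pressure at the mean boundary head, zero flow
  p0 <- (pin_fun(0) + pout_fun(0)) / 2
  P <- rep(p0, np)
  ta0 <- ta_mat[, n_per] # activation at t = 0 equals the periodic slice
  d0 <- pmax(diameter_update(P, ta0, curves), d_floor)
  A_state <- pi / 4 * d0^2
  C0 <- compliance_update(P, ta0, curves)
  Qf <- numeric(nf)
  Qv <- numeric(nv)
  dp0 <- c(pin_fun(0) - P[1], if (nv > 2) P[vup[2:(nv - 1)]] - P[vdn[2:(nv - 1)]], P[np] - pout_fun(0))
  Rv <- valve_resistance(dp0, vp)

  P_hist[, 1] <- P
  d_hist[, 1] <- d0
  C_hist[, 1] <- C0
  Qf_hist[, 1] <- Qf
  Qv_hist[, 1] <- Qv
  Rv_hist[, 1] <- Rv
  ta_hist[, 1] <- ta0

  mid_valves <- which(vup > 0L & vdn > 0L)

  # node flow = mean of the flows entering and leaving its control volume
  node_flow <- function(Qf, Qv) {
    q_in <- numeric(np)
    q_out <- numeric(np)
    hasf_in <- geom$node_in_face > 0L
    hasf_out <- geom$node_out_face > 0L
    q_in[hasf_in] <- Qf[geom$node_in_face[hasf_in]]
    q_out[hasf_out] <- Qf[geom$node_out_face[hasf_out]]
    hasv_in <- geom$node_in_valve > 0L
    hasv_out <- geom$node_out_valve > 0L
    q_in[hasv_in] <- Qv[geom$node_in_valve[hasv_in]]
    q_out[hasv_out] <- Qv[geom$node_out_valve[hasv_out]]
    (q_in + q_out) / 2
  }

  cycle_means <- numeric(0)
  converged <- FALSE
  max_picard_used <- 0L
  picard_failures <- 0L
  collapse_warned <- FALSE
  steps_run <- 0L

  for (cyc in seq_len(max_cycles)) {
    for (i_in_cyc in seq_len(n_per)) {
      step <- (cyc - 1L) * n_per + i_in_cyc
      t_new <- step * dt
      ta <- ta_mat[, i_in_cyc]
      pin_t <- pin_fun(t_new)
      pout_t <- pout_fun(t_new)

      d_act <- diameter_update(P, ta, curves)
      if (any(d_act < d_floor)) {
        d_act <- pmax(d_act, d_floor)
        if (!collapse_warned) {
          warn("lumen diameter clamped at floor (5% of D0)")
          collapse_warned <- TRUE
        }
      }
      A_act <- pi / 4 * d_act^2
      Cc <- pmax(compliance_update(P, ta, curves), 1e-14)
      A_face <- (A_act[fup] + A_act[fdn]) / 2
      alpha <- fluid$rho / (A_face * dt) + kmu / A_face^2
      beta <- 1 / (alpha * dz)
      qcoef <- fluid$rho * Qf / (A_face * dt)

      diag_base <- h * Cc / dt
      rhs_base <- h * Cc * P / dt - h * (A_act - A_state) / dt

      P_it <- P
      Qf_it <- Qf
      Qv_it <- Qv
      Rv_it <- Rv
      ok <- FALSE
      for (iter in seq_len(max_iter)) {
        omega <- if (iter > 60) 0.25 else if (iter > 15) 0.5 else 1
        dpv <- c(pin_t - P_it[1], P_it[vup[mid_valves]] - P_it[vdn[mid_valves]], P_it[np] - pout_t)
        Rv_calc <- valve_resistance(dpv, vp)
        Rv_new <- exp(omega * log(Rv_calc) + (1 - omega) * log(Rv_it))
        gv <- 1 / Rv_new

        qn <- node_flow(Qf_it, Qv_it)
        G <- qn^2 / A_act
        conv <- one_ds * fluid$rho / A_face * (G[fdn] - G[fup]) / dz
        gam <- (qcoef - conv) / alpha

        dg <- diag_base
        lo <- numeric(np - 1L)
        up <- numeric(np - 1L)
        rhs <- rhs_base
        # faces: out of fup, into fdn
        dg[fup] <- dg[fup] + beta
        dg[fdn] <- dg[fdn] + beta
        up[fup] <- up[fup] - beta # coef of P[fup+1] in row fup
        lo[fdn - 1L] <- lo[fdn - 1L] - beta # coef of P[fdn-1] in row fdn
        rhs[fup] <- rhs[fup] - gam
        rhs[fdn] <- rhs[fdn] + gam
        # inlet valve
        dg[1] <- dg[1] + gv[1]
        rhs[1] <- rhs[1] + gv[1] * pin_t
        # interior valves (connect consecutive global nodes)
        for (v in mid_valves) {
          u <- vup[v]
          dn <- vdn[v]
          dg[u] <- dg[u] + gv[v]
          up[u] <- up[u] - gv[v]
          dg[dn] <- dg[dn] + gv[v]
          lo[dn - 1L] <- lo[dn - 1L] - gv[v]
        }
        # outlet valve
        dg[np] <- dg[np] + gv[nv]
        rhs[np] <- rhs[np] + gv[nv] * pout_t

        P_new <- thomas_solve(lo, dg, up, rhs)
        Qf_new <- gam - beta * (P_new[fdn] - P_new[fup])
        Qv_new <- gv * c(
          pin_t - P_new[1], P_new[vup[mid_valves]] - P_new[vdn[mid_valves]],
          P_new[np] - pout_t
        )

        p_scale <- max(1, max(abs(P_new)))
        q_scale <- max(max(abs(Qf_new), abs(Qv_new)), 1e-10)
        dP <- max(abs(P_new - P_it)) / p_scale
        dQ <- max(max(abs(Qf_new - Qf_it), 0), if (nv > 0) max(abs(Qv_new - Qv_it)) else 0) / q_scale
        dR <- max(abs(Rv_new - Rv_it) / Rv_it)
        P_it <- P_new
        Qf_it <- Qf_new
        Qv_it <- Qv_new
        Rv_it <- Rv_new
        if (dP < tol && dQ < tol && dR < 1e-6) {
          ok <- TRUE
          break
        }
      }
      if (!ok) picard_failures <- picard_failures + 1L
      max_picard_used <- max(max_picard_used, iter)

      A_state <- pmax(A_act + Cc * (P_it - P), a_floor)
      P <- P_it
      Qf <- Qf_it
      Qv <- Qv_it
      Rv <- Rv_it

      P_hist[, step + 1L] <- P
      d_hist[, step + 1L] <- sqrt(4 * A_state / pi)
      C_hist[, step + 1L] <- Cc
      Qf_hist[, step + 1L] <- Qf
      Qv_hist[, step + 1L] <- Qv
      Rv_hist[, step + 1L] <- Rv
      ta_hist[, step + 1L] <- ta
      steps_run <- step
    }
    idx <- ((cyc - 1L) * n_per + 2L):(cyc * n_per + 1L)
    cycle_means[cyc] <- mean(Qv_hist[nv, idx])
    if (!quiet) {
      message(sprintf(
        "cycle %d: mean outflow %.4g uL/h", cyc, cycle_means[cyc] * CM3S_TO_UL_H
      ))
    }
    if (cyc >= min_cycles && cyc >= 2) {
      delta <- abs(cycle_means[cyc] - cycle_means[cyc - 1])
      if (delta < max(steady_tol * abs(cycle_means[cyc]), 1e-9)) {
        converged <- TRUE
        break
      }
    }
  }

  keep <- seq_len(steps_run + 1L)
  structure(
    list(
      P = P_hist[, keep, drop = FALSE],
      d = d_hist[, keep, drop = FALSE],
      C = C_hist[, keep, drop = FALSE],
      Qf = Qf_hist[, keep, drop = FALSE],
      Qv = Qv_hist[, keep, drop = FALSE],
      Rv = Rv_hist[, keep, drop = FALSE],
      t_act = ta_hist[, keep, drop = FALSE],
      time = dt * (keep - 1L),
      geometry = geom, fluid = fluid, curves = curves, valve = vp,
      field = field, config = config,
      dt = dt, period = period, steps_per_cycle = n_per,
      cycles_run = length(cycle_means), cycle_mean_outflow = cycle_means,
      converged = converged, picard_failures = picard_failures,
      max_picard_iterations = max_picard_used,
      boundary = list(pin = pin_fun, pout = pout_fun)
    ),
    class = "lymph_sim"
  )
}

#' @export
print.lymph_sim <- function(x, ...) {
  cat("<lymph_sim>\n")
  cat(sprintf(
    "  %d lymphangions, %d nodes, dt = %g ms, period = %g s\n",
    x$geometry$n_lymphangions, x$geometry$n_nodes, x$dt * 1000, x$period
  ))
  cat(sprintf(
    "  %d cycle(s) run, periodic steady state: %s\n",
    x$cycles_run, if (x$converged) "reached" else "not reached"
  ))
  cat(sprintf(
    "  last-cycle mean outflow: %.4g uL/h\n",
    tail(x$cycle_mean_outflow, 1) * CM3S_TO_UL_H
  ))
  invisible(x)
}

# Column indices of the last complete cycle (excluding the shared endpoint
# convention: uses the n_per steps ending at the final stored column).
last_cycle_index <- function(sim) {
  n <- ncol(sim$P)
  n_per <- sim$steps_per_cycle
  if (n - 1L < n_per) {
    abort("simulation holds less than one complete cycle",
      class = "lymphchain_invalid_parameter"
    )
  }
  (n - n_per + 1L):n
}

#' Cycle-averaged mass-conservation residual
#'
#' Verifies the solver by comparing the cycle-averaged flow at every valve
#' plane with the flow entering the first lymphangion: at periodic steady
#' state they must coincide, because the lumen volume returns to its
#' starting value each cycle.
#'
#' @param sim A `lymph_sim`.
#' @return Maximum relative residual
#'   `max_v |<Q_v> - <Q_1>| / |<Q_1>|` over the last complete cycle. If the
#'   mean inflow is (numerically) zero the absolute residual is returned
#'   with a warning.
#' @export
check_mass_conservation <- function(sim) {
  idx <- last_cycle_index(sim)
  means <- rowMeans(sim$Qv[, idx, drop = FALSE])
  ref <- means[1]
  if (abs(ref) < 1e-12) {
    warn("mean inflow is zero; returning absolute residual (cm^3/s)")
    return(max(abs(means - ref)))
  }
  max(abs(means - ref) / abs(ref))
}
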