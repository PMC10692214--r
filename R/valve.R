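#' Secondary-valve parameters
#'
#' Parameters of the sigmoidal resistance law of a bileaflet lymphatic
#' valve. The valve is a lumped resistance whose value switches smoothly
#' between `rv_min` (open, favourable trans-valvular pressure difference)
#' and `rv_min + rv_max` (closed) around the opening threshold `p_o`; at
#' very large adverse differences (below the failure threshold `p_f`) the
#' leaflets prolapse and the resistance drops back towards `rv_min`. With
#' the default `p_f` far outside the physiological operating range the
#' failure branch never engages.
#'
#' The numeric defaults are calibrated stand-ins in the lineage of lumped
#' valve models for rat mesenteric lymphangions; every value can be
#' overridden through the configuration.
#'
#' @param rv_min Open-valve resistance, cmH2O s/cm^3 (> 0).
#' @param rv_max Resistance increment when closed, cmH2O s/cm^3 (> 0).
#' @param s_o Opening slope, 1/cmH2O (> 0).
#' @param p_o Opening threshold, cmH2O.
#' @param s_f Failure slope, 1/cmH2O (> 0).
#' @param p_f Failure threshold, cmH2O (`p_f < p_o`).
#' @return An object of class `valve_params`.
#' @export
valve_params <- function(rv_min = 600, rv_max = 3.5e5, s_o = 15, p_o = 0.01,
                         s_f = 4, p_f = -6) {
  if (!is.finite(rv_min) || !is.finite(rv_max) || rv_min <= 0 || rv_max <= 0) {
    abort("`rv_min` and `rv_max` must be positive", class = "lymphchain_invalid_parameter")
  }
  if (!is.finite(s_o) || !is.finite(s_f) || s_o <= 0 || s_f <= 0) {
    abort("`s_o` and `s_f` must be positive", class = "lymphchain_invalid_parameter")
  }
  if (!(p_f < p_o)) {
    abort("`p_f` must be below `p_o` (failure at large adverse pressure)",
      class = "lymphchain_invalid_parameter"
    )
  }
  structure(
    list(rv_min = rv_min, rv_max = rv_max, s_o = s_o, p_o = p_o, s_f = s_f, p_f = p_f),
    class = "valve_params"
  )
}

#' Sigmoidal valve resistance
#'
#' Resistance of a secondary valve as a function of the trans-valvular
#' pressure difference `delta_p = P_upstream - P_downstream`:
#'
#' `Rv = rv_min + rv_max * (1/(1 + exp(s_o (delta_p - p_o))) +
#'                          1/(1 + exp(-s_f (delta_p - p_f))) - 1)`
#'
#' The sign of the opening slope is calibrated so that a favourable
#' (positive) difference opens the valve: `Rv -> rv_min` as
#' `delta_p -> +Inf`, `Rv = rv_min + rv_max` on the closed plateau
#' `p_f < delta_p < p_o`, and `Rv -> rv_min` again below the failure
#' threshold (leaflet prolapse).
#'
#' @param delta_p Trans-valvular pressure difference(s), cmH2O
#'   (upstream minus downstream).
#' @param params A [valve_params()] object.
#' @return Resistance(s), cmH2O s/cm^3; always `>= rv_min`.
#' @examples
#' vp <- valve_params()
#' valve_resistance(c(1, -1), vp) # open vs closed
#' @export
valve_resistance <- function(delta_p, params) {
  sig_open <- 1 / (1 + exp(pmin(params$s_o * (delta_p - params$p_o), 700)))
  sig_fail <- 1 / (1 + exp(pmax(-params$s_f * (delta_p - params$p_f), -700)))
  params$rv_min + params$rv_max * (sig_open + sig_fail - 1)
}

#' Flow through a valve
#'
#' Lumped resistive junction: `Q = delta_p / Rv(delta_p)` with
#' `delta_p = p_up - p_down`. Continuous in `delta_p`; strongly rectifying
#' because `Rv` is orders of magnitude larger when the valve is closed.
#'
#' @param p_up,p_down Pressures immediately upstream/downstream, cmH2O.
#' @inheritParams valve_resistance
#' @return Flow(s), cm^3/s (positive towards downstream).
#' @export
valve_flow <- function(p_up, p_down, params) {
  dp <- p_up - p_down
  dp / valve_resistance(dp, params)
}

#' @export
print.valve_params <- function(x, ...) {
  cat("<valve_params>\n")
  cat(sprintf(
    "  rv_min: %.3g  rv_max: %.3g cmH2O s/cm^3\n", x$rv_min, x$rv_max
  ))
  cat(sprintf(
    "  opening: s_o = %.3g /cmH2O at p_o = %.3g cmH2O\n", x$s_o, x$p_o
  ))
  cat(sprintf(
    "  failure: s_f = %.3g /cmH2O at p_f = %.3g cmH2O\n", x$s_f, x$p_f
  ))
  invisible(x)
}
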