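#' Saturating-exponential pressure-diameter curve
#'
#' One mechanical state of the lymphatic wall (pre-twitch = fully relaxed,
#' or peak-twitch = maximally contracted) is represented by a monotone,
#' strain-stiffening pressure-diameter map
#' `d(P) = d_max - (d_max - d_min) * exp(-k * P)`,
#' the concave saturating family typical of mesenteric lymphatic inflation
#' data. Diameters enter in micrometres and are stored internally in cm.
#'
#' @param d_min_um Diameter at zero pressure, um.
#' @param d_max_um Saturation diameter at high pressure, um
#'   (`>= d_min_um`; equality gives a rigid tube).
#' @param k Stiffening rate, 1/cmH2O (> 0).
#' @return An object of class `constitutive_curve`.
#' @examples
#' cv <- constitutive_curve(140, 263, 0.74)
#' diameter_at(cv, 3.75) # cm
#' @export
constitutive_curve <- function(d_min_um, d_max_um, k) {
  if (!is.finite(d_min_um) || !is.finite(d_max_um) || !is.finite(k) ||
    d_min_um <= 0 || d_max_um < d_min_um || k <= 0) {
    abort("require 0 < d_min_um <= d_max_um and k > 0",
      class = "lymphchain_invalid_parameter"
    )
  }
  structure(
    list(d_min = um_to_cm(d_min_um), d_max = um_to_cm(d_max_um), k = k),
    class = "constitutive_curve"
  )
}

#' Diameter and slope of a constitutive curve
#'
#' @param curve A [constitutive_curve()].
#' @param P Pressure(s), cmH2O.
#' @return `diameter_at()`: diameter in cm; `slope_at()`: dd/dP in
#'   cm/cmH2O (non-negative, vanishing at high pressure).
#' @export
diameter_at <- function(curve, P) {
  curve$d_max - (curve$d_max - curve$d_min) * exp(-curve$k * P)
}

#' @rdname diameter_at
#' @export
slope_at <- function(curve, P) {
  (curve$d_max - curve$d_min) * curve$k * exp(-curve$k * P)
}

#' Pair of pre- and peak-twitch constitutive curves
#'
#' @param pre,peak [constitutive_curve()] objects for the relaxed and the
#'   peak contractile state. The pre-twitch diameter must dominate the
#'   peak-twitch diameter over the operating range 0-10 cmH2O.
#' @return An object of class `constitutive_set`.
#' @export
constitutive_set <- function(pre, peak) {
  stopifnot(inherits(pre, "constitutive_curve"), inherits(peak, "constitutive_curve"))
  pgrid <- seq(0, 10, by = 0.1)
  if (any(diameter_at(pre, pgrid) < diameter_at(peak, pgrid))) {
    abort("pre-twitch diameter must be >= peak-twitch diameter on 0-10 cmH2O",
      class = "lymphchain_invalid_parameter"
    )
  }
  structure(list(pre = pre, peak = peak), class = "constitutive_set")
}

#' Default constitutive curve set anchored at a resting diameter
#'
#' Builds a pre/peak curve pair whose pre-twitch diameter equals `d0_um` at
#' the mean operating pressure (default 3.75 cmH2O, the average of the
#' 3.5/4 cmH2O boundary pressures) and whose peak-twitch plateau is
#' `peak_fraction * d0_um`. The numeric coefficients are calibrated
#' stand-ins for rat mesenteric inflation data; every anchor is exposed so
#' users with their own pressure-diameter measurements can override them
#' (see [curves_from_table()]).
#'
#' @param d0_um Resting (pre-twitch) diameter at `anchor_pressure`, um.
#' @param anchor_pressure Pressure at which the pre-twitch curve passes
#'   through `d0_um`, cmH2O.
#' @param peak_fraction Peak-twitch saturation diameter as a fraction of
#'   `d0_um` (default 0.45, giving a roughly 50% systolic caliber
#'   reduction at full activation).
#' @param pre_floor_frac,pre_ceiling_frac Pre-twitch diameter at P = 0 and
#'   at saturation, as fractions of `d0_um` (`pre_ceiling_frac > 1`).
#' @param peak_floor_frac Peak-twitch diameter at P = 0 as a fraction of
#'   `d0_um`.
#' @param k_peak Optional stiffening rate of the peak curve; defaults to
#'   the pre-twitch rate.
#' @return A [constitutive_set()].
#' @examples
#' cs <- calibrate_default_curves()
#' cm_to_um(diameter_at(cs$pre, 3.75)) # 255
#' @export
calibrate_default_curves <- function(d0_um = 255, anchor_pressure = 3.75,
                                     peak_fraction = 0.45,
                                     pre_floor_frac = 0.55,
                                     pre_ceiling_frac = 1.03,
                                     peak_floor_frac = 0.16,
                                     k_peak = NULL) {
  if (!is.finite(d0_um) || d0_um <= 0) {
    abort("`d0_um` must be positive", class = "lymphchain_invalid_parameter")
  }
  if (pre_ceiling_frac <= 1) {
    abort("`pre_ceiling_frac` must exceed 1 so the anchor is reachable",
      class = "lymphchain_invalid_parameter"
    )
  }
  d_max <- pre_ceiling_frac * d0_um
  d_min <- pre_floor_frac * d0_um
  # solve d(anchor) = d0 for the stiffening rate
  k_pre <- -log((d_max - d0_um) / (d_max - d_min)) / anchor_pressure
  pre <- constitutive_curve(d_min, d_max, k_pre)
  peak <- constitutive_curve(
    peak_floor_frac * d0_um, peak_fraction * d0_um,
    k_peak %||% k_pre
  )
  constitutive_set(pre, peak)
}

#' Constitutive curves fitted from tabulated pressure-diameter data
#'
#' Least-squares fit of the saturating-exponential family to user-supplied
#' `(P, d_pre, d_peak)` triples, e.g. digitized from an inflation test.
#'
#' @param data A data frame with columns `P` (cmH2O), `d_pre` and `d_peak`
#'   (um).
#' @return A [constitutive_set()].
#' @export
curves_from_table <- function(data) {
  stopifnot(all(c("P", "d_pre", "d_peak") %in% names(data)))
  fit_one <- function(P, d_um) {
    start <- c(d_min = min(d_um), d_max = max(d_um) * 1.02, k = 0.7)
    fn <- function(par) {
      sum((par[2] - (par[2] - par[1]) * exp(-par[3] * P) - d_um)^2)
    }
    par <- stats::optim(start, fn, method = "L-BFGS-B",
      lower = c(1e-3, 1e-3, 1e-4)
    )$par
    constitutive_curve(min(par[1], par[2] - 1e-9), par[2], par[3])
  }
  constitutive_set(
    fit_one(data$P, data$d_pre),
    fit_one(data$P, data$d_peak)
  )
}

#' Diameter from pressure and activation state
#'
#' The lumen diameter is the activation-weighted average of the pre- and
#' peak-twitch diameters, both evaluated at the pressure of the previous
#' time step: `d = (d_peak - d_pre) * t_act + d_pre`. This keeps the wall
#' update explicit inside the implicit fluid step.
#'
#' @param P_prev Pressure(s) from the previous time step, cmH2O.
#' @param t_act Activation state(s) in `[0, 1]`.
#' @param curves A [constitutive_set()].
#' @return Diameter(s), cm.
#' @examples
#' cs <- calibrate_default_curves()
#' diameter_update(3.75, 0, cs) # pre-twitch diameter
#' @export
diameter_update <- function(P_prev, t_act, curves) {
  check_t_act(t_act)
  d_pre <- diameter_at(curves$pre, P_prev)
  d_peak <- diameter_at(curves$peak, P_prev)
  (d_peak - d_pre) * t_act + d_pre
}

#' Area compliance from pressure and activation state
#'
#' For a circular lumen `C = dA/dP = (pi/2) d (dd/dP)`; the pre- and
#' peak-twitch compliances are interpolated linearly in the activation:
#' `C = (C_peak - C_pre) * t_act + C_pre`.
#'
#' @inheritParams diameter_update
#' @return Area compliance(s), cm^2/cmH2O (positive).
#' @export
compliance_update <- function(P_prev, t_act, curves) {
  check_t_act(t_act)
  c_pre <- pi / 2 * diameter_at(curves$pre, P_prev) * slope_at(curves$pre, P_prev)
  c_peak <- pi / 2 * diameter_at(curves$peak, P_prev) * slope_at(curves$peak, P_prev)
  (c_peak - c_pre) * t_act + c_pre
}

check_t_act <- function(t_act) {
  if (any(!is.finite(t_act)) || any(t_act < -1e-12) || any(t_act > 1 + 1e-12)) {
    abort("`t_act` must lie in [0, 1]", class = "lymphchain_invalid_parameter")
  }
  invisible(TRUE)
}

#' @export
print.constitutive_set <- function(x, ...) {
  cat("<constitutive_set>\n")
  for (state in c("pre", "peak")) {
    cv <- x[[state]]
    cat(sprintf(
      "  %s:  d(0) = %.1f um, d(inf) = %.1f um, k = %.3g /cmH2O\n",
      format(state, width = 4), cm_to_um(cv$d_min), cm_to_um(cv$d_max), cv$k
    ))
  }
  invisible(x)
}
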