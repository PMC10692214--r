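#' Derive activation-field parameters from contractility metrics
#'
#' Converts the pacemaking metrics measured on a vessel (initiation-site
#' density, contraction-wave conduction speed, contraction frequency and
#' period) into the parameters of the bivariate-Gaussian activation field.
#'
#' The spread rules encode that a contraction signal must decay between any
#' two pacemakers within one period: one decay spans about four standard
#' deviations, so `sigma_z = spacing / 8` with `spacing = 1/sites_per_cm`
#' (two decays between neighbouring sites) and `sigma_t = period / 4` (one
#' decay per period). The space-time correlation `rho` carries the wave
#' speed: the conditional-mean ridge of a bivariate Gaussian has slope
#' `rho * sigma_t / sigma_z` in the t-z plane, and equating that slope to
#' `1 / conduction_speed` gives `rho = sigma_z / (conduction_speed * sigma_t)`.
#' Fast conduction therefore yields a near-symmetric (unskewed) pulse and
#' slow conduction a strongly skewed one. `rho` is clipped to
#' `[0, rho_max]`; `rho_max` defaults to 0.99 so the covariance stays
#' positive definite.
#'
#' @param sites_per_cm Number of pacemaking (initiation) sites per cm (> 0).
#' @param conduction_speed Contraction-wave conduction speed in cm/s (> 0).
#' @param frequency Contraction frequency in 1/min (> 0).
#' @param period Contraction period in s; defaults to `60 / frequency`.
#' @param rho_max Upper bound applied to `rho` (< 1).
#'
#' @return An object of class `activation_params`: a list with the inputs
#'   plus `spacing` (cm), `sigma_z` (cm), `sigma_t` (s) and `rho`.
#' @examples
#' # wild-type contractility
#' activation_params(10, 0.98, 8.3, 7.23)
#' @export
activation_params <- function(sites_per_cm, conduction_speed, frequency,
                              period = 60 / frequency, rho_max = 0.99) {
  vals <- c(
    sites_per_cm = sites_per_cm, conduction_speed = conduction_speed,
    frequency = frequency, period = period
  )
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("all activation parameters must be finite and positive",
      class = "lymphchain_invalid_parameter"
    )
  }
  if (!is.finite(rho_max) || rho_max <= 0 || rho_max >= 1) {
    abort("`rho_max` must lie in (0, 1)", class = "lymphchain_invalid_parameter")
  }
  spacing <- 1 / sites_per_cm
  sigma_z <- spacing / 8
  sigma_t <- period / 4
  rho <- min(sigma_z / (conduction_speed * sigma_t), rho_max)
  structure(
    list(
      sites_per_cm = sites_per_cm, conduction_speed = conduction_speed,
      frequency = frequency, period = period, spacing = spacing,
      sigma_z = sigma_z, sigma_t = sigma_t, rho = rho, rho_max = rho_max
    ),
    class = "activation_params"
  )
}

#' @export
print.activation_params <- function(x, ...) {
  cat("<activation_params>\n")
  cat(sprintf(
    "  sites: %g /cm (spacing %.4g cm)   speed: %g cm/s\n",
    x$sites_per_cm, x$spacing, x$conduction_speed
  ))
  cat(sprintf(
    "  frequency: %g /min   period: %g s\n", x$frequency, x$period
  ))
  cat(sprintf(
    "  sigma_z: %.4g cm   sigma_t: %.4g s   rho: %.4g\n",
    x$sigma_z, x$sigma_t, x$rho
  ))
  invisible(x)
}

#' Place pacemaker sites along a lymphangion chain
#'
#' Sites are evenly spaced at the pacemaking distance `1/sites_per_cm`,
#' centred on the chain, and all fire at mid-period (`mu_t = period/2`);
#' wave propagation away from each site is carried entirely by the skew of
#' the activation Gaussian, not by phase offsets. Signal direction follows
#' `pattern`: `"antegrade"` (all forward), `"retrograde"` (all backward) or
#' `"alternating"` (antegrade, retrograde, antegrade, ...).
#'
#' @param chain_length Total chain length in cm (> 0).
#' @param sites_per_cm Pacemaking sites per cm (> 0).
#' @param pattern Directionality pattern of the pacemaking signals.
#' @param period Contraction period in s, used to set `mu_t = period/2`.
#'
#' @return A tibble of class `pacemaker_sites` with columns `site`,
#'   `position_z` (cm), `mu_t` (s) and `direction`.
#' @examples
#' place_pacemakers(0.3, 10, "antegrade", period = 7.23)
#' @export
place_pacemakers <- function(chain_length, sites_per_cm,
                             pattern = c("antegrade", "alternating", "retrograde"),
                             period) {
  pattern <- match.arg(pattern)
  if (!is.finite(chain_length) || chain_length <= 0) {
    abort("`chain_length` must be positive", class = "lymphchain_invalid_parameter")
  }
  if (!is.finite(sites_per_cm) || sites_per_cm <= 0) {
    abort("`sites_per_cm` must be positive", class = "lymphchain_invalid_parameter")
  }
  if (!is.finite(period) || period <= 0) {
    abort("`period` must be positive", class = "lymphchain_invalid_parameter")
  }
  spacing <- 1 / sites_per_cm
  if (spacing > chain_length) {
    warn("pacemaking distance exceeds chain length; placing a single midpoint site")
    k <- 1L
  } else {
    k <- max(1L, round(chain_length * sites_per_cm))
    # keep the centred arrangement inside the chain
    k <- min(k, floor(chain_length / spacing) + 1L)
  }
  position <- chain_length / 2 + (seq_len(k) - (k + 1) / 2) * spacing
  direction <- switch(pattern,
    antegrade = rep("antegrade", k),
    retrograde = rep("retrograde", k),
    alternating = rep(c("antegrade", "retrograde"), length.out = k)
  )
  out <- tibble(
    site = seq_len(k),
    position_z = position,
    mu_t = rep(period / 2, k),
    direction = direction
  )
  class(out) <- c("pacemaker_sites", class(out))
  out
}

#' Bivariate Gaussian pacemaker signal density
#'
#' Evaluates the two-dimensional Gaussian density over space and time that
#' models a single pacemaker's contraction signal. `rho` skews the density
#' in the z-t plane and encodes the propagation of the contraction wave;
#' its sign sets the propagation direction.
#'
#' @param z Axial coordinate(s), cm.
#' @param t Time(s), s. Recycled against `z`.
#' @param mu_z,mu_t Centre of the signal (pacemaker position, firing time).
#' @param sigma_z,sigma_t Spatial and temporal standard deviations (> 0).
#' @param rho Space-time correlation, `|rho| < 1`.
#'
#' @return Density values, 1/(cm s).
#' @examples
#' bivariate_gaussian(0, 0, 0, 0, 0.0125, 1.8075, 0) # peak = 1/(2*pi*sz*st)
#' @export
bivariate_gaussian <- function(z, t, mu_z, mu_t, sigma_z, sigma_t, rho) {
  if (!is.finite(sigma_z) || !is.finite(sigma_t) || sigma_z <= 0 || sigma_t <= 0) {
    abort("`sigma_z` and `sigma_t` must be positive", class = "lymphchain_invalid_parameter")
  }
  if (!is.finite(rho) || abs(rho) >= 1) {
    abort("|rho| must be < 1 (positive-definite covariance)",
      class = "lymphchain_invalid_parameter"
    )
  }
  zz <- (z - mu_z) / sigma_z
  tt <- (t - mu_t) / sigma_t
  q <- (zz^2 - 2 * rho * zz * tt + tt^2) / (2 * (1 - rho^2))
  exp(-q) / (2 * pi * sigma_z * sigma_t * sqrt(1 - rho^2))
}

# Raw (unnormalized) summed signal of all sites at (z, t), t already in
# [0, period); the sum runs over 2*n_images + 1 periodic temporal images so
# the steady-state cycle has no boundary artifact.
raw_activation <- function(z, t, sites, params, n_images = 1L) {
  total <- 0
  for (i in seq_len(nrow(sites))) {
    rho_i <- if (sites$direction[i] == "retrograde") -params$rho else params$rho
    for (k in -n_images:n_images) {
      total <- total + bivariate_gaussian(
        z, t + k * params$period,
        mu_z = sites$position_z[i], mu_t = sites$mu_t[i],
        sigma_z = params$sigma_z, sigma_t = params$sigma_t, rho = rho_i
      )
    }
  }
  total
}

#' Build the normalized spatiotemporal activation field
#'
#' Sums the bivariate-Gaussian signals of all pacemaker sites (including
#' periodic temporal images of each firing, so that the field is exactly
#' periodic) on a space-time grid and normalizes by the global maximum
#' `Gamma`, yielding the contraction parameter `t_act(z, t)` in `[0, 1]`.
#'
#' @param sites A `pacemaker_sites` tibble (see [place_pacemakers()]).
#' @param params An [activation_params()] object.
#' @param z_grid Node coordinates along the chain, cm.
#' @param t_grid Time samples covering one period, s; values are wrapped
#'   into `[0, period)`.
#' @param n_images Number of periodic temporal images summed on each side
#'   of the base firing (default 1, i.e. three images in total; Gaussians
#'   decay within one period under the `sigma_t = period/4` rule).
#'
#' @return An object of class `activation_field`: list with `z`, `t`,
#'   `period`, `values` (nodes x steps matrix, max exactly 1), `gamma`
#'   (the normalization constant), `sites` and `params`.
#' @examples
#' p <- activation_params(10, 0.98, 8.3, 7.23)
#' s <- place_pacemakers(0.3, 10, "antegrade", p$period)
#' f <- build_activation_field(s, p, seq(0, 0.3, 0.005), seq(0, 7.225, 0.05))
#' max(f$values) # 1
#' @export
build_activation_field <- function(sites, params, z_grid, t_grid, n_images = 1L) {
  if (is.null(sites) || nrow(sites) == 0) {
    abort("at least one pacemaker site is required", class = "lymphchain_invalid_parameter")
  }
  if (length(z_grid) == 0 || length(t_grid) == 0) {
    abort("`z_grid` and `t_grid` must be non-empty", class = "lymphchain_invalid_parameter")
  }
  t_wrapped <- t_grid %% params$period
  vals <- matrix(0, nrow = length(z_grid), ncol = length(t_grid))
  for (j in seq_along(t_wrapped)) {
    vals[, j] <- raw_activation(z_grid, t_wrapped[j], sites, params, n_images)
  }
  gamma <- max(vals)
  if (gamma <= 0) {
    abort("activation field is identically zero", class = "lymphchain_invalid_parameter")
  }
  structure(
    list(
      z = z_grid, t = t_grid, period = params$period,
      values = vals / gamma, gamma = gamma,
      sites = sites, params = params, n_images = as.integer(n_images)
    ),
    class = "activation_field"
  )
}

#' Evaluate an activation field at an arbitrary time
#'
#' Returns the normalized activation of every node at time `t`, wrapping
#' `t` into the contraction period, so the field is periodic to machine
#' precision. Grid times are looked up directly; off-grid times are
#' recomputed from the Gaussian sum with the stored normalization.
#'
#' @param field An `activation_field`.
#' @param t Scalar time, s.
#' @return Numeric vector over `field$z`.
#' @export
eval_activation <- function(field, t) {
  tw <- t %% field$period
  tg <- field$t %% field$period
  j <- which(abs(tg - tw) < 1e-9)
  if (length(j) > 0) {
    return(field$values[, j[1]])
  }
  raw_activation(field$z, tw, field$sites, field$params, field$n_images) / field$gamma
}

#' @export
print.activation_field <- function(x, ...) {
  cat("<activation_field>\n")
  cat(sprintf(
    "  %d nodes x %d time steps, period %g s, %d site(s)\n",
    length(x$z), length(x$t), x$period, nrow(x$sites)
  ))
  cat(sprintf("  gamma = %.4g, mean t_act = %.4g\n", x$gamma, mean(x$values)))
  invisible(x)
}
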