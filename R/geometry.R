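#' Discretized geometry of a lymphangion chain
#'
#' A chain of `n_lymphangions` segments, each a tube of length
#' `lymphangion_length` discretized with spacing `dz` (which must divide
#' the segment length exactly). Secondary valves sit at the segment
#' boundaries: one at the inlet, one between each pair of adjacent
#' lymphangions and one at the outlet, i.e. `n_lymphangions + 1` valves.
#'
#' @param n_lymphangions Number of lymphangions (default 3).
#' @param lymphangion_length Segment length, cm (default 0.1 = 1 mm).
#' @param dz Axial grid spacing, cm (default 0.005 = 50 um).
#' @return An object of class `chain_geometry` with node coordinates,
#'   segment ids, face and valve index maps.
#' @examples
#' chain_geometry()
#' @export
chain_geometry <- function(n_lymphangions = 3, lymphangion_length = 0.1,
                           dz = 0.005) {
  if (n_lymphangions < 1 || lymphangion_length <= 0 || dz <= 0) {
    abort("geometry parameters must be positive", class = "lymphchain_invalid_parameter")
  }
  ncell <- lymphangion_length / dz
  if (abs(ncell - round(ncell)) > 1e-9) {
    abort("`dz` must divide `lymphangion_length` exactly",
      class = "lymphchain_invalid_parameter"
    )
  }
  ncell <- as.integer(round(ncell))
  m <- ncell + 1L # nodes per lymphangion
  s <- as.integer(n_lymphangions)
  np <- s * m
  node_seg <- rep(seq_len(s), each = m)
  local_j <- rep(seq_len(m), times = s)
  node_z <- (node_seg - 1L) * lymphangion_length + (local_j - 1L) * dz

  # faces connect consecutive nodes within a segment
  face_up <- which(local_j < m)
  face_dn <- face_up + 1L
  nf <- length(face_up)

  # valve v connects up-node (0 = inlet reservoir) to down-node (0 = outlet)
  valve_up <- c(0L, seq_len(s - 1L) * m, s * m)
  valve_dn <- c(1L, seq_len(s - 1L) * m + 1L, 0L)

  # per-node adjacency: index of the face/valve carrying flow in and out
  node_in_face <- integer(np)
  node_out_face <- integer(np)
  node_in_face[face_dn] <- seq_len(nf)
  node_out_face[face_up] <- seq_len(nf)
  node_in_valve <- integer(np)
  node_out_valve <- integer(np)
  nv <- s + 1L
  for (v in seq_len(nv)) {
    if (valve_dn[v] > 0L) node_in_valve[valve_dn[v]] <- v
    if (valve_up[v] > 0L) node_out_valve[valve_up[v]] <- v
  }

  # control-volume length of each node (half cells at segment ends)
  h <- rep(dz, np)
  h[local_j == 1L | local_j == m] <- dz / 2

  structure(
    list(
      n_lymphangions = s, lymphangion_length = lymphangion_length, dz = dz,
      nodes_per_segment = m, n_nodes = np, n_faces = nf, n_valves = nv,
      node_z = node_z, node_seg = node_seg, local_j = local_j, h = h,
      face_up = face_up, face_dn = face_dn,
      valve_up = valve_up, valve_dn = valve_dn,
      node_in_face = node_in_face, node_out_face = node_out_face,
      node_in_valve = node_in_valve, node_out_valve = node_out_valve,
      chain_length = s * lymphangion_length
    ),
    class = "chain_geometry"
  )
}

#' @export
print.chain_geometry <- function(x, ...) {
  cat("<chain_geometry>\n")
  cat(sprintf(
    "  %d lymphangion(s) x %g cm, dz = %g cm (%d nodes, %d valves)\n",
    x$n_lymphangions, x$lymphangion_length, x$dz, x$n_nodes, x$n_valves
  ))
  invisible(x)
}

#' Lymph fluid parameters
#'
#' @param mu Lymph viscosity, cmH2O s (default 1e-5).
#' @param rho Lymph density, cmH2O s^2/cm^2 (default 1070e-6).
#' @param zeta Velocity-profile constant (>= 2; 2 gives the parabolic
#'   Poiseuille profile).
#' @param delta_s Convective correction; `1 + delta_s` is the momentum-flux
#'   correction factor. Defaults to `1/(zeta + 1)`, the exact factor of the
#'   power-law profile (4/3 for `zeta = 2`).
#' @return An object of class `fluid_params`.
#' @export
fluid_params <- function(mu = 1e-5, rho = 1070e-6, zeta = 2,
                         delta_s = 1 / (zeta + 1)) {
  if (mu <= 0 || rho <= 0) {
    abort("`mu` and `rho` must be positive", class = "lymphchain_invalid_parameter")
  }
  if (zeta < 2) {
    abort("`zeta` must be >= 2", class = "lymphchain_invalid_parameter")
  }
  structure(
    list(mu = mu, rho = rho, zeta = zeta, delta_s = delta_s),
    class = "fluid_params"
  )
}

#' Viscous friction force per unit length
#'
#' `tau = -2 (zeta + 2) mu pi Q / A`, the wall friction of the prescribed
#' power-law velocity profile. Always opposes the flow. For `zeta = 2` the
#' steady momentum balance reduces to the Hagen-Poiseuille law.
#'
#' @param Q Flow(s), cm^3/s.
#' @param A Lumen area(s), cm^2 (> 0).
#' @param fluid A [fluid_params()] object.
#' @return Friction force per unit length, cmH2O (force/length in the
#'   cm-s-cmH2O unit system).
#' @export
friction_term <- function(Q, A, fluid) {
  if (any(A <= 0)) {
    abort("lumen area must be positive (lumen collapse)",
      class = "lymphchain_degenerate_lumen"
    )
  }
  -2 * (fluid$zeta + 2) * fluid$mu * pi * Q / A
}

#' Axial velocity profile
#'
#' `u(r) = (Q/A) (zeta + 2)/zeta (1 - (r/r_i)^zeta)` with `r` the radial
#' coordinate and `r_i` the lumen radius: no-slip at the wall, and the
#' cross-sectional average equals the mean velocity `Q/A`.
#'
#' @param r Radial coordinate(s), cm, in `[0, r_i]`.
#' @param Q Flow, cm^3/s.
#' @param A Lumen area, cm^2.
#' @param zeta Velocity-profile constant.
#' @return Axial velocity, cm/s.
#' @export
velocity_profile <- function(r, Q, A, zeta = 2) {
  ri <- sqrt(A / pi)
  if (any(r < 0) || any(r > ri + 1e-12)) {
    abort("`r` must lie inside the lumen [0, r_i]", class = "lymphchain_invalid_parameter")
  }
  (Q / A) * (zeta + 2) / zeta * (1 - (r / ri)^zeta)
}
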