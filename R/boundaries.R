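# Boundary closures resolving the links left open by streaming. Fixed
# resolution order each step: walls, then velocity inlets, then pressure
# outlets (corner sites shared by a cap and a wall resolve their wall links
# first). All three operate on the `lbm_state` returned by
# stream_populations() and consume its stored post-collision populations.

#' Halfway bounce-back walls
#'
#' For every wet site `x` and direction `i` whose neighbour is solid, the
#' post-collision population is reflected into the opposite direction:
#' `f_opp(i)(x) <- f*_i(x)`. This places a no-slip wall halfway along the
#' cut link and conserves mass exactly.
#'
#' @param state An `lbm_state` from [stream_populations()].
#' @param domain A `voxel_domain`.
#' @return The state with wall links resolved.
#' @export
apply_walls <- function(state, domain) {
  vs <- velocity_set()
  opp <- vs$opposite
  ng <- domain$neigh
  for (i in 1:19) {
    wall <- which(ng[i, ] == -1L)
    if (length(wall) > 0) {
      state$f[cbind(opp[i], wall)] <- state$f_star[cbind(i, wall)]
    }
  }
  state
}

#' Prescribed-velocity inlet (moving-wall bounce-back)
#'
#' Imposes the transient inlet velocity on a cap plane. Each inlet site's
#' target velocity is `u_b(s, t) = v_peak(t) * w(s) * d`, with `w(s)` the
#' parabolic wall-distance weight and `d` the (unit) inlet direction,
#' normally the inward cap normal. Links crossing the cap plane are closed
#' with momentum-corrected bounce-back against a fictitious wall moving at
#' `u_b`:
#' `f_opp(i)(x) <- f*_i(x) - 6 w_i rho0 (c_i . u_b)`, `rho0` the local
#' post-collision density. With `v_peak = 0` this reduces exactly to
#' [apply_walls()] on those links.
#'
#' @param state An `lbm_state` (walls already applied).
#' @param domain A `voxel_domain`.
#' @param iolet Iolet id or label.
#' @param v_peak Peak inlet speed in m/s (requires `units`).
#' @param units A [lattice_units()] object (with `v_peak`).
#' @param v_lat Alternatively, the peak speed directly in lattice units.
#' @return The state with this inlet's links resolved.
#' @export
apply_velocity_inlet <- function(state, domain, iolet, v_peak = NULL,
                                 units = NULL, v_lat = NULL) {
  io <- resolve_iolet(domain, iolet)
  if (is.null(v_lat)) {
    if (is.null(v_peak) || is.null(units)) {
      abort_config("Supply either `v_lat` or both `v_peak` and `units`.")
    }
    v_lat <- v_peak * units$dt / units$dx
  }
  if (!is.finite(v_lat)) abort_parameter("Inlet speed must be finite.")
  if (abs(v_lat) >= 1 / sqrt(3)) {
    abort_parameter(sprintf(
      "Inlet lattice speed %.3g reaches the lattice sound speed; reduce dt or the inlet velocity.",
      v_lat
    ))
  }
  vs <- velocity_set()
  opp <- vs$opposite
  sel <- which(domain$iolet_of == io$id)
  if (length(sel) == 0) return(state)
  rho0 <- colSums(state$f_star[, sel, drop = FALSE])
  dirv <- c(io$dirx, io$diry, io$dirz)
  ub <- v_lat * domain$weight[sel]          # per-site speed along dirv
  ng <- domain$neigh
  for (i in 1:19) {
    cu <- sum(vs$directions[i, ] * dirv)
    open <- which(ng[i, sel] == -2L)
    if (length(open) > 0) {
      s <- sel[open]
      state$f[cbind(opp[i], s)] <-
        state$f_star[cbind(i, s)] -
        6 * vs$weights[i] * rho0[open] * cu * ub[open]
    }
  }
  state
}

#' Fixed-pressure outlet with zero normal pressure gradient
#'
#' Holds the outlet plane at a reference lattice density `rho_out`
#' (pressure `c_s^2 rho_out`) while extrapolating the velocity of the
#' interior neighbour along the cap normal (zeroth order). The outlet
#' sites' populations are replaced by `equilibrium(rho_out, u_interior)`,
#' which pins the plane density and leaves the normal pressure gradient at
#' (approximately) zero. A domain resting uniformly at
#' `equilibrium(rho_out, 0)` is a fixed point of this closure.
#'
#' @param state An `lbm_state` (walls and inlets already applied, so the
#'   interior neighbours are fully resolved).
#' @param domain A `voxel_domain`.
#' @param iolet Iolet id or label.
#' @param rho_out Reference lattice density (default 1).
#' @return The state with this outlet's sites closed.
#' @export
apply_pressure_outlet <- function(state, domain, iolet, rho_out = 1) {
  io <- resolve_iolet(domain, iolet)
  sel <- which(domain$iolet_of == io$id)
  if (length(sel) == 0) return(state)
  nb <- domain$interior[sel]
  if (any(nb <= 0)) abort_geometry("Outlet site lacks an interior neighbour.")
  fnb <- state$f[, nb, drop = FALSE]
  if (anyNA(fnb)) {
    abort_geometry("Outlet interior neighbours are not fully resolved; apply walls and inlets first.")
  }
  m <- macroscopics(fnb)
  state$f[, sel] <- equilibrium(rho_out, m$u)
  state
}
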