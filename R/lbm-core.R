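# Reference (vectorised R) implementation of the BGK lattice Boltzmann
# kernel. The production time-stepper lives in src/lbm.cpp; these functions
# define the operations one at a time, are used directly on small problems
# and in the test-suite, and the compiled driver is required to agree with
# their composition to rounding.

#' Second-order Maxwell-Boltzmann equilibrium populations
#'
#' \eqn{f_i^{eq} = w_i \rho (1 + 3 c_i\cdot u + \tfrac{9}{2}(c_i\cdot u)^2
#' - \tfrac{3}{2} u^2)} in lattice units. The zeroth and first moments of
#' the result equal `rho` and `rho * u` exactly (to rounding).
#'
#' @param rho Lattice density: scalar or length-n vector (must be > 0).
#' @param u Lattice velocity: length-3 vector or 3 x n matrix.
#' @return A 19 x n matrix of populations (n = 1 for scalar input).
#' @export
#' @examples
#' f <- equilibrium(1, c(0.1, 0, 0))
#' colSums(f)  # density 1
equilibrium <- function(rho, u) {
  vs <- velocity_set()
  if (is.null(dim(u))) u <- matrix(u, nrow = 3)
  n <- ncol(u)
  if (length(rho) == 1) rho <- rep(rho, n)
  if (length(rho) != n) abort_parameter("`rho` and `u` lengths disagree.")
  if (any(rho <= 0)) abort_parameter("`rho` must be positive.")
  cu <- vs$directions %*% u                       # 19 x n
  usq <- colSums(u * u)
  poly <- 1 + 3 * cu + 4.5 * cu^2 -
    matrix(1.5 * usq, 19, n, byrow = TRUE)
  vs$weights * poly * matrix(rho, 19, n, byrow = TRUE)
}

#' Macroscopic moments of a distribution field
#'
#' Density is the zeroth moment \eqn{\rho = \sum_i f_i}, velocity the first
#' \eqn{u = \sum_i c_i f_i / \rho}, and pressure \eqn{p = c_s^2 \rho}
#' (all in lattice units).
#'
#' @param f A 19 x n population matrix.
#' @return An object of class `macro_field`: list with `rho` (length n),
#'   `u` (3 x n), `p` (length n).
#' @export
macroscopics <- function(f) {
  vs <- velocity_set()
  rho <- colSums(f)
  if (any(!is.finite(rho)) || any(rho <= 0)) {
    bad <- which(!is.finite(rho) | rho <= 0)[1]
    abort_diverged(sprintf(
      "Non-positive or non-finite density at site %d: simulation diverged.", bad
    ), site = bad)
  }
  m <- t(vs$directions) %*% f                      # 3 x n
  u <- sweep(m, 2, rho, "/")
  structure(list(rho = rho, u = u, p = vs$cs2 * rho), class = "macro_field")
}

#' BGK single-relaxation-time collision
#'
#' Relaxes every site's populations towards the local equilibrium:
#' \eqn{f_i \leftarrow f_i - (f_i - f_i^{eq}(\rho, u))/\tau}. Mass and
#' momentum are conserved per site; with `tau = 1` the output is exactly
#' the local equilibrium.
#'
#' @param f A 19 x n population matrix.
#' @param tau Dimensionless relaxation time (> 1/2).
#' @return The post-collision 19 x n population matrix.
#' @export
collide_bgk <- function(f, tau) {
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0.5) {
    abort_parameter("`tau` must be a single value > 1/2.")
  }
  if (any(!is.finite(f))) {
    bad <- which(!apply(is.finite(f), 2, all))[1]
    abort_diverged(sprintf(
      "Non-finite population at site %d: simulation diverged.", bad
    ), site = bad)
  }
  m <- macroscopics(f)
  feq <- equilibrium(m$rho, m$u)
  f - (f - feq) / tau
}

#' Initialise a field at local equilibrium
#'
#' @param domain A `voxel_domain`.
#' @param rho Lattice density (scalar or per-site).
#' @param u Lattice velocity (length-3, recycled, or 3 x n matrix).
#' @return A 19 x n population matrix over the wet sites of `domain`.
#' @export
init_equilibrium <- function(domain, rho = 1, u = c(0, 0, 0)) {
  n <- n_wet(domain)
  if (is.null(dim(u))) u <- matrix(u, nrow = 3, ncol = n)
  equilibrium(rho, u)
}

#' Stream populations along their lattice directions
#'
#' Propagates each post-collision population from its site to the
#' neighbouring site one lattice vector away, for links whose target is a
#' wet site (fluid or iolet). Links that hit a wall or leave the domain
#' through an iolet cap are *not* resolved here: the returned state records
#' them as missing, and [apply_walls()], [apply_velocity_inlet()] and
#' [apply_pressure_outlet()] fill them in. On a fully periodic domain every
#' link is wet and the result is complete.
#'
#' @param f The post-collision 19 x n population matrix.
#' @param domain A `voxel_domain`.
#' @return An object of class `lbm_state`: list with `f` (streamed
#'   populations, `NA` where unresolved) and `f_star` (the post-collision
#'   input, needed by the boundary closures).
#' @export
stream_populations <- function(f, domain) {
  ng <- domain$neigh
  n <- ncol(f)
  fn <- matrix(NA_real_, 19, n)
  for (i in 1:19) {
    tgt <- ng[i, ]
    ok <- tgt > 0
    fn[i, tgt[ok]] <- f[i, ok]
  }
  structure(list(f = fn, f_star = f), class = "lbm_state")
}

#' Advance the solver state by one time step (reference path)
#'
#' Applies the fixed update order collide, stream, walls, velocity inlets,
#' pressure outlets. This is the vectorised R reference used for small
#' domains and verification; production runs go through
#' [run_simulation()], whose compiled driver performs the identical update.
#'
#' @param f 19 x n population matrix.
#' @param domain A `voxel_domain`.
#' @param tau Relaxation time.
#' @param inlet_speed Named numeric vector of *lattice* peak speeds, one
#'   entry per velocity-inlet iolet label (may be empty if none).
#' @param rho_out Lattice outlet density (scalar, default 1).
#' @return The updated 19 x n population matrix.
#' @export
lbm_step <- function(f, domain, tau, inlet_speed = numeric(), rho_out = 1) {
  fstar <- collide_bgk(f, tau)
  state <- stream_populations(fstar, domain)
  state <- apply_walls(state, domain)
  io <- domain$iolets
  for (k in which(io$kind == "velocity_inlet")) {
    v <- inlet_speed[[io$label[k]]]
    if (is.null(v)) abort_config(sprintf("No inlet speed given for '%s'.", io$label[k]))
    state <- apply_velocity_inlet(state, domain, io$id[k], v_lat = v)
  }
  for (k in which(io$kind == "pressure_outlet")) {
    state <- apply_pressure_outlet(state, domain, io$id[k], rho_out = rho_out)
  }
  if (anyNA(state$f)) {
    abort_geometry("Unresolved links remain after boundary closure; domain classification is incomplete.")
  }
  state$f
}
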