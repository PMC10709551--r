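#' Physical-to-lattice unit system
#'
#' Bundles the lattice spacing, time step and reference mass density that
#' define the map between physical (SI) and lattice quantities. All solver
#' arithmetic happens in lattice units (site spacing 1, time step 1,
#' reference density 1); observables are converted back with the factors
#' stored here.
#'
#' Conversion factors: velocity `dx/dt`, pressure and stress
#' `rho_ref * (dx/dt)^2`, volumetric flow rate `dx^3/dt`, kinematic
#' viscosity `dx^2/dt`.
#'
#' @param dx Lattice spacing in metres.
#' @param dt Time step in seconds.
#' @param rho_ref Physical mass density mapped to lattice density 1,
#'   in kg/m^3 (default 1000, whole blood).
#' @return An object of class `lattice_units`.
#' @export
#' @examples
#' u <- lattice_units(dx = 25e-6, dt = 1e-6)
#' u$velocity   # dx/dt in m/s per lattice unit
lattice_units <- function(dx, dt, rho_ref = 1000) {
  if (!is.numeric(dx) || length(dx) != 1 || dx <= 0) {
    abort_parameter("`dx` must be a single positive length in metres.")
  }
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) {
    abort_parameter("`dt` must be a single positive time in seconds.")
  }
  if (!is.numeric(rho_ref) || length(rho_ref) != 1 || rho_ref <= 0) {
    abort_parameter("`rho_ref` must be a single positive density in kg/m^3.")
  }
  structure(
    list(
      dx = dx, dt = dt, rho_ref = rho_ref,
      velocity = dx / dt,
      stress = rho_ref * (dx / dt)^2,
      flow_rate = dx^3 / dt,
      viscosity = dx^2 / dt
    ),
    class = "lattice_units"
  )
}

#' @export
print.lattice_units <- function(x, ...) {
  cat(sprintf(
    "<lattice_units> dx = %g m, dt = %g s, rho_ref = %g kg/m^3\n",
    x$dx, x$dt, x$rho_ref
  ))
  invisible(x)
}

#' BGK relaxation time from a physical viscosity
#'
#' Computes the dimensionless single-relaxation-time parameter
#' \eqn{\tau = 3 \nu \, dt / dx^2 + 1/2}, equivalently
#' \eqn{\tau = \nu_{lat}/c_s^2 + 1/2} with \eqn{c_s^2 = 1/3}. With blood
#' viscosity 4.0e-6 m^2/s on a 25 micrometre / 1 microsecond lattice this
#' gives 0.5192.
#'
#' @param nu Kinematic viscosity in m^2/s (must be positive).
#' @param units A [lattice_units()] object.
#' @return The dimensionless relaxation time (a value > 1/2).
#' @seealso [viscosity_from_tau()] for the inverse map.
#' @export
#' @examples
#' relaxation_time(4.0e-6, lattice_units(25e-6, 1e-6))  # 0.5192
relaxation_time <- function(nu, units) {
  stopifnot(inherits(units, "lattice_units"))
  if (!is.numeric(nu) || length(nu) != 1 || !is.finite(nu) || nu <= 0) {
    abort_parameter("`nu` must be a single positive kinematic viscosity in m^2/s.")
  }
  tau <- 3 * nu * units$dt / units$dx^2 + 0.5
  if (tau <= 0.5) {
    abort_parameter("Computed relaxation time is not > 1/2; check `nu`, `dx`, `dt`.")
  }
  tau
}

#' Kinematic viscosity implied by a relaxation time
#'
#' Inverse of [relaxation_time()]: \eqn{\nu = c_s^2 (\tau - 1/2) dx^2/dt}.
#'
#' @param tau Dimensionless relaxation time (> 1/2).
#' @param units A [lattice_units()] object.
#' @return Kinematic viscosity in m^2/s.
#' @export
viscosity_from_tau <- function(tau, units) {
  stopifnot(inherits(units, "lattice_units"))
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0.5) {
    abort_parameter("`tau` must be a single value > 1/2.")
  }
  (tau - 0.5) / 3 * units$dx^2 / units$dt
}

#' Low-Mach stability diagnostic
#'
#' The lattice Boltzmann method recovers incompressible flow only when the
#' lattice Mach number is small; error terms grow as Ma^2. This diagnostic
#' converts a peak physical speed to lattice units, forms
#' \eqn{Ma = u_{lat}/c_s} with \eqn{c_s = 1/\sqrt{3}}, and reports a
#' pass/fail against a Mach cap (default 0.1) together with the relaxation
#' time check \eqn{\tau > 1/2}.
#'
#' @param u_max_phys Peak flow speed in m/s (non-negative).
#' @param units A [lattice_units()] object.
#' @param tau Dimensionless relaxation time.
#' @param mach_cap Largest acceptable lattice Mach number (default 0.1).
#' @return A one-row tibble with columns `u_max_phys`, `lattice_speed`,
#'   `mach`, `tau`, `mach_cap`, `pass`.
#' @export
#' @examples
#' stability_report(0.595, lattice_units(25e-6, 1e-6), tau = 0.5192)
stability_report <- function(u_max_phys, units, tau, mach_cap = 0.1) {
  stopifnot(inherits(units, "lattice_units"))
  if (!is.numeric(u_max_phys) || length(u_max_phys) != 1 || u_max_phys < 0) {
    abort_parameter("`u_max_phys` must be a single non-negative speed in m/s.")
  }
  u_lat <- u_max_phys * units$dt / units$dx
  cs <- 1 / sqrt(3)
  mach <- u_lat / cs
  tibble::tibble(
    u_max_phys = u_max_phys,
    lattice_speed = u_lat,
    mach = mach,
    tau = tau,
    mach_cap = mach_cap,
    pass = (mach <= mach_cap) && (tau > 0.5) && (u_lat < cs)
  )
}
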