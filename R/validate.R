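# Analytic validation cases: decaying shear wave (viscosity recovery),
# Poiseuille tube (profile, discharge, wall shear stress), planar Couette
# flow (wall shear stress). These are the package's "validate" suite; the
# test-suite asserts their tolerances and the methods vignette discusses
# the expected error levels.

#' Viscosity recovery from a decaying shear wave
#'
#' Initialises a fully periodic box with a transverse shear wave
#' `u_y(x, 0) = u0 sin(2 pi x / n)`, evolves it, and fits the kinematic
#' viscosity from the exponential amplitude decay
#' `A(t) = A(0) exp(-nu k^2 t)` between two measurement times. The fitted
#' value is compared with the nominal `c_s^2 (tau - 1/2) dx^2 / dt`.
#' The run is performed in pure lattice units (`dx = dt = 1`).
#'
#' @param tau Relaxation time.
#' @param n_sites Sites per wavelength (box length; at least 8).
#' @param u0 Initial lattice velocity amplitude (small, to stay in the
#'   linear regime).
#' @param measure_steps Length-2 vector: the two measurement steps.
#' @return A one-row tibble: `tau`, `nu_fit`, `nu_nominal`, `rel_err`
#'   (all viscosities in lattice units).
#' @export
#' @examples
#' \donttest{
#' fit_shear_viscosity(0.8)
#' }
fit_shear_viscosity <- function(tau, n_sites = 64, u0 = 1e-3,
                                measure_steps = c(400, 1400)) {
  if (n_sites < 8) abort_parameter("Need at least 8 sites per wavelength.")
  dom <- build_periodic_box(c(n_sites, 4, 4), dx = 1)
  nu_lat <- (tau - 0.5) / 3
  k <- 2 * pi / n_sites
  x <- dom$sites[, 1] - 0.5
  u <- rbind(0, u0 * sin(k * x), 0)
  f0 <- equilibrium(1, u)
  cfg <- run_config(dom, inlets = list(), nu = nu_lat, rho_ref = 1,
                    tau = tau, duration = max(measure_steps), cadence = 0,
                    snapshot_times = measure_steps, label = "shear wave")
  run <- run_simulation(cfg, f0 = f0)
  amp <- vapply(run$snapshots, function(s) {
    m <- macroscopics(s$f)
    2 * sum(m$u[2, ] * sin(k * x)) / length(x)
  }, numeric(1))
  nu_fit <- log(amp[1] / amp[2]) / (k^2 * diff(measure_steps))
  tibble::tibble(
    tau = tau, nu_fit = nu_fit, nu_nominal = nu_lat,
    rel_err = nu_fit / nu_lat - 1
  )
}

#' Poiseuille tube validation
#'
#' Voxelises a straight circular tube, drives it with a steady parabolic
#' velocity inlet against a fixed-pressure outlet, runs to steady state,
#' and measures (at the mid-tube cross-section, away from the caps):
#' the relative L2 error of the axial velocity profile against the
#' analytic parabola `u = u_max (1 - (r/R)^2)`, the outlet discharge
#' against `pi R^2 u_max / 2`, the mean wall shear stress against
#' `2 rho nu u_max / R`, and the inlet/outlet mass balance.
#'
#' @param radius,length Tube dimensions, m.
#' @param dx Lattice spacing, m (default gives 32 sites per diameter).
#' @param v_inlet Peak inlet velocity, m/s.
#' @param nu Kinematic viscosity, m^2/s.
#' @param rho_ref Physical density, kg/m^3.
#' @param tau Relaxation time (default 1, where the combined
#'   BGK/bounce-back truncation error is smallest).
#' @param steady_tol,max_time Steady-state stopping tolerance and time cap.
#' @return A list with `measures` (one-row tibble: `profile_l2`,
#'   `q_rel_err`, `wss_rel_err`, `mass_imbalance`, `u_max`), `run`,
#'   `domain`.
#' @export
poiseuille_validation <- function(radius = 8e-4, length = 4e-3, dx = 5e-5,
                                  v_inlet = 0.01, nu = 4.0e-6,
                                  rho_ref = 1000, tau = 1.0,
                                  steady_tol = 1e-6, max_time = 0.6) {
  dom <- voxelize(build_tube(radius, length), dx)
  run <- steady_run(dom, v_inlet, nu = nu, tau = tau,
                    steady_tol = steady_tol, max_time = max_time)
  units <- run$config$units
  m <- macroscopics(run$f_final)

  mid_layer <- round(dim(dom$labels)[2] / 2)
  mid <- which(dom$sites[, 2] == mid_layer)
  uy <- m$u[2, mid] * units$velocity
  xz <- dom$sites[mid, c(1, 3), drop = FALSE]
  # tube axis at x = z = 0 by construction
  xc <- dom$origin[1] + (xz[, 1] - 0.5) * dx
  zc <- dom$origin[3] + (xz[, 2] - 0.5) * dx
  r <- sqrt(xc^2 + zc^2)
  u_max <- max(uy)
  u_analytic <- u_max * pmax(0, 1 - (r / radius)^2)
  profile_l2 <- sqrt(sum((uy - u_analytic)^2) / sum(u_analytic^2))

  q_in <- outlet_flow_rate(run$f_final, dom, "in", units)
  q_out <- outlet_flow_rate(run$f_final, dom, "out", units)
  q_rel_err <- q_out / (pi * radius^2 * u_max / 2) - 1
  mass_imbalance <- (q_out - q_in) / q_out

  w <- wss_field(run$f_final, run$config$tau, dom, units)
  ymid <- dom$origin[2] + (mid_layer - 0.5) * dx
  band <- abs(w$y - ymid) < length / 4
  wss_target <- 2 * rho_ref * nu * u_max / radius
  wss_rel_err <- mean(w$wss_pa[band]) / wss_target - 1

  list(
    measures = tibble::tibble(
      profile_l2 = profile_l2, q_rel_err = q_rel_err,
      wss_rel_err = wss_rel_err, mass_imbalance = mass_imbalance,
      u_max = u_max
    ),
    run = run, domain = dom
  )
}

#' Planar Couette validation
#'
#' Runs a channel (periodic in-plane) sheared by a tangentially moving
#' lid to steady state and compares the wall shear stress at the static
#' wall with the analytic `rho nu U / H`, `H` the gap between the two
#' halfway wall planes, plus the linearity of the velocity profile.
#'
#' @param nz Fluid layers across the gap.
#' @param dx Lattice spacing, m.
#' @param U Lid speed, m/s.
#' @param nu Kinematic viscosity, m^2/s.
#' @param rho_ref Physical density, kg/m^3.
#' @param tau Relaxation time.
#' @return A list with `measures` (one-row tibble: `wss_rel_err`,
#'   `profile_rms`), `run`, `domain`.
#' @export
couette_validation <- function(nz = 16, dx = 1e-4, U = 0.02, nu = 4.0e-6,
                               rho_ref = 1000, tau = 0.8) {
  dom <- build_couette_channel(nx = 4, ny = 4, nz = nz, dx = dx)
  wfs <- list(lid = healthy_profile(U, period = 0.2, warmup = 0.02,
                                    p_min = 1 - 1e-12))
  cfg <- run_config(dom, wfs, nu = nu, rho_ref = rho_ref, tau = tau,
                    duration = 1.2, cadence = 100,
                    steady_tol = 1e-9, steady_every = 100,
                    label = "Couette")
  run <- run_simulation(cfg)
  units <- run$config$units
  m <- macroscopics(run$f_final)
  H <- nz * dx
  z <- dom$sites[, 3]
  prof <- tapply(m$u[1, ], z, mean) * units$velocity
  # analytic linear profile between the halfway wall planes
  zl <- (as.numeric(names(prof)) - 1.5) * dx   # 0 at the static wall
  lin <- U * zl / H
  profile_rms <- sqrt(mean((prof - lin)^2)) / U
  w <- wss_field(run$f_final, cfg$tau, dom, units)
  wss_rel_err <- mean(w$wss_pa) / (rho_ref * nu * U / H) - 1
  list(
    measures = tibble::tibble(wss_rel_err = wss_rel_err,
                              profile_rms = profile_rms),
    run = run, domain = dom
  )
}

#' Run the analytic validation suite
#'
#' Convenience wrapper running the decaying shear wave (three relaxation
#' times), a small Poiseuille tube and the Couette channel, and returning
#' one row per check with its measured relative error.
#'
#' @param quick If `TRUE` (default) the Poiseuille tube runs at 16 sites
#'   per diameter for speed; `FALSE` uses the full 32-site fixture.
#' @return A tibble `check`, `value`, `reference`, `rel_err`.
#' @export
validate_solver <- function(quick = TRUE) {
  rows <- list()
  for (tau in c(0.55, 0.8, 1.2)) {
    sw <- fit_shear_viscosity(tau)
    rows[[length(rows) + 1]] <- tibble::tibble(
      check = sprintf("shear-wave viscosity (tau = %.2f)", tau),
      value = sw$nu_fit, reference = sw$nu_nominal, rel_err = sw$rel_err
    )
  }
  pv <- if (quick) {
    poiseuille_validation(radius = 4e-4, length = 2.4e-3, dx = 5e-5,
                          max_time = 0.4)
  } else {
    poiseuille_validation()
  }
  pm <- pv$measures
  rows[[length(rows) + 1]] <- tibble::tibble(
    check = c("Poiseuille profile L2", "Poiseuille discharge",
              "Poiseuille wall shear stress"),
    value = c(pm$profile_l2, pm$q_rel_err + 1, pm$wss_rel_err + 1),
    reference = c(0, 1, 1),
    rel_err = c(pm$profile_l2, pm$q_rel_err, pm$wss_rel_err)
  )
  cm <- couette_validation()$measures
  rows[[length(rows) + 1]] <- tibble::tibble(
    check = "Couette wall shear stress",
    value = cm$wss_rel_err + 1, reference = 1, rel_err = cm$wss_rel_err
  )
  dplyr::bind_rows(rows)
}
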