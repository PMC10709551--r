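# Run orchestration: a validated configuration object, the compiled-driver
# run, paired healthy/stroke comparisons, the variant x scenario experiment
# matrix, and grid-convergence studies.

#' Build and validate a run configuration
#'
#' Derives the full discretisation from the domain spacing and either a
#' target relaxation time or an explicit time step, checks the low-Mach
#' requirement against the largest inlet velocity that will ever be
#' applied, and schedules the step count (`round(duration / dt)`; 3 s at
#' dt = 1 microsecond schedules exactly 3,000,000 iterations).
#'
#' @param domain A `voxel_domain`.
#' @param inlets Named list of [healthy_profile()] waveforms; names must
#'   cover every velocity inlet of `domain`.
#' @param nu Kinematic viscosity, m^2/s (default 4.0e-6, whole blood).
#' @param rho_ref Physical density mapped to lattice density 1, kg/m^3.
#' @param tau Target relaxation time; sets `dt = (tau - 1/2) dx^2 / (3 nu)`.
#'   Ignored when `dt` is given (then `tau` follows from `dt`).
#' @param dt Explicit time step, s.
#' @param duration Total simulated time, s (default: warm-up plus three
#'   heartbeats of the first inlet waveform).
#' @param rho_out Lattice outlet density shared by all pressure outlets.
#' @param cadence Sampling cadence in steps (default 100).
#' @param snapshot_times Physical times (s) at which to keep full field
#'   snapshots.
#' @param mach_cap Largest admissible lattice Mach number (default 0.1).
#' @param steady_tol Relative velocity-change tolerance for early stopping
#'   at steady state (0 disables; used by steady validation runs).
#' @param steady_every Steps between steady-state checks.
#' @param label Optional run label.
#' @return A `willis_config` object.
#' @export
run_config <- function(domain, inlets, nu = 4.0e-6, rho_ref = 1000,
                       tau = 0.8, dt = NULL, duration = NULL, rho_out = 1,
                       cadence = 100, snapshot_times = numeric(),
                       mach_cap = 0.1, steady_tol = 0, steady_every = 50,
                       label = "") {
  stopifnot(inherits(domain, "voxel_domain"))
  if (is.null(dt)) {
    dt <- (tau - 0.5) / 3 * domain$dx^2 / nu
  }
  units <- lattice_units(domain$dx, dt, rho_ref)
  tau <- relaxation_time(nu, units)

  inlet_labels <- domain$iolets$label[domain$iolets$kind == "velocity_inlet"]
  missing_in <- setdiff(inlet_labels, names(inlets))
  if (length(missing_in) > 0) {
    abort_config(sprintf("No waveform supplied for inlet(s): %s.",
                         paste(missing_in, collapse = ", ")))
  }
  wf1 <- if (length(inlets) > 0) inlets[[1]] else NULL
  if (is.null(duration)) {
    if (is.null(wf1)) abort_config("`duration` is required when the domain has no inlets.")
    duration <- wf1$warmup + 3 * wf1$period
  }
  if (length(inlet_labels) > 0 && duration < wf1$warmup + wf1$period) {
    abort_config("`duration` must cover the warm-up plus at least one period.")
  }
  n_steps <- round(duration / dt)

  v_peak <- 0
  if (length(inlet_labels) > 0) {
    tgrid <- seq(0, duration, length.out = 2001)
    v_peak <- max(vapply(inlets[inlet_labels],
                         function(w) max(wf_eval(w, tgrid)), numeric(1)))
  }
  stab <- stability_report(v_peak, units, tau, mach_cap)
  if (!stab$pass) {
    abort_config(sprintf(
      "Configuration fails the stability check: lattice Mach %.3f exceeds the cap %.2f (or tau <= 1/2). Reduce dt or the inlet velocities.",
      stab$mach, mach_cap
    ))
  }

  structure(
    list(
      domain = domain, inlets = inlets, nu = nu, units = units, tau = tau,
      dt = dt, duration = duration, n_steps = as.integer(n_steps),
      rho_out = rho_out, cadence = as.integer(cadence),
      snapshot_steps = sort(unique(pmax(1L, as.integer(round(snapshot_times / dt))))),
      mach_predicted = stab$mach, mach_cap = mach_cap,
      steady_tol = steady_tol, steady_every = as.integer(steady_every),
      label = label
    ),
    class = "willis_config"
  )
}

#' @export
print.willis_config <- function(x, ...) {
  cat(sprintf(
    "<willis_config> %s%d steps of dt = %g s (%.3g s), tau = %.4f, predicted Ma = %.3f, %d wet sites\n",
    if (nzchar(x$label)) paste0(x$label, ": ") else "", x$n_steps, x$dt,
    x$duration, x$tau, x$mach_predicted, n_wet(x$domain)
  ))
  invisible(x)
}

#' Run a simulation
#'
#' Executes the configured number of BGK steps with the fixed update order
#' collide, stream, walls, inlets, outlets, recording per-iolet flow-rate
#' series and mass/velocity diagnostics at the sampling cadence and full
#' population snapshots at the requested times. Fully deterministic:
#' identical configurations produce bit-identical results.
#'
#' @param config A `willis_config`.
#' @param f0 Optional initial 19 x n population matrix (default: uniform
#'   equilibrium at density `rho_out`, zero velocity).
#' @return A `willis_run` object: list with `config`, `series` (tibble
#'   `time_s`, `iolet`, `kind`, `q_m3s`), `diagnostics` (tibble `time_s`,
#'   `mass`, `mass_drift`, `umax_lat`, `mach`), `snapshots`, `f_final`,
#'   `steps_run`, `converged`.
#' @export
run_simulation <- function(config, f0 = NULL) {
  stopifnot(inherits(config, "willis_config"))
  dom <- config$domain
  io <- dom$iolets
  n_io <- nrow(io)
  if (is.null(f0)) f0 <- init_equilibrium(dom, rho = config$rho_out)

  inlet_speed <- matrix(0, config$n_steps, max(1L, n_io))
  for (k in seq_len(n_io)) {
    if (io$kind[k] == "velocity_inlet") {
      wf <- config$inlets[[io$label[k]]]
      tt <- seq_len(config$n_steps) * config$dt
      inlet_speed[, k] <- wf_eval(wf, tt) * config$dt / dom$dx
    }
  }
  iolet_dir <- rbind(io$dirx, io$diry, io$dirz)
  if (n_io == 0) iolet_dir <- matrix(0, 3, 1)
  rho_out_v <- rep(config$rho_out, max(1L, n_io))

  res <- cpp_run_lbm(
    f0, dom$neigh, dom$kind, dom$iolet_of, dom$weight,
    iolet_dir, inlet_speed, rho_out_v, dom$interior,
    config$tau, config$n_steps, config$cadence,
    as.integer(config$snapshot_steps),
    config$steady_tol, config$steady_every
  )
  if (isTRUE(res$diverged)) {
    abort_diverged(sprintf(
      "Simulation diverged at site %d, step %d (non-finite population or non-positive density).",
      res$div_site, res$div_step
    ), site = res$div_site, step = res$div_step)
  }

  mass0 <- sum(f0)
  q_factor <- dom$dx^3 / config$dt
  series <- tibble::tibble()
  if (n_io > 0 && length(res$sample_steps) > 0) {
    series <- tidyr::expand_grid(
      step = res$sample_steps,
      iolet = io$label
    )
    series$kind <- rep(io$kind, times = length(res$sample_steps))
    series$time_s <- series$step * config$dt
    series$q_m3s <- as.vector(t(res$flow)) * q_factor
    series <- series[, c("time_s", "iolet", "kind", "q_m3s")]
  }
  diagnostics <- tibble::tibble(
    time_s = res$sample_steps * config$dt,
    mass = res$mass,
    mass_drift = (res$mass - mass0) / mass0,
    umax_lat = res$umax,
    mach = res$umax * sqrt(3)
  )
  snapshots <- purrr::map2(
    res$snapshots, res$snapshot_steps,
    function(fm, st) list(step = st, time_s = st * config$dt, f = fm)
  )
  structure(
    list(
      config = config, series = series, diagnostics = diagnostics,
      snapshots = snapshots, f_final = res$f,
      steps_run = res$steps_run, converged = res$converged
    ),
    class = "willis_run"
  )
}

#' @export
print.willis_run <- function(x, ...) {
  cat(sprintf(
    "<willis_run> %s%d steps (%.3g s), %d iolets, max Mach %.3f\n",
    if (nzchar(x$config$label)) paste0(x$config$label, ": ") else "",
    x$steps_run, x$steps_run * x$config$dt, nrow(x$config$domain$iolets),
    max(c(0, x$diagnostics$mach))
  ))
  invisible(x)
}

run_period <- function(run) {
  wf <- run$config$inlets[[1]]
  if (is.null(wf)) abort_config("Run has no inlet waveform to take a period from.")
  wf$period
}

#' Compare a stroke run against its healthy counterpart
#'
#' Produces the per-outlet stroke-to-healthy flow-ratio series (after
#' window smoothing, default one twentieth of a period) and final-beat
#' cycle-averaged ratios ranked from most to least reduced. Both runs must
#' share the geometry, discretisation and sampling cadence.
#'
#' @param healthy,stroke `willis_run` objects from the same configuration
#'   apart from the inlet scenario.
#' @param window_s Smoothing window (s); default `period / 20`.
#' @return A `willis_comparison`: list with `ratios` (series tibble) and
#'   `summary` (per-outlet tibble with `ratio_final_beat` and `rank`).
#' @export
compare_runs <- function(healthy, stroke, window_s = NULL) {
  ch <- healthy$config; cs <- stroke$config
  if (!identical(ch$domain$shape, cs$domain$shape) ||
      ch$domain$dx != cs$domain$dx || ch$dt != cs$dt ||
      ch$cadence != cs$cadence || ch$n_steps != cs$n_steps) {
    abort_config("Healthy and stroke runs use different grids, time steps or cadences.")
  }
  period <- run_period(healthy)
  if (is.null(window_s)) window_s <- period / 20
  out_h <- dplyr::filter(healthy$series, .data$kind == "pressure_outlet")
  out_s <- dplyr::filter(stroke$series, .data$kind == "pressure_outlet")
  ratios <- flow_ratio(out_s, out_h, window_s = window_s)

  t_end <- healthy$steps_run * ch$dt
  a <- t_end - period
  fb <- function(df) {
    df <- dplyr::filter(df, .data$time_s >= a - 1e-12)
    dplyr::summarise(dplyr::group_by(df, .data$iolet),
                     q_mean = mean(.data$q_m3s), .groups = "drop")
  }
  qh <- fb(out_h); qs <- fb(out_s)
  summary <- dplyr::inner_join(qh, qs, by = "iolet",
                               suffix = c("_healthy", "_stroke"))
  summary$ratio_final_beat <- summary$q_mean_stroke / summary$q_mean_healthy
  summary <- dplyr::arrange(summary, .data$ratio_final_beat)
  summary$rank <- seq_len(nrow(summary))
  structure(
    list(ratios = ratios, summary = summary, period = period,
         final_beat = c(a, t_end), window_s = window_s),
    class = "willis_comparison"
  )
}

#' @export
print.willis_comparison <- function(x, ...) {
  cat(sprintf("<willis_comparison> final beat [%.3g, %.3g] s\n",
              x$final_beat[1], x$final_beat[2]))
  print(x$summary[, c("iolet", "ratio_final_beat", "rank")])
  invisible(x)
}

#' Desk-scale circle-of-Willis run configuration
#'
#' Convenience constructor for the study configuration: an idealised
#' circle-of-Willis variant voxelised at `dx`, pulsatile inlets on the
#' basilar and carotid arteries, optionally with one of the five infarct
#' scenarios applied to the basilar inlet. The desk-scale default peak
#' velocities (BA 0.0072, ICA 0.009 m/s; the physiological 0.4:0.5 ratio)
#' keep the lattice Mach number under the cap at the default resolution
#' and relaxation time; see the methods vignette for the regime discussion.
#'
#' @param variant Circle-of-Willis variant (see [build_idealized_cow()]).
#' @param scenario `NULL` for healthy flow, or a scenario id 1-5.
#' @param dx Lattice spacing, m (default 2e-4).
#' @param tau Target relaxation time (default 0.8).
#' @param v_ba,v_ica Peak inlet velocities, m/s.
#' @param warmup Warm-up, s.
#' @param n_beats Number of heartbeats after warm-up.
#' @param domain Optionally a pre-voxelised domain (skips voxelisation, for
#'   reuse across scenarios).
#' @param ... Passed to [run_config()].
#' @return A `willis_config`.
#' @export
cow_config <- function(variant = "FULL", scenario = NULL, dx = 2e-4,
                       tau = 0.8, v_ba = 0.0072, v_ica = 0.009,
                       warmup = 0.4, n_beats = 3, domain = NULL, ...) {
  if (is.null(domain)) domain <- voxelize(build_idealized_cow(variant), dx)
  period <- 2.6 / 3
  wf_ba <- healthy_profile(v_ba, period = period, warmup = warmup)
  wf_ica <- healthy_profile(v_ica, period = period, warmup = warmup)
  duration <- warmup + n_beats * period
  if (!is.null(scenario)) {
    sc <- stroke_scenario(scenario, period = period, warmup = warmup,
                          t_end = duration)
    wf_ba <- apply_scenario(wf_ba, sc)
  }
  run_config(
    domain,
    inlets = list(BA = wf_ba, LICA = wf_ica, RICA = wf_ica),
    tau = tau, duration = duration,
    label = sprintf("CoW %s / %s", variant,
                    if (is.null(scenario)) "healthy" else paste0("stroke ", scenario)),
    ...
  )
}

#' Run the variant x scenario experiment matrix
#'
#' Executes one healthy run per circle-of-Willis variant plus every
#' requested stroke scenario, and pairs each stroke run with its variant's
#' healthy run. Runs are independent and order-insensitive.
#'
#' @param variants Character vector of variants.
#' @param scenarios Integer vector of scenario ids (1-5).
#' @param ... Passed to [cow_config()].
#' @return A tibble with columns `variant`, `scenario` (`NA` for healthy),
#'   `run` (list of `willis_run`), `comparison` (list of
#'   `willis_comparison`, `NULL` for healthy rows).
#' @export
run_matrix <- function(variants = c("FULL", "NO_PCOA_LEFT", "NO_PCOA_RIGHT"),
                       scenarios = 1:5, ...) {
  rows <- list()
  for (v in variants) {
    dom <- voxelize(build_idealized_cow(v), dx = list(...)$dx %||% 2e-4)
    healthy <- run_simulation(cow_config(v, scenario = NULL, domain = dom, ...))
    rows[[length(rows) + 1]] <- tibble::tibble(
      variant = v, scenario = NA_integer_,
      run = list(healthy), comparison = list(NULL)
    )
    for (s in scenarios) {
      stroke <- run_simulation(cow_config(v, scenario = s, domain = dom, ...))
      rows[[length(rows) + 1]] <- tibble::tibble(
        variant = v, scenario = as.integer(s),
        run = list(stroke), comparison = list(compare_runs(healthy, stroke))
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Grid-convergence study on a steady network flow
#'
#' Runs the same steady-inlet configuration at a sequence of resolutions,
#' rescaling the time step diffusively (`dt` proportional to `dx^2` at
#' fixed viscosity, i.e. fixed relaxation time) and reports the total
#' outlet flow with its relative change between successive resolutions; a
#' change of at most 2% flags the pair grid-independent.
#'
#' @param network A `vessel_network`.
#' @param dx_values Decreasing lattice spacings, m (at least 2).
#' @param v_inlet Steady peak inlet velocity, m/s (applied to every inlet).
#' @param nu Kinematic viscosity, m^2/s.
#' @param tau Relaxation time (fixed across resolutions).
#' @param steady_tol,max_time Steady-state stopping tolerance and run-time
#'   cap (s).
#' @return A tibble `dx`, `n_wet`, `q_out_m3s`, `rel_change`,
#'   `grid_independent`.
#' @export
convergence_study <- function(network, dx_values, v_inlet = 0.01,
                              nu = 4.0e-6, tau = 0.8, steady_tol = 1e-6,
                              max_time = 1.0) {
  if (length(dx_values) < 2) abort_config("Need at least two resolutions.")
  res <- purrr::map(dx_values, function(dx) {
    dom <- voxelize(network, dx)
    run <- steady_run(dom, v_inlet, nu = nu, tau = tau,
                      steady_tol = steady_tol, max_time = max_time)
    u <- run$config$units
    q <- sum(vapply(
      dom$iolets$label[dom$iolets$kind == "pressure_outlet"],
      function(l) outlet_flow_rate(run$f_final, dom, l, u), numeric(1)
    ))
    list(n = n_wet(dom), q = q)
  })
  q <- vapply(res, `[[`, numeric(1), "q")
  rel <- c(NA, abs(diff(q)) / abs(q[-length(q)]))
  tibble::tibble(
    dx = dx_values,
    n_wet = vapply(res, `[[`, numeric(1), "n"),
    q_out_m3s = q,
    rel_change = rel,
    grid_independent = !is.na(rel) & rel <= 0.02
  )
}

# steady flat-amplitude run used by validation and convergence studies
steady_run <- function(domain, v_inlet, nu = 4.0e-6, tau = 0.8,
                       steady_tol = 1e-6, max_time = 1.0, cadence = 100) {
  wfs <- list()
  for (l in domain$iolets$label[domain$iolets$kind == "velocity_inlet"]) {
    # constant signal: flat shape, short ramp to ease the start
    wfs[[l]] <- healthy_profile(v_inlet, period = max_time / 4,
                                warmup = 20 * steady_warmup_dt(domain, nu, tau),
                                p_min = 1 - 1e-12, peak_width = 0.5)
  }
  cfg <- run_config(domain, wfs, nu = nu, tau = tau,
                    duration = max_time, cadence = cadence,
                    steady_tol = steady_tol, steady_every = cadence,
                    label = "steady")
  run_simulation(cfg)
}

steady_warmup_dt <- function(domain, nu, tau) {
  (tau - 0.5) / 3 * domain$dx^2 / nu
}

`%||%` <- function(a, b) if (is.null(a)) b else a
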