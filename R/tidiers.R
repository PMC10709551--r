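# broom-style tidiers for runs and comparisons.

#' Tidy a simulation run
#'
#' @param x A `willis_run`.
#' @param ... Unused.
#' @return The per-iolet flow-rate series as a tibble (`time_s`, `iolet`,
#'   `kind`, `q_m3s`).
#' @method tidy willis_run
#' @export
tidy.willis_run <- function(x, ...) x$series

#' One-row summary of a simulation run
#'
#' @param x A `willis_run`.
#' @param ... Unused.
#' @return A one-row tibble: step count, discretisation, relaxation time,
#'   predicted and realised lattice Mach number, cumulative relative mass
#'   drift, wet-site count and convergence flag.
#' @method glance willis_run
#' @export
glance.willis_run <- function(x, ...) {
  tibble::tibble(
    label = x$config$label,
    steps = x$steps_run,
    dt = x$config$dt,
    dx = x$config$domain$dx,
    tau = x$config$tau,
    mach_predicted = x$config$mach_predicted,
    mach_realized = max(c(0, x$diagnostics$mach)),
    mass_drift = if (nrow(x$diagnostics)) utils::tail(x$diagnostics$mass_drift, 1) else NA_real_,
    n_wet = n_wet(x$config$domain),
    converged = x$converged
  )
}

#' Tidy a healthy/stroke comparison
#'
#' @param x A `willis_comparison`.
#' @param ... Unused.
#' @return The ratio series tibble.
#' @method tidy willis_comparison
#' @export
tidy.willis_comparison <- function(x, ...) x$ratios

#' Per-outlet summary of a comparison
#'
#' @param x A `willis_comparison`.
#' @param ... Unused.
#' @return The per-outlet tibble of final-beat cycle-averaged
#'   stroke-to-healthy ratios, ranked from most to least reduced.
#' @method glance willis_comparison
#' @export
glance.willis_comparison <- function(x, ...) x$summary

#' Final-beat stroke-to-healthy ratios
#'
#' @param x A `willis_comparison`.
#' @return Named numeric vector of final-beat ratios, one per outlet.
#' @export
final_beat_ratios <- function(x) {
  stopifnot(inherits(x, "willis_comparison"))
  stats::setNames(x$summary$ratio_final_beat, x$summary$iolet)
}
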