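# Pulsatile inlet waveforms and the five basilar-infarct scenarios. A
# waveform is the time course of the *peak* inlet velocity; the per-site
# parabolic weights scale it across the cap plane. Scenarios multiply the
# healthy signal by a piecewise-linear envelope.

#' Healthy pulsatile inlet waveform
#'
#' A periodic, non-negative peak-velocity signal with one systolic peak per
#' cardiac cycle: a raised-cosine pulse of relative width `peak_width`
#' centred at phase `peak_phase`, above a diastolic floor `p_min`. A linear
#' multiplicative ramp over the warm-up interval eases the simulation from
#' rest. The default period (2.6/3 s) makes three heartbeats span 2.6 s of
#' physical time.
#'
#' @param v_max Peak systolic velocity, m/s.
#' @param period Cardiac period, s.
#' @param warmup Warm-up duration, s (linear 0 -> 1 amplitude ramp).
#' @param p_min Diastolic floor as a fraction of `v_max` (in `[0, 1)`).
#' @param peak_phase Phase in `[0, 1)` of the systolic peak.
#' @param peak_width Relative width of the systolic pulse (fraction of one
#'   period).
#' @return An object of class `waveform`.
#' @export
#' @examples
#' wf <- healthy_profile(v_max = 0.4)
#' wf_eval(wf, seq(0, 2.6, by = 0.1))
healthy_profile <- function(v_max, period = 2.6 / 3, warmup = 0.4,
                            p_min = 0.25, peak_phase = 0.2,
                            peak_width = 0.35) {
  if (period <= 0) abort_parameter("`period` must be positive.")
  if (v_max < 0) abort_parameter("`v_max` must be non-negative.")
  if (p_min < 0 || p_min >= 1) abort_parameter("`p_min` must lie in [0, 1).")
  structure(
    list(
      v_max = v_max, period = period, warmup = warmup,
      p_min = p_min, peak_phase = peak_phase, peak_width = peak_width,
      envelope = NULL
    ),
    class = "waveform"
  )
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf(
    "<waveform> v_max = %g m/s, period = %g s, warmup = %g s%s\n",
    x$v_max, x$period, x$warmup,
    if (is.null(x$envelope)) "" else
      sprintf(" [scenario %s applied]", x$envelope$id)
  ))
  invisible(x)
}

# dimensionless periodic shape p(phi) in [p_min, 1]
waveform_shape <- function(w, phi) {
  phi <- phi %% 1
  d <- phi - w$peak_phase
  d <- d - round(d)                    # wrapped phase distance in [-0.5, 0.5]
  pulse <- ifelse(abs(d) <= w$peak_width / 2,
                  0.5 * (1 + cos(2 * pi * d / w$peak_width)), 0)
  w$p_min + (1 - w$p_min) * pulse
}

#' Evaluate a waveform
#'
#' Peak inlet velocity at physical times `t`:
#' `v(t) = ramp(t) * g(t) * v_max * p(phi(t))` where `ramp` is the linear
#' warm-up factor, `g` any applied stroke envelope, and `p` the periodic
#' shape. The cardiac phase is referenced to the end of warm-up.
#'
#' @param w A `waveform`.
#' @param t Numeric vector of times, s.
#' @return Velocities in m/s (same length as `t`).
#' @export
wf_eval <- function(w, t) {
  stopifnot(inherits(w, "waveform"))
  ramp <- if (w$warmup > 0) pmin(1, pmax(0, t / w$warmup)) else rep(1, length(t))
  phi <- (t - w$warmup) / w$period
  v <- w$v_max * ramp * waveform_shape(w, phi)
  if (!is.null(w$envelope)) {
    v <- v * stroke_envelope(w$envelope, t)
  }
  v
}

#' The five basilar-infarct scenarios
#'
#' Scenario table: (1) a sudden halt, the flow ramping linearly to zero
#' within a quarter heartbeat of onset; (2) a slow stoppage, ramping
#' linearly to zero from onset to the end of the simulation; (3)-(5)
#' linear restriction over a quarter heartbeat to 50%, 30% and 10% of the
#' healthy flow, then held. All five share one onset instant (by default
#' the start of the second beat after warm-up).
#'
#' @param period Cardiac period, s.
#' @param onset Stroke onset time, s (default `warmup + period`).
#' @param t_end Simulation end time, s (sets scenario 2's ramp).
#' @param warmup Warm-up used for the default onset, s.
#' @return A tibble with columns `id`, `label`, `onset`, `ramp`,
#'   `residual`; class `stroke_scenario` rows are extracted with
#'   [stroke_scenario()].
#' @export
scenario_defaults <- function(period = 2.6 / 3, onset = NULL, t_end = NULL,
                              warmup = 0.4) {
  if (is.null(onset)) onset <- warmup + period
  if (is.null(t_end)) t_end <- warmup + 3 * period
  if (t_end <= onset) abort_parameter("`t_end` must exceed `onset`.")
  ramp <- c(period / 4, t_end - onset, period / 4, period / 4, period / 4)
  tibble::tibble(
    id = 1:5,
    label = c("sudden halt", "slow stoppage", "restrict to 50%",
              "restrict to 30%", "restrict to 10%"),
    onset = onset,
    ramp = ramp,
    residual = c(0, 0, 0.5, 0.3, 0.1)
  )
}

#' Extract one stroke scenario record
#'
#' @param id Scenario id, 1-5.
#' @inheritParams scenario_defaults
#' @return A one-row scenario record (list with class `stroke_scenario`).
#' @export
stroke_scenario <- function(id, period = 2.6 / 3, onset = NULL, t_end = NULL,
                            warmup = 0.4) {
  tab <- scenario_defaults(period, onset, t_end, warmup)
  if (!id %in% tab$id) abort_parameter("Scenario `id` must be 1..5.")
  row <- as.list(tab[tab$id == id, ])
  structure(row, class = "stroke_scenario")
}

#' Stroke envelope multiplier
#'
#' The piecewise-linear factor `g(t)` applied to the healthy inlet signal:
#' 1 before onset, linear from 1 to the residual fraction over the ramp,
#' constant at the residual afterwards. Continuous and non-increasing.
#'
#' @param scenario A `stroke_scenario` (or any list with `onset`, `ramp`,
#'   `residual`).
#' @param t Times, s.
#' @return Multipliers in `[residual, 1]`.
#' @export
stroke_envelope <- function(scenario, t) {
  a <- scenario$residual
  frac <- pmin(1, pmax(0, (t - scenario$onset) / scenario$ramp))
  1 + (a - 1) * frac
}

#' Apply a stroke scenario to a waveform
#'
#' Returns the infarcted inlet signal `v'(t) = g(t) v(t)`. Healthy
#' comparison runs simply use the unmodified waveform.
#'
#' @param w A `waveform`.
#' @param scenario A `stroke_scenario`.
#' @return A `waveform` with the envelope attached.
#' @export
#' @examples
#' wf <- healthy_profile(0.4)
#' s5 <- stroke_scenario(5)
#' wf5 <- apply_scenario(wf, s5)
apply_scenario <- function(w, scenario) {
  stopifnot(inherits(w, "waveform"))
  w$envelope <- scenario
  w
}

#' Write / read a sampled waveform as two-column delimited text
#'
#' Columns: `time_s`, `velocity_m_s` (tab separated, header line).
#'
#' @param w A `waveform`.
#' @param path Output file path.
#' @param t Sample times, s.
#' @return `export_waveform()` returns `path` invisibly;
#'   `import_waveform()` returns a tibble.
#' @export
export_waveform <- function(w, path, t = seq(0, w$warmup + 3 * w$period,
                                             by = w$period / 200)) {
  tbl <- tibble::tibble(time_s = t, velocity_m_s = wf_eval(w, t))
  utils::write.table(tbl, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname export_waveform
#' @export
import_waveform <- function(path) {
  tibble::as_tibble(utils::read.delim(path))
}
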