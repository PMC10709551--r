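# Shared fixtures, built lazily and cached for the whole test run. All are
# deterministic solver runs; the slower ones (Poiseuille tube, bifurcation,
# circle-of-Willis matrix) are reused across several test files.

fx_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(fx_env[[name]])) fx_env[[name]] <- build()
  fx_env[[name]]
}

# Poiseuille tube at 32 sites/diameter, tau = 1: the main analytic fixture.
poiseuille_fixture <- function() {
  fixture("poiseuille", function() poiseuille_validation())
}

# Mirror-symmetric bifurcation, tau = 0.55 (minimal compressibility error).
bifurcation_fixture <- function() {
  fixture("bifurcation", function() {
    dom <- voxelize(build_bifurcation(), 1.5e-4)
    run <- willisflow:::steady_run(dom, 0.01, tau = 0.55,
                                   steady_tol = 1e-6, max_time = 3.0)
    list(domain = dom, run = run)
  })
}

# Small tube with a pulsatile inlet for cheap end-to-end checks.
small_tube_fixture <- function() {
  fixture("small_tube", function() {
    dom <- voxelize(build_tube(4e-4, 1.6e-3), 1e-4)
    wf <- healthy_profile(0.01, period = 2e-3, warmup = 1e-3)
    cfg <- run_config(dom, list("in" = wf), tau = 0.8,
                      duration = 15 * 2.5e-4, cadence = 5)
    list(domain = dom, waveform = wf, config = cfg,
         run = run_simulation(cfg))
  })
}

# Desk-scale circle-of-Willis matrix: healthy + scenario-1 runs on the
# three variants, with healthy/stroke comparisons per variant.
cow_fixture <- function() {
  fixture("cow", function() {
    out <- list()
    for (v in c("FULL", "NO_PCOA_LEFT", "NO_PCOA_RIGHT")) {
      dom <- voxelize(build_idealized_cow(v), 2e-4)
      healthy <- run_simulation(cow_config(v, NULL, domain = dom))
      stroke <- run_simulation(cow_config(v, 1, domain = dom))
      out[[v]] <- list(domain = dom, healthy = healthy, stroke = stroke,
                       comparison = compare_runs(healthy, stroke))
    }
    out
  })
}
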