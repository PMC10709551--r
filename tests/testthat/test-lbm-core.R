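test_that("equilibrium populations match direct evaluation and their moments", {
  f <- equilibrium(1, c(0.1, 0, 0))
  # rest direction, w = 1/3: (1/3)(1 - 0.1^2 * 3/2)
  expect_equal(f[1, 1], (1 / 3) * (1 - 0.015), tolerance = 1e-14)
  # direction (1,0,0), w = 1/18: (1/18)(1 + 0.3 + 0.045 - 0.015)
  expect_equal(f[2, 1], (1 / 18) * 1.33, tolerance = 1e-14)
  # rest state: f = w
  expect_equal(as.vector(equilibrium(1, c(0, 0, 0))), velocity_set()$weights,
               tolerance = 1e-15)
  # moments are exact for a batch of random states
  set.seed(42)
  n <- 50
  rho <- runif(n, 0.8, 1.2)
  u <- matrix(runif(3 * n, -0.05, 0.05), 3)
  fe <- equilibrium(rho, u)
  expect_equal(colSums(fe), rho, tolerance = 1e-14)
  expect_equal(t(velocity_set()$directions) %*% fe,
               sweep(u, 2, rho, "*"), tolerance = 1e-14,
               ignore_attr = TRUE)
  m <- macroscopics(fe)
  expect_equal(m$rho, rho, tolerance = 1e-14)
  expect_equal(m$u, u, tolerance = 1e-13)
  expect_equal(m$p, rho / 3, tolerance = 1e-14)
})

test_that("macroscopics computes moments of hand-built populations", {
  f <- matrix(0, 19, 1)
  f[2, 1] <- 0.6   # (1, 0, 0)
  f[3, 1] <- 0.4   # (-1, 0, 0)
  m <- macroscopics(f)
  expect_equal(m$rho, 1)
  expect_equal(as.vector(m$u), c(0.2, 0, 0))
  expect_error(macroscopics(-f), class = "willisflow_diverged_error")
})

test_that("BGK collision conserves mass and momentum and relaxes fully at tau = 1", {
  set.seed(7)
  n <- 200
  rho <- runif(n, 0.9, 1.1)
  u <- matrix(runif(3 * n, -0.05, 0.05), 3)
  f <- equilibrium(rho, u) * (1 + matrix(runif(19 * n, -0.05, 0.05), 19))
  vs <- velocity_set()
  for (tau in c(0.55, 0.8, 1.3)) {
    fc <- collide_bgk(f, tau)
    expect_equal(colSums(fc), colSums(f), tolerance = 1e-12)
    expect_equal(t(vs$directions) %*% fc, t(vs$directions) %*% f,
                 tolerance = 1e-12)
  }
  # fixed point: equilibrium input returns itself
  fe <- equilibrium(rho, u)
  expect_equal(collide_bgk(fe, 0.77), fe, tolerance = 1e-14)
  # full relaxation: tau = 1 lands exactly on the local equilibrium
  m <- macroscopics(f)
  expect_equal(collide_bgk(f, 1), equilibrium(m$rho, m$u), tolerance = 1e-14)
  expect_error(collide_bgk(f, 0.5), class = "willisflow_parameter_error")
  f_bad <- f; f_bad[4, 10] <- NaN
  expect_error(collide_bgk(f_bad, 0.8), class = "willisflow_diverged_error")
})

test_that("streaming advects populations one cell per step and conserves mass", {
  dom <- build_periodic_box(c(6, 5, 4), 1e-4)
  n <- n_wet(dom)
  f <- matrix(0, 19, n)
  s0 <- dom$site_id[2, 3, 2]
  f[2, s0] <- 1  # single population along (1, 0, 0)
  st <- stream_populations(f, dom)
  expect_false(anyNA(st$f))  # fully periodic: every link resolved
  s1 <- dom$site_id[3, 3, 2]
  expect_equal(st$f[2, s1], 1)
  expect_equal(sum(st$f), 1)
  # second application moves it one more cell
  st2 <- stream_populations(st$f, dom)
  expect_equal(st2$f[2, dom$site_id[4, 3, 2]], 1)
  # mass conservation for a disordered field
  set.seed(1)
  fr <- matrix(runif(19 * n), 19, n)
  expect_equal(sum(stream_populations(fr, dom)$f), sum(fr),
               tolerance = 1e-14)
})

test_that("a quiescent closed box is a fixed point and conserves mass long-term", {
  dom <- build_closed_box(c(10, 10, 10), 1e-4)
  dt <- willisflow:::steady_warmup_dt(dom, 4e-6, 0.8)
  cfg <- run_config(dom, list(), nu = 4e-6, tau = 0.8,
                    duration = 200 * dt, cadence = 50)
  fq <- init_equilibrium(dom, rho = 1)
  rq <- run_simulation(cfg, f0 = fq)
  expect_lt(max(abs(rq$f_final - fq)), 1e-14)
  # sheared initial state: mass still conserved to rounding
  x <- dom$sites
  ui <- rbind(0.01 * sin(2 * pi * x[, 3] / 11),
              0.01 * cos(2 * pi * x[, 1] / 11), 0)
  rs <- run_simulation(cfg, f0 = equilibrium(1, ui))
  expect_lt(abs(utils::tail(rs$diagnostics$mass_drift, 1)), 1e-12)
})

test_that("the compiled driver reproduces the composed reference update", {
  fix <- small_tube_fixture()
  dom <- fix$domain
  cfg <- fix$config
  f <- init_equilibrium(dom, rho = 1)
  for (s in seq_len(cfg$n_steps)) {
    v <- wf_eval(fix$waveform, s * cfg$dt) * cfg$dt / dom$dx
    f <- lbm_step(f, dom, cfg$tau, inlet_speed = c("in" = v), rho_out = 1)
  }
  expect_lt(max(abs(f - fix$run$f_final)), 1e-12)
})
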