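test_that("quiescent iolets leave an equilibrium state exactly fixed", {
  dom <- voxelize(build_tube(4e-4, 1.2e-3), 1e-4)
  wf0 <- healthy_profile(0, period = 2e-3, warmup = 1e-3)
  cfg <- run_config(dom, list("in" = wf0), tau = 0.8,
                    duration = 20 * 2.5e-4, cadence = 10)
  f0 <- init_equilibrium(dom, rho = 1)
  run <- run_simulation(cfg, f0 = f0)
  expect_lt(max(abs(run$f_final - f0)), 1e-14)
})

test_that("a zero-velocity inlet reduces to static bounce-back", {
  dom <- voxelize(build_tube(4e-4, 1.2e-3), 1e-4)
  set.seed(11)
  n <- n_wet(dom)
  f <- equilibrium(runif(n, 0.95, 1.05),
                   matrix(runif(3 * n, -0.02, 0.02), 3))
  fstar <- collide_bgk(f, 0.8)
  st <- stream_populations(fstar, dom)
  st <- apply_walls(st, dom)
  st <- apply_velocity_inlet(st, dom, "in", v_lat = 0)
  vs <- velocity_set()
  sel <- which(dom$iolet_of == 1)
  for (i in 1:19) {
    open <- sel[dom$neigh[i, sel] == -2L]
    if (length(open) > 0) {
      expect_equal(st$f[cbind(vs$opposite[i], open)],
                   fstar[cbind(i, open)], tolerance = 1e-15)
    }
  }
})

test_that("the pressure outlet is a fixed point of a uniform resting state", {
  dom <- voxelize(build_tube(4e-4, 1.2e-3), 1e-4)
  f <- init_equilibrium(dom, rho = 1)
  st <- stream_populations(collide_bgk(f, 0.8), dom)
  st <- apply_walls(st, dom)
  st <- apply_velocity_inlet(st, dom, "in", v_lat = 0)
  st <- apply_pressure_outlet(st, dom, "out", rho_out = 1)
  expect_false(anyNA(st$f))
  expect_lt(max(abs(st$f - f)), 1e-14)
})

test_that("a steady tube realises the imposed inlet profile and flow", {
  fix <- poiseuille_fixture()
  dom <- fix$domain
  run <- fix$run
  units <- run$config$units
  sel <- which(dom$iolet_of == 1)
  v_lat <- 0.01 * run$config$dt / dom$dx
  imposed <- v_lat * dom$weight[sel]
  m <- macroscopics(run$f_final[, sel, drop = FALSE])
  # realised per-site normal velocity tracks the prescribed parabola
  expect_lt(sqrt(sum((m$u[2, ] - imposed)^2) / sum(imposed^2)), 0.03)
  # discharge equals the prescribed weighted flow
  q_in <- outlet_flow_rate(run$f_final, dom, "in", units)
  expect_equal(q_in, sum(imposed) * units$velocity * dom$dx^2,
               tolerance = 0.03)
  # outlet plane density pinned at the reference
  osel <- which(dom$iolet_of == 2)
  rho_out <- macroscopics(run$f_final[, osel, drop = FALSE])$rho
  expect_equal(mean(rho_out), 1, tolerance = 1e-3)
})

test_that("inlet speeds approaching the sound speed are refused", {
  dom <- voxelize(build_tube(4e-4, 1.2e-3), 1e-4)
  f <- init_equilibrium(dom)
  st <- stream_populations(collide_bgk(f, 0.8), dom)
  st <- apply_walls(st, dom)
  expect_error(apply_velocity_inlet(st, dom, "in", v_lat = 0.6),
               class = "willisflow_parameter_error")
})

test_that("global mass balance and symmetry hold at steady state", {
  fix <- bifurcation_fixture()
  units <- fix$run$config$units
  q_in <- outlet_flow_rate(fix$run$f_final, fix$domain, "in", units)
  q_r <- outlet_flow_rate(fix$run$f_final, fix$domain, "out-R", units)
  q_l <- outlet_flow_rate(fix$run$f_final, fix$domain, "out-L", units)
  expect_equal(q_r + q_l, q_in, tolerance = 0.01)
  expect_equal(q_r / (q_r + q_l), 0.5, tolerance = 1e-10)
  # the two outlet series agree pointwise after the initial transient
  s <- fix$run$series
  late <- s[s$time_s > 0.25 * max(s$time_s) & s$kind == "pressure_outlet", ]
  qr <- late$q_m3s[late$iolet == "out-R"]
  ql <- late$q_m3s[late$iolet == "out-L"]
  expect_lt(max(abs(qr - ql) / pmax(abs(qr), 1e-30)), 0.01)
})
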