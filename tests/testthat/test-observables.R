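test_that("flow rate through a plane sums the normal velocity", {
  dom <- voxelize(build_tube(4e-4, 1.2e-3), 1e-4)
  units <- lattice_units(dom$dx, 2.5e-4)
  U <- 0.02  # lattice
  f <- init_equilibrium(dom, rho = 1, u = c(0, U, 0))
  nsel <- sum(dom$iolet_of == 2)
  q <- outlet_flow_rate(f, dom, "out", units)
  expect_equal(q, nsel * U * units$velocity * dom$dx^2, tolerance = 1e-12)
  # quiescent state: zero
  expect_equal(outlet_flow_rate(init_equilibrium(dom), dom, "out", units), 0)
  # analytic Poiseuille discharge from the solver fixture
  fix <- poiseuille_fixture()
  expect_lt(abs(fix$measures$q_rel_err), 0.03)
})

test_that("cycle averages integrate constants, sinusoids and sawtooths", {
  T <- 0.8
  t <- seq(0, 3 * T, length.out = 1201)
  expect_equal(cycle_average(t, rep(3.3, length(t)), T, cycle = 2), 3.3)
  v <- 2 + 0.7 * sin(2 * pi * t / T)
  expect_equal(cycle_average(t, v, T, cycle = 1), 2, tolerance = 1e-5)
  expect_equal(cycle_average(t, v, T, cycle = 3), 2, tolerance = 1e-5)
  # sawtooth from a to b over one period: mean (a + b) / 2
  a <- -1; b <- 5
  t1 <- seq(0, T, length.out = 401)
  saw <- a + (b - a) * t1 / T
  expect_equal(cycle_average(t1, saw, T, cycle = 1), (a + b) / 2,
               tolerance = 1e-9)
  expect_error(cycle_average(t, v, T, cycle = 4),
               class = "willisflow_parameter_error")
})

test_that("flow ratios divide window-averaged series and mask weak denominators", {
  t <- seq(0.01, 1, by = 0.01)
  base <- tibble::tibble(
    time_s = rep(t, 2),
    iolet = rep(c("a", "b"), each = length(t)),
    kind = "pressure_outlet",
    q_m3s = rep(2 + sin(2 * pi * t), 2)
  )
  same <- flow_ratio(base, base, window_s = 0.05)
  expect_equal(same$ratio, rep(1, nrow(same)), tolerance = 1e-12)
  half <- base
  half$q_m3s <- base$q_m3s / 2
  r <- flow_ratio(half, base, window_s = 0.05)
  expect_equal(r$ratio, rep(0.5, nrow(r)), tolerance = 1e-12)
  expect_false(any(r$masked))
  # healthy flow crossing zero: masked, not divided
  osc <- base
  osc$q_m3s <- rep(sin(2 * pi * t), 2)
  rm <- flow_ratio(osc, osc)
  expect_true(any(rm$masked))
  expect_true(all(is.na(rm$ratio[rm$masked])))
  # mismatched stamps refused
  shifted <- base
  shifted$time_s <- shifted$time_s + 1e-3
  expect_error(flow_ratio(shifted, base), class = "willisflow_config_error")
})

test_that("velocity magnitude is the Euclidean norm with its maximum on the axis", {
  dom <- voxelize(build_tube(4e-4, 1.2e-3), 1e-4)
  units <- lattice_units(dom$dx, 2.5e-4)
  f <- init_equilibrium(dom, rho = 1, u = c(0.003, 0.004, 0))
  vm <- velocity_magnitude(f, dom, units)
  expect_equal(vm$speed_m_s, rep(0.005 * units$velocity, n_wet(dom)),
               tolerance = 1e-12)
  expect_equal(attr(vm, "max"), 0.005 * units$velocity, tolerance = 1e-12)
  expect_equal(max(velocity_magnitude(init_equilibrium(dom), dom,
                                      units)$speed_m_s), 0)
  # Poiseuille: the fastest site sits on the tube axis (x = z = 0)
  fix <- poiseuille_fixture()
  vmx <- velocity_magnitude(fix$run$f_final, fix$domain,
                            fix$run$config$units)
  top <- vmx[which.max(vmx$speed_m_s), ]
  expect_lt(sqrt(top$x^2 + top$z^2), 1.5 * fix$domain$dx)
})

test_that("wall shear stress vanishes at rest and matches Couette and Poiseuille", {
  dom <- voxelize(build_tube(4e-4, 1.2e-3), 1e-4)
  units <- lattice_units(dom$dx, 2.5e-4)
  w0 <- wss_field(init_equilibrium(dom), 0.8, dom, units)
  expect_gt(nrow(w0), 0)
  expect_lt(max(w0$wss_pa), 1e-12)
  expect_true(all(c("nx", "ny", "nz") %in% names(w0)))
  expect_true(is.numeric(attr(w0, "skipped")))
  # planar Couette: analytic rho nu U / H
  cm <- couette_validation()$measures
  expect_lt(abs(cm$wss_rel_err), 0.03)
  expect_lt(cm$profile_rms, 0.01)
  # Poiseuille wall stress: 2 rho nu u_max / R
  fix <- poiseuille_fixture()
  expect_lt(abs(fix$measures$wss_rel_err), 0.05)
})

test_that("WSS exports clamp to the display range", {
  w <- tibble::tibble(wss_pa = c(-1, 0.5, 10, 50))
  cl <- clamp_wss(w)
  expect_equal(cl$wss_pa, c(0, 0.5, 10, 20))
})
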