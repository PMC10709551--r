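test_that("relaxation time reproduces the blood discretisation and inverts", {
  u <- lattice_units(dx = 25e-6, dt = 1e-6)
  expect_equal(relaxation_time(4.0e-6, u), 0.5192, tolerance = 1e-12)
  # inverse map recovers the viscosity
  for (nu in c(1e-6, 4e-6, 3.3e-5)) {
    expect_equal(viscosity_from_tau(relaxation_time(nu, u), u), nu,
                 tolerance = 1e-12)
  }
  # zero-viscosity limit tau -> 1/2
  expect_lt(relaxation_time(1e-15, u) - 0.5, 1e-6)
  # lattice viscosity 1/6 gives tau = 1
  u2 <- lattice_units(dx = 1e-4, dt = 1e-3)
  expect_equal(relaxation_time(u2$dx^2 / (6 * u2$dt), u2), 1, tolerance = 1e-14)
})

test_that("invalid unit and viscosity inputs are refused", {
  expect_error(lattice_units(-1e-6, 1e-6), class = "willisflow_parameter_error")
  expect_error(lattice_units(1e-6, 0), class = "willisflow_parameter_error")
  u <- lattice_units(25e-6, 1e-6)
  expect_error(relaxation_time(0, u), class = "willisflow_parameter_error")
  expect_error(relaxation_time(-1e-6, u), class = "willisflow_parameter_error")
  expect_error(viscosity_from_tau(0.5, u), class = "willisflow_parameter_error")
})

test_that("the low-Mach diagnostic flags admissible and supersonic flows", {
  u <- lattice_units(25e-6, 1e-6)
  r0 <- stability_report(0, u, tau = 0.5192)
  expect_equal(r0$mach, 0)
  expect_true(r0$pass)
  # peak in-domain speed of the healthy runs
  r <- stability_report(0.595, u, tau = 0.5192)
  expect_equal(r$lattice_speed, 0.0238, tolerance = 1e-12)
  expect_equal(r$mach, 0.0238 * sqrt(3), tolerance = 1e-12)
  expect_equal(r$mach, 0.0412, tolerance = 1e-2)
  expect_true(r$pass)
  # at or above the lattice sound speed: never admissible
  u_sonic <- (1 / sqrt(3)) * u$dx / u$dt
  expect_false(stability_report(u_sonic * 1.01, u, tau = 5)$pass)
  expect_false(stability_report(u_sonic * 20, u, tau = 0.8)$pass)
})
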