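test_that("the healthy profile is periodic, normalised and spans three beats", {
  wf <- healthy_profile(v_max = 0.4)
  expect_equal(3 * wf$period, 2.6, tolerance = 1e-12)
  tt <- seq(wf$warmup, wf$warmup + wf$period, length.out = 20001)
  v <- wf_eval(wf, tt)
  expect_equal(max(v) / wf$v_max, 1, tolerance = 1e-6)
  expect_true(all(v >= 0))
  # exact periodicity after warm-up
  t2 <- seq(wf$warmup, wf$warmup + wf$period, length.out = 997)
  expect_equal(wf_eval(wf, t2), wf_eval(wf, t2 + wf$period), tolerance = 1e-12)
  expect_equal(wf_eval(wf, t2), wf_eval(wf, t2 + 2 * wf$period), tolerance = 1e-12)
  # linear multiplicative warm-up ramp from zero
  expect_equal(wf_eval(wf, 0), 0)
  half <- wf_eval(wf, wf$warmup / 2)
  shape_half <- wf_eval(wf, wf$warmup / 2 + 0)  # same phase reference
  expect_lt(half, wf$v_max)
  # diastolic floor respected
  expect_gte(min(v), wf$p_min * wf$v_max - 1e-12)
})

test_that("the five scenario records carry the study parameters", {
  tab <- scenario_defaults()
  expect_identical(tab$id, 1:5)
  expect_equal(tab$residual, c(0, 0, 0.5, 0.3, 0.1))
  expect_length(unique(tab$onset), 1)   # all share one onset
  T <- 2.6 / 3
  expect_equal(tab$ramp[c(1, 3, 4, 5)], rep(T / 4, 4))
  expect_equal(tab$ramp[2], (0.4 + 3 * T) - tab$onset[2])
  expect_true(all(tab$ramp > 0))
})

test_that("envelopes are continuous, non-increasing, piecewise linear", {
  t_end <- 0.4 + 2.6
  for (id in 1:5) {
    sc <- stroke_scenario(id, t_end = t_end)
    tt <- seq(0, t_end, length.out = 4001)
    g <- stroke_envelope(sc, tt)
    expect_true(all(g >= sc$residual - 1e-12 & g <= 1 + 1e-12))
    expect_true(all(diff(g) <= 1e-12))
    expect_equal(g[tt < sc$onset], rep(1, sum(tt < sc$onset)))
    expect_lt(max(abs(diff(g, differences = 2)[
      abs(tt[-c(1, 2)] - sc$onset) > 2e-3 &
      abs(tt[-c(1, 2)] - (sc$onset + sc$ramp)) > 2e-3])), 1e-9)
  }
  # quarter-heartbeat halt
  s1 <- stroke_scenario(1, t_end = t_end)
  expect_equal(stroke_envelope(s1, s1$onset + s1$ramp + c(0, 0.1, 1)),
               c(0, 0, 0))
  # slow stoppage: exactly 1/2 at the midpoint of onset -> simulation end
  s2 <- stroke_scenario(2, t_end = t_end)
  expect_equal(stroke_envelope(s2, (s2$onset + t_end) / 2), 0.5,
               tolerance = 1e-12)
  expect_equal(stroke_envelope(s2, t_end), 0, tolerance = 1e-12)
  # 50% restriction holds beyond the ramp
  s3 <- stroke_scenario(3, t_end = t_end)
  expect_equal(stroke_envelope(s3, s3$onset + s3$ramp + c(0, 0.5)),
               c(0.5, 0.5))
})

test_that("scenario waveforms never exceed the healthy signal", {
  wf <- healthy_profile(0.4)
  t_end <- wf$warmup + 3 * wf$period
  tt <- seq(0, t_end, length.out = 3001)
  v <- wf_eval(wf, tt)
  for (id in 1:5) {
    vs <- wf_eval(apply_scenario(wf, stroke_scenario(id, t_end = t_end)), tt)
    expect_true(all(vs >= -1e-15))
    expect_true(all(vs <= v + 1e-15))
  }
  # an identity envelope leaves the waveform untouched
  ident <- structure(list(onset = 1, ramp = 1, residual = 1),
                     class = "stroke_scenario")
  expect_equal(wf_eval(apply_scenario(wf, ident), tt), v)
  # sudden halt: zero for all t beyond onset + ramp
  w1 <- apply_scenario(wf, stroke_scenario(1, t_end = t_end))
  late <- tt[tt >= wf$warmup + wf$period + wf$period / 4]
  expect_equal(wf_eval(w1, late), rep(0, length(late)))
})

test_that("sampled waveforms round-trip through delimited text", {
  wf <- healthy_profile(0.4)
  path <- withr::local_tempfile(fileext = ".tsv")
  export_waveform(wf, path)
  back <- import_waveform(path)
  expect_named(back, c("time_s", "velocity_m_s"))
  expect_equal(back$velocity_m_s, wf_eval(wf, back$time_s), tolerance = 1e-6)
})
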