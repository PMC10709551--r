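test_that("D3Q19 moment identities hold in exact integer arithmetic", {
  vs <- velocity_set()
  w36 <- round(36 * vs$weights)
  expect_identical(w36, c(12, rep(2, 6), rep(1, 12)))
  expect_equal(36 * vs$weights, w36, tolerance = 1e-15)
  expect_identical(sum(w36), 36)
  # first moment vanishes
  expect_identical(as.vector(t(vs$directions) %*% w36), c(0, 0, 0))
  # second moment is cs2 * identity: sum w ci cj = (1/3) delta_ij
  second <- t(vs$directions) %*% (w36 * vs$directions)
  expect_identical(second, diag(12, 3))
  expect_equal(vs$cs2, 1 / 3)
})

test_that("the opposite map is an involution pairing c and -c", {
  vs <- velocity_set()
  expect_identical(vs$opposite[vs$opposite], 1:19)
  expect_identical(vs$directions[vs$opposite, ], -vs$directions)
  expect_identical(which(vs$opposite == 1:19), 1L)  # only the rest vector
})
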