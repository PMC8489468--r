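test_that("acquire in the noiseless limit reproduces noiseless_signal", {
  gt <- fixture_gt()
  pr <- acquisition_protocol(noise_sigma = 1e-9, seed = 5L)
  st <- acquire(gt, pr, noiseless = TRUE)
  for (ib in 1:3)
    for (id in 1:3)
      expect_equal(st$data[ib, id, 1, , ], noiseless_signal(gt, pr$b_values[ib], id))
})

test_that("acquire is deterministic and clipped to the ceiling", {
  gt <- fixture_gt(s0_tissue = 4000)
  pr <- acquisition_protocol(noise_sigma = 400, intensity_ceiling = 4095L,
                             seed = 7L)
  s1 <- acquire(gt, pr)
  s2 <- acquire(gt, pr)
  expect_identical(s1$data, s2$data)
  expect_true(all(s1$data >= 0) && all(s1$data <= 4095))
  expect_true(any(s1$data == 4095))  # clipping engaged at this S0/sigma
})

test_that("background magnitudes follow the Rayleigh mean", {
  # S = 0 voxels: E|n| = sigma * sqrt(pi/2)
  spec <- phantom_spec(c(128L, 128L), list(
    compartment("t", "ellipse", c(64, 64), c(18, 18), s0 = 1000,
                adc = 1e-3)), background_s0 = 0)
  gt <- generate_phantom(spec)
  pr <- acquisition_protocol(b_values = 900, n_directions = 3L,
                             n_acquisitions = 3L, noise_sigma = 50, seed = 2L)
  st <- acquire(gt, pr)
  bg <- gt$s0_map == 0
  draws <- unlist(lapply(1:3, function(id) lapply(1:3, function(ia)
    st$data[1, id, ia, , ][bg])))
  expect_gt(length(draws), 1e5)
  expect_equal(mean(draws), 50 * sqrt(pi / 2), tolerance = 0.05)
  # averaging does not remove the noise floor: the trace-weighted chain
  # leaves E[NOA_9 background] = sqrt(2) * gamma(7/6)^3 * sigma (~1.129
  # sigma, from Rayleigh fractional moments E[X^k] = sigma^k 2^(k/2)
  # Gamma(1 + k/2)), verified by Monte Carlo
  noa9_bg <- average_acquisitions(trace_weighted(st))$data[1, , ][bg]
  expect_gt(mean(noa9_bg), 0)
  expect_equal(mean(noa9_bg), sqrt(2) * gamma(7 / 6)^3 * 50,
               tolerance = 0.02)
})

test_that("trace_weighted matches the exp-mean-log oracle", {
  st <- fixture_random_stack(seed = 3L)
  tr <- trace_weighted(st)
  for (ib in 1:2)
    for (ia in 1:3) {
      oracle <- matrix(0, 8, 8)
      for (i in 1:8)
        for (j in 1:8)
          oracle[i, j] <- exp(mean(log(st$data[ib, , ia, i, j])))
      expect_equal(tr$data[ib, ia, , ], oracle, tolerance = 1e-12)
    }
})

test_that("trace_weighted special cases", {
  st <- fixture_random_stack(seed = 4L, nb = 1L, na = 1L)
  st$data[1, , 1, 1, 1] <- c(2, 4, 8)
  tr <- trace_weighted(st)
  expect_equal(tr$data[1, 1, 1, 1], 4)
  # all directions identical -> identity
  for (d in 2:3) st$data[1, d, 1, , ] <- st$data[1, 1, 1, , ]
  expect_equal(trace_weighted(st)$data[1, 1, , ], st$data[1, 1, 1, , ])
})

test_that("AM-GM holds voxel-wise for the trace image", {
  st <- fixture_random_stack(seed = 9L)
  tr <- trace_weighted(st)
  for (ib in 1:2)
    for (ia in 1:3) {
      am <- (st$data[ib, 1, ia, , ] + st$data[ib, 2, ia, , ] +
               st$data[ib, 3, ia, , ]) / 3
      expect_true(all(tr$data[ib, ia, , ] <= am + 1e-12))
    }
})

test_that("average_acquisitions matches a per-voxel loop oracle and sets NOA", {
  st <- fixture_random_stack(seed = 5L)
  tr <- trace_weighted(st)
  ci <- average_acquisitions(tr)
  expect_identical(ci$noa, 9L)  # 3 directions x 3 acquisitions
  for (ib in 1:2) {
    oracle <- matrix(0, 8, 8)
    for (i in 1:8)
      for (j in 1:8)
        oracle[i, j] <- sum(tr$data[ib, , i, j]) / 3
    expect_equal(ci$data[ib, , ], oracle, tolerance = 1e-12)
  }
  # identical trace images -> identity
  for (ia in 2:3) tr$data[, ia, , ] <- tr$data[, 1, , ]
  expect_equal(average_acquisitions(tr)$data[1, , ], tr$data[1, 1, , ])
})

test_that("normalize maps the ceiling to 1 and inverts exactly", {
  expect_identical(normalize_intensity(4095, 4095), 1)
  expect_identical(normalize_intensity(0, 4095), 0)
  expect_identical(normalize_intensity(939, 939), 1)
  set.seed(8)
  img <- matrix(sample(0:4095, 256, replace = TRUE), 16, 16)
  expect_equal(denormalize_intensity(normalize_intensity(img, 4095L), 4095L),
               img)
})
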