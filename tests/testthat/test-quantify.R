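test_that("fit_adc recovers exact log-linear decay and the phantom truth", {
  b <- c(50, 600, 900)
  gt <- fixture_gt(background_s0 = 100)   # positive signal everywhere
  imgs <- lapply(b, function(bb) noiseless_signal(gt, bb))
  adc <- fit_adc(imgs, b, source = "ground_truth")
  expect_lt(max(abs(adc$data - gt$adc_map)), 1e-10)
  expect_true(all(adc$valid))
  # single-voxel closed form
  s <- lapply(b, function(bb) matrix(1000 * exp(-1.0e-3 * bb), 2, 2))
  a <- fit_adc(s, b)
  expect_equal(a$data[1, 1], 1.0e-3, tolerance = 1e-12)
})

test_that("fit_adc matches the normal-equations oracle on random signals", {
  set.seed(21)
  b <- c(50, 600, 900)
  imgs <- lapply(b, function(bb) matrix(runif(64, 10, 3000), 8, 8))
  adc <- fit_adc(imgs, b)
  for (i in 1:8)
    for (j in 1:8) {
      y <- log(c(imgs[[1]][i, j], imgs[[2]][i, j], imgs[[3]][i, j]))
      slope <- sum((b - mean(b)) * (y - mean(y))) / sum((b - mean(b))^2)
      expect_equal(adc$data[i, j], -slope, tolerance = 1e-12)
    }
})

test_that("fit_adc handles non-positive voxels and bad input", {
  b <- c(50, 600, 900)
  imgs <- lapply(b, function(bb) matrix(100, 4, 4))
  imgs[[2]][2, 2] <- 0
  a <- fit_adc(imgs, b)
  expect_false(a$valid[2, 2])
  expect_identical(a$data[2, 2], 0)
  expect_true(all(a$valid[-6]))
  expect_error(fit_adc(imgs[1], 50), "2 distinct b-values")
  expect_error(fit_adc(imgs, c(50, 600)), "must match")
  # noise can produce negative ADCs, which are preserved
  imgs2 <- list(matrix(100, 2, 2), matrix(150, 2, 2), matrix(200, 2, 2))
  expect_lt(fit_adc(imgs2, b)$data[1, 1], 0)
})

test_that("roi_stats computes mean, population SD and CoV", {
  m <- matrix(1.0e-3, 4, 4)
  mask <- matrix(TRUE, 4, 4)
  st <- roi_stats(m, mask)
  expect_equal(st$mean_adc, 1.0e-3)
  expect_equal(st$std_adc, 0)
  expect_equal(st$cov, 0)
  two <- matrix(c(0.5e-3, 1.5e-3, 0, 0), 2, 2)
  mask2 <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  st2 <- roi_stats(two, mask2)
  expect_equal(st2$mean_adc, 1.0e-3)
  expect_equal(st2$std_adc, 0.5e-3)
  expect_equal(st2$cov, 0.5)
  expect_identical(st2$n_voxels, 2L)
  expect_error(roi_stats(m, matrix(FALSE, 4, 4)), "empty")
  # loop oracle on a random region
  set.seed(3)
  r <- matrix(rnorm(100, 1e-3, 4e-4), 10, 10)
  mk <- matrix(runif(100) < 0.4, 10, 10)
  v <- c()
  for (i in 1:10) for (j in 1:10) if (mk[i, j]) v <- c(v, r[i, j])
  st3 <- roi_stats(r, mk)
  expect_equal(st3$mean_adc, sum(v) / length(v), tolerance = 1e-12)
  expect_equal(st3$std_adc, sqrt(sum((v - mean(v))^2) / length(v)),
               tolerance = 1e-12)
})

test_that("rdm is an absolute percent difference of ROI means", {
  m1 <- matrix(1.02e-3, 4, 4)
  m0 <- matrix(1.00e-3, 4, 4)
  mask <- matrix(TRUE, 4, 4)
  expect_equal(rdm(m1, m0, mask), 2.0, tolerance = 1e-10)
  expect_equal(rdm(m0, m0, mask), 0)
  # scale invariance
  set.seed(4)
  a <- matrix(rnorm(16, 1e-3, 2e-4), 4, 4)
  b <- matrix(rnorm(16, 1.2e-3, 2e-4), 4, 4)
  expect_equal(rdm(a, b, mask), rdm(a * 7, b * 7, mask), tolerance = 1e-10)
  # compositional oracle via roi_stats
  expect_equal(rdm(a, b, mask),
               abs(roi_stats(a, mask)$mean_adc - roi_stats(b, mask)$mean_adc) /
                 roi_stats(b, mask)$mean_adc * 100, tolerance = 1e-12)
  expect_error(rdm(a, matrix(0, 4, 4), mask), "zero")
})

test_that("mavd is the masked mean absolute difference", {
  mask <- matrix(TRUE, 3, 3)
  a <- matrix(1e-3, 3, 3)
  expect_equal(mavd(a, a, mask), 0)
  expect_equal(mavd(a, a + 1e-4, mask), 1e-4, tolerance = 1e-15)
  set.seed(5)
  x <- matrix(rnorm(9), 3, 3); y <- matrix(rnorm(9), 3, 3)
  acc <- 0
  for (i in 1:3) for (j in 1:3) acc <- acc + abs(x[i, j] - y[i, j])
  expect_equal(mavd(x, y, mask), acc / 9, tolerance = 1e-12)
  expect_error(mavd(x, y, matrix(FALSE, 3, 3)), "empty")
})
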