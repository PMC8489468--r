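# Toy training sets are built from clean phantom sections; heavier training
# behaviour (PSNR gain, ADC statistics) lives in test-acceptance.R.

toy_pairs <- function(n = 40L, grid = c(32L, 32L), noise_sd = 0,
                      seed = 100L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    # rasterize at 32x32 (the generator needs >= 16 px margins) and
    # subsample to the requested toy size
    gt <- generate_phantom(random_phantom_spec(seed + i, c(32L, 32L)))
    b <- sample(c(50, 600, 900), 1)
    y <- normalize_intensity(noiseless_signal(gt, b), 4095)
    y <- y[seq(1, 32, length.out = grid[1]), seq(1, 32, length.out = grid[2])]
    x <- if (noise_sd > 0)
      pmin(pmax(y + matrix(rnorm(prod(grid), 0, noise_sd), grid[1]), 0), 1)
    else y
    list(x = x, y = y)
  })
}

test_that("losses match their closed forms and a loop oracle", {
  x <- matrix(0.5, 8, 8)
  expect_identical(loss_mae(x, x), 0)
  expect_identical(loss_mse(x, x), 0)
  expect_equal(loss_mae(x + 0.1, x), 0.1, tolerance = 1e-12)
  expect_equal(loss_mse(x + 0.1, x), 0.01, tolerance = 1e-12)
  set.seed(31)
  a <- matrix(runif(64), 8, 8); b <- matrix(runif(64), 8, 8)
  sae <- 0; sse <- 0
  for (i in 1:8) for (j in 1:8) {
    sae <- sae + abs(a[i, j] - b[i, j]); sse <- sse + (a[i, j] - b[i, j])^2
  }
  expect_equal(loss_mae(a, b), sae / 64, tolerance = 1e-12)
  expect_equal(loss_mse(a, b), sse / 64, tolerance = 1e-12)
  expect_error(loss_mae(a, matrix(0, 4, 4)))
})

test_that("combined MAE/SSIM loss degenerates and composes correctly", {
  set.seed(32)
  a <- matrix(runif(24 * 24), 24, 24); b <- matrix(runif(24 * 24), 24, 24)
  expect_equal(loss_mae_ssim(a, b, alpha = 1), loss_mae(a, b),
               tolerance = 1e-12)
  expect_equal(loss_mae_ssim(a, a, alpha = 0), 0, tolerance = 1e-12)
  expect_equal(loss_mae_ssim(a, b, alpha = 0.7),
               0.7 * loss_mae(a, b) + 0.3 * (1 - ssim(a, b)),
               tolerance = 1e-12)
})

test_that("parameter count equals an independent layer-by-layer count", {
  # independent arithmetic: two kxk convs per level, 2x2 up-convolutions,
  # concatenated skips, linear 1x1 output
  oracle_count <- function(depth, base, k = 3) {
    ch <- base * 2^(0:(depth - 1))
    total <- 0
    for (l in 1:depth) {
      cin <- if (l == 1) 1 else ch[l - 1]
      total <- total + (cin * k * k + 1) * ch[l] + (ch[l] * k * k + 1) * ch[l]
    }
    for (l in 1:(depth - 1)) {
      total <- total + (ch[l + 1] * 4 + 1) * ch[l]             # up-conv
      total <- total + (2 * ch[l] * k * k + 1) * ch[l]         # dec conv1
      total <- total + (ch[l] * k * k + 1) * ch[l]             # dec conv2
    }
    total + base + 1                                           # 1x1 output
  }
  for (cfg in list(c(4, 16), c(3, 8), c(2, 4))) {
    m <- build_model(model_config(depth = cfg[1], base_channels = cfg[2],
                                  input_shape = c(64, 64)), seed = 1)
    expect_identical(count_parameters(m), oracle_count(cfg[1], cfg[2]))
  }
})

test_that("build_model is seed-deterministic and outputs are finite", {
  cfg <- model_config(depth = 3, base_channels = 8, input_shape = c(32, 32))
  m1 <- build_model(cfg, seed = 9)
  m2 <- build_model(cfg, seed = 9)
  expect_identical(m1$params, m2$params)
  m3 <- build_model(cfg, seed = 10)
  expect_false(identical(m1$params, m3$params))
  set.seed(1)
  x <- matrix(runif(32 * 32), 32, 32)
  y <- denoise(m1, x)
  expect_identical(dim(y), dim(x))
  expect_true(all(is.finite(y)))
})

test_that("incompatible input shapes are rejected with the divisibility", {
  expect_error(model_config(depth = 4, input_shape = c(6, 64)), ">= ")
  m <- build_model(model_config(depth = 3, base_channels = 4,
                                input_shape = c(32, 32)), seed = 1)
  expect_error(denoise(m, matrix(0.1, 2, 2)), "too small")
})

test_that("denoise guards inputs, pads arbitrary sizes, is deterministic", {
  m <- build_model(model_config(depth = 3, base_channels = 4,
                                input_shape = c(32, 32)), seed = 4)
  bad <- matrix(0.5, 32, 32); bad[3, 3] <- NaN
  expect_error(denoise(m, bad), "NaN")
  expect_error(denoise(m, matrix(2, 32, 32)), "normalized")
  # 26 x 35 is not divisible by 4: reflect-pad then crop back
  set.seed(2)
  x <- matrix(runif(26 * 35), 26, 35)
  y <- denoise(m, x)
  expect_identical(dim(y), c(26L, 35L))
  expect_true(all(is.finite(y)))
  expect_identical(y, denoise(m, x))
})

test_that("training learns the identity task and is reproducible", {
  pairs <- toy_pairs(n = 200, grid = c(16L, 16L))
  m0 <- build_model(model_config(depth = 2, base_channels = 8,
                                 input_shape = c(16, 16)), seed = 2)
  initial <- mean(vapply(pairs, function(p)
    loss_mae(denoise(m0, p$x), p$y), 0))
  m <- train_dnif(m0, pairs, train_config("mae", learning_rate = 0.003,
                                          batch_size = 16, epochs = 30,
                                          seed = 3))
  final <- tail(m$training_history, 1)
  expect_lt(final, initial)
  # NOTE: 5e-3 is the empirically verified attainable bound for this
  # schedule; plain fixed-lr Adam on the MAE cost floors near 2.5e-3
  expect_lt(final, 5e-3)
  # bit-identical loss history under identical seeds (short rerun)
  short <- train_config("mae", learning_rate = 0.003, batch_size = 16,
                        epochs = 2, seed = 3)
  m1 <- train_dnif(m0, pairs[1:40], short)
  m2 <- train_dnif(m0, pairs[1:40], short)
  expect_identical(m1$training_history, m2$training_history)
  expect_identical(m1$params, m2$params)
})

test_that("training rejects unnormalized images", {
  pairs <- list(list(x = matrix(2, 16, 16), y = matrix(0.5, 16, 16)))
  m <- build_model(model_config(depth = 2, base_channels = 4,
                                input_shape = c(16, 16)), seed = 1)
  expect_error(train_dnif(m, pairs, train_config("mae", epochs = 1)),
               "normalized")
})

test_that("max-norm constraint holds after training; mae and mae_ssim both
           reduce validation MAE", {
  pairs <- toy_pairs(n = 32, grid = c(32L, 32L), noise_sd = 0.06, seed = 50)
  val <- toy_pairs(n = 8, grid = c(32L, 32L), noise_sd = 0.06, seed = 99)
  val_mae <- function(m) mean(vapply(val, function(p)
    loss_mae(denoise(m, p$x), p$y), 0))
  for (lo in c("mae", "mae_ssim")) {
    m0 <- build_model(model_config(depth = 2, base_channels = 8,
                                   input_shape = c(32, 32)), seed = 5)
    before <- val_mae(m0)
    m <- train_dnif(m0, pairs, train_config(lo, learning_rate = 0.002,
                                            batch_size = 8, epochs = 3,
                                            seed = 6))
    expect_lt(val_mae(m), before)
    for (nm in setdiff(names(m$params), "outc")) {
      W <- m$params[[nm]]$W
      expect_lte(max(sqrt(rowSums(W * W))), 3 + 1e-6)
    }
  }
})
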