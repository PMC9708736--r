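test_that("kernel bank has the published layer geometry and is seed-reproducible", {
  bank <- init_kernel_bank(celm_config(), seed = 5)
  expect_length(bank$layers, 3L)
  expect_equal(vapply(bank$layers, function(l) dim(l$kernels)[4], 0L),
               c(64L, 128L, 256L))
  expect_equal(dim(bank$layers[[2]]$kernels)[1:3], c(3L, 3L, 64L))
  expect_true(all(vapply(bank$layers, function(l) all(l$biases == 0), TRUE)))
  expect_identical(bank, init_kernel_bank(celm_config(), seed = 5))
})

test_that("kernel entries follow Normal(0, 1/fan_in)", {
  cfg <- celm_config(conv_channels = c(2000L, 4L, 4L))  # many layer-1 draws
  bank <- init_kernel_bank(cfg, seed = 11)
  k1 <- c(bank$layers[[1]]$kernels)  # fan_in = 9, sd = 1/3
  n <- length(k1)
  expect_gt(n, 1e4)
  expect_lt(abs(mean(k1)), 3 * (1 / 3) / sqrt(n))
  se_sd <- (1 / 3) / sqrt(2 * (n - 1))
  expect_lt(abs(sd(k1) - 1 / 3), 3 * se_sd)
})

test_that("conv_relu matches a brute-force cross-correlation oracle", {
  set.seed(101)
  for (case in 1:40) {
    cin <- sample(1:3, 1)
    cout <- sample(1:4, 1)
    n <- sample(3:16, 1)
    x <- array(rnorm(n * n * cin), dim = c(n, n, cin))
    layer <- list(kernels = array(rnorm(9 * cin * cout), dim = c(3, 3, cin, cout)),
                  biases = rnorm(cout))
    expect_equal(conv_relu(x, layer), oracle_conv_relu(x, layer$kernels, layer$biases),
                 tolerance = 1e-12)
  }
})

test_that("convolution shrinks k to k - r + 1 and rejects undersized input", {
  layer <- list(kernels = array(1, dim = c(3, 3, 1, 2)), biases = c(0, 0))
  expect_equal(dim(conv_relu(matrix(0, 32, 32), layer)), c(30L, 30L, 2L))
  expect_error(conv_relu(matrix(0, 2, 2), layer), "smaller")
})

test_that("max_pool matches a block-maximum oracle and handles the examples", {
  m <- matrix(1:16, 4, 4, byrow = TRUE)
  expect_equal(max_pool(m)[, , 1], matrix(c(6, 8, 14, 16), 2, 2, byrow = TRUE))
  expect_equal(max_pool(matrix(7, 30, 30))[, , 1], matrix(7, 15, 15))
  set.seed(202)
  for (case in 1:30) {
    n <- sample(4:16, 1)
    x <- array(rnorm(n * n * 2), dim = c(n, n, 2))
    expect_equal(max_pool(x, 2, 2), oracle_max_pool(x, 2L, 2L))
  }
  expect_equal(dim(max_pool(matrix(0, 31, 31))), c(15L, 15L, 1L))  # odd input truncates
})

test_that("global average pooling returns per-channel spatial means", {
  x <- array(c(0, 2, 1, 3, 4, 4, 4, 4), dim = c(2, 2, 2))
  expect_equal(global_avg_pool(x), c(1.5, 4))
  expect_equal(global_avg_pool(matrix(0.3, 5, 7)), 0.3)
})

test_that("branch spatial trace under defaults is 32-30-15-13-6-4 ending in 256 features", {
  bank <- init_kernel_bank(celm_config(), seed = 1)
  x <- array(matrix(rnorm(32 * 32), 32, 32), dim = c(32, 32, 1))
  sizes <- c(dim(x)[1])
  for (l in 1:3) {
    x <- conv_relu(x, bank$layers[[l]])
    sizes <- c(sizes, dim(x)[1])
    if (l < 3) {
      x <- max_pool(x)
      sizes <- c(sizes, dim(x)[1])
    }
  }
  expect_equal(sizes, c(32L, 30L, 15L, 13L, 6L, 4L))
  feat <- global_avg_pool(x)
  expect_length(feat, 256L)
  expect_true(all(feat >= 0))
  # branch_features reproduces the manual composition
  expect_equal(branch_features(x <- matrix(rnorm(32 * 32), 32, 32), bank),
               {
                 y <- conv_relu(x, bank$layers[[1]])
                 y <- max_pool(y)
                 y <- conv_relu(y, bank$layers[[2]])
                 y <- max_pool(y)
                 global_avg_pool(conv_relu(y, bank$layers[[3]]))
               })
})

test_that("zero input with zero biases propagates to zero features", {
  bank <- init_kernel_bank(small_config(), seed = 2)
  expect_equal(branch_features(matrix(0, 20, 20), bank), numeric(16))
})

test_that("siamese pair features share weights and swap with their inputs", {
  bank <- init_kernel_bank(small_config(), seed = 3)
  set.seed(4)
  pa <- matrix(runif(400), 20, 20)
  pb <- matrix(runif(400), 20, 20)
  fab <- pair_features(pa, pb, bank)
  fba <- pair_features(pb, pa, bank)
  expect_length(fab, 32L)
  expect_identical(fab, c(fba[17:32], fba[1:16]))
  faa <- pair_features(pa, pa, bank)
  expect_identical(faa[1:16], faa[17:32])
})
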