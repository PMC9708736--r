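test_that("windowed RMSE matches the brute-force oracle and its closed forms", {
  set.seed(50)
  for (case in 1:30) {
    n <- sample(5:16, 1)
    x <- matrix(rnorm(n * n), n, n)
    y <- matrix(rnorm(n * n), n, n)
    expect_equal(windowed_rmse(x, y, 5L), oracle_windowed_rmse(x, y, 5L),
                 tolerance = 1e-12)
  }
  z <- matrix(runif(64), 8, 8)
  expect_equal(windowed_rmse(z, z), matrix(0, 8, 8))
  expect_equal(windowed_rmse(z + 0.3, z), matrix(0.3, 8, 8))
  # window sizes other than 5 follow the same rule
  expect_equal(windowed_rmse(z, 0 * z, 3L), oracle_windowed_rmse(z, 0 * z, 3L))
})

test_that("the comparison map answers which source the fusion drew from", {
  set.seed(51)
  a <- matrix(runif(144), 12, 12)
  b <- matrix(runif(144), 12, 12)
  # identical triple: every window ties, strict rule gives all zeros
  expect_equal(mf_map(a, a, a), matrix(0L, 12, 12))
  # f == a: locally farther from b wherever they differ at all
  expect_true(all(mf_map(a, a, b)[windowed_rmse(a, b) > 0] == 1L))
  # f == b: never farther from b than from b itself
  expect_equal(mf_map(b, a, b), matrix(0L, 12, 12))
  # swapping the sources complements the map wherever the contest is strict
  f <- b
  f[1:6, ] <- a[1:6, ]
  m1 <- mf_map(f, a, b)
  m2 <- mf_map(f, b, a)
  r1 <- windowed_rmse(f - b, 0 * f)
  r2 <- windowed_rmse(f - a, 0 * f)
  strict <- r1 != r2
  expect_equal(m1[strict], 1L - m2[strict])
})

test_that("an impulse block fused from A is claimed for A by the comparison map", {
  a <- matrix(0, 8, 8)
  a[3:5, 3:5] <- 1
  b <- matrix(0, 8, 8)
  f <- a
  got <- mf_map(f, a, b)
  r1 <- oracle_windowed_rmse(f - b, matrix(0, 8, 8), 5L)
  r2 <- oracle_windowed_rmse(f - a, matrix(0, 8, 8), 5L)
  expect_equal(got, matrix(as.integer(r1 > r2), 8, 8))
  expect_true(all(got[3:5, 3:5] == 1L))
})

test_that("morphological smoothing removes speckle and preserves large shapes", {
  # isolated pixel: the 5x5 element cannot fit, opening removes it
  m <- matrix(0L, 16, 16)
  m[8, 8] <- 1L
  expect_equal(smooth_mm(m), matrix(0L, 16, 16))
  expect_equal(smooth_mm(matrix(0L, 16, 16)), matrix(0L, 16, 16))
  # solid 20x20 square survives opening and closing untouched
  sq <- matrix(0L, 64, 64)
  sq[21:40, 21:40] <- 1L
  expect_identical(smooth_mm(sq), sq)
})

test_that("morphological smoothing matches a brute-force open-close oracle", {
  set.seed(52)
  for (case in 1:25) {
    m <- matrix(as.integer(runif(32 * 32) < runif(1, 0.2, 0.8)), 32, 32)
    expect_identical(smooth_mm(m), oracle_open_close(m, 5L))
  }
})

test_that("final selection only rewrites unanimous neighborhoods", {
  set.seed(53)
  a <- matrix(runif(64), 8, 8)
  b <- matrix(runif(64), 8, 8)
  f <- initial_fuse(a, b, matrix(rbinom(64, 1, 0.5), 8, 8))$f
  expect_identical(final_fuse(f, a, b, matrix(1L, 8, 8)), a)
  expect_identical(final_fuse(f, a, b, matrix(0L, 8, 8)), b)
  # identical sources: the initial fusion is that source and stays it
  expect_identical(final_fuse(a, a, a, matrix(rbinom(64, 1, 0.5), 8, 8)), a)
  # ideal checkerboard: every 8-neighbor sum is 4, nothing is unanimous
  chk <- matrix(as.integer((row(matrix(0, 8, 8)) + col(matrix(0, 8, 8))) %% 2 == 0), 8, 8)
  expect_identical(final_fuse(f, a, b, chk), f)
})

test_that("fusing an image with itself returns it exactly through both stages", {
  m <- small_model()
  a <- make_texture(48, seed = 30)
  res <- fuse_images(a, a, m)
  expect_identical(res$ff, a)
  expect_identical(res$f, a)
})

test_that("end-to-end selection closure: every fused pixel comes from a source", {
  m <- small_model()
  for (seed in 1:3) {
    ph <- make_phantom_pair(64, seed = seed)
    res <- fuse_images(ph$image_a, ph$image_b, m)
    expect_true(all(res$f == ph$image_a | res$f == ph$image_b))
    expect_true(all(res$ff == ph$image_a | res$ff == ph$image_b |
                      res$ff == res$f))
    expect_true(all(res$ff == ph$image_a | res$ff == ph$image_b))
  }
})

test_that("a trained model recovers the informative regions of a phantom", {
  m <- small_model()
  ph <- make_phantom_pair(96, seed = 0)
  res <- fuse_images(ph$image_a, ph$image_b, m)
  expect_gte(mean((res$ff == ph$image_a)[ph$mask_a]), 0.85)
  expect_gte(mean((res$ff == ph$image_b)[ph$mask_b]), 0.85)
})
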